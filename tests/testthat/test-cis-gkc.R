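test_that("kernel density matches its closed form and the brute-force oracle", {
  sc <- kernel_scale(1000, grid_step = 100)
  tr <- kernel_density(5001, sc, 20000)   # grid runs 1, 101, ..., so 5001 is on it
  expect_equal(tr$density[tr$grid == 5001], 1.0)
  expect_equal(tr$density[tr$grid == 6001], exp(-0.5))
  # superposition: k coincident insertions peak at exactly k
  trk <- kernel_density(rep(5001, 7), sc, 20000)
  expect_equal(max(trk$density), 7)

  set.seed(123)
  pos <- sort(runif(100, 1, 2e6))
  sc2 <- kernel_scale(30e3, grid_step = 3000)
  tr2 <- kernel_density(pos, sc2, 2e6)
  expect_lt(max(abs(tr2$density - naive_gkc(tr2$grid, pos, sc2$h))), 1e-9)

  expect_error(kernel_density(c(10, -5), sc, 20000), "within")
})

test_that("density mass is conserved away from chromosome ends", {
  set.seed(5)
  h <- 20e3
  pos <- runif(40, 4 * h + 1, 10e6 - 4 * h)
  tr <- kernel_density(pos, kernel_scale(h), 10e6)
  integral <- sum(diff(tr$grid) * (head(tr$density, -1) + tr$density[-1]) / 2)
  expect_lt(abs(integral - 40 * h * sqrt(2 * pi)) / (40 * h * sqrt(2 * pi)),
            0.01)
})

test_that("permutation threshold behaves as an empirical max-peak quantile", {
  sc <- kernel_scale(30e3)
  # single insertion: every permutation max peak is exactly 1
  thr1 <- null_peak_threshold(1, 10e6, sc, alpha = 0.05, n_perm = 100, seed = 1)
  expect_equal(as.numeric(thr1), 1.0)
  expect_true(all(abs(attr(thr1, "max_peaks") - 1) < 1e-12))

  peaks <- attr(null_peak_threshold(30, 50e6, sc, n_perm = 300, seed = 2),
                "max_peaks")
  thr_strict <- null_peak_threshold(30, 50e6, sc, alpha = 0.01,
                                    n_perm = 300, seed = 2)
  thr_loose <- null_peak_threshold(30, 50e6, sc, alpha = 0.5,
                                   n_perm = 300, seed = 2)
  thr_all <- null_peak_threshold(30, 50e6, sc, alpha = 0.999,
                                 n_perm = 300, seed = 2)
  expect_gte(thr_strict, thr_loose)
  expect_gte(thr_loose, thr_all)
  expect_equal(as.numeric(thr_all), min(peaks))

  expect_error(null_peak_threshold(10, 1e6, sc, alpha = 0), "alpha")
  expect_error(null_peak_threshold(10, 1e6, sc, n_perm = 10), "n_perm")
})

test_that("two independent seeds agree within the Monte-Carlo CI of the 95th percentile", {
  sc <- kernel_scale(30e3)
  t1 <- null_peak_threshold(50, 100e6, sc, alpha = 0.05, n_perm = 1000,
                            seed = 101)
  t2 <- null_peak_threshold(50, 100e6, sc, alpha = 0.05, n_perm = 1000,
                            seed = 202)
  # bootstrap CI of the quantile from the first run's maxima
  peaks <- attr(t1, "max_peaks")
  set.seed(7)
  boot <- replicate(2000, quantile(sample(peaks, replace = TRUE), 0.95,
                                   type = 1, names = FALSE))
  expect_gte(as.numeric(t2), quantile(boot, 0.001))
  expect_lte(as.numeric(t2), quantile(boot, 0.999))
})

test_that("a planted cluster is detected as one CIS with correct tumor support", {
  set.seed(9)
  ins <- make_insertions(tumor_id = sprintf("T%02d", c(1:15, 1:5)),
                         chrom = "chr1",
                         position = round(runif(20, 25e6, 25e6 + 10e3)),
                         lp_count = 3)
  cis <- detect_cis(ins, genome_layout("chr1", 50e6), scales = 30e3,
                    alpha = 0.05, n_perm = 300, seed = 4)
  expect_equal(nrow(cis), 1L)
  expect_lte(cis$start, 25e6)
  expect_gte(cis$end, 25e6 + 10e3)
  expect_equal(cis$n_tumors, 15L)
  expect_equal(cis$n_insertions, 20L)

  expect_equal(nrow(detect_cis(ins[0, ], genome_layout("chr1", 50e6))), 0L)
})

test_that("kernel scale controls resolution and overlapping scales merge", {
  set.seed(10)
  pos <- c(round(runif(15, 20e6, 20e6 + 5e3)),
           round(runif(15, 21e6, 21e6 + 5e3)))
  ins <- make_insertions(sprintf("T%02d", rep(1:15, 2)), "chr1", pos,
                         lp_count = 2)
  g <- genome_layout("chr1", 50e6)
  two <- detect_cis(ins, g, scales = 30e3, n_perm = 300, seed = 5)
  expect_equal(nrow(two), 2L)
  one <- detect_cis(ins, g, scales = 1e6, n_perm = 300, seed = 5)
  expect_equal(nrow(one), 1L)
  # multi-scale: overlapping regions merge, smallest scale is reported
  both <- detect_cis(ins, g, scales = c(30e3, 1e6), n_perm = 300, seed = 5)
  expect_true(all(both$scale == 30e3))
})

test_that("detection is input-order invariant and monotone under added support", {
  set.seed(11)
  ins <- make_insertions(sprintf("T%02d", 1:18), "chr1",
                         round(runif(18, 30e6, 30e6 + 8e3)), lp_count = 2)
  g <- genome_layout("chr1", 40e6)
  a <- detect_cis(ins, g, scales = 30e3, n_perm = 300, seed = 6)
  b <- detect_cis(ins[sample.int(nrow(ins)), ], g, scales = 30e3,
                  n_perm = 300, seed = 6)
  expect_equal(a, b)

  # fixed calibration: adding an insertion inside the CIS can only widen it
  thr <- data.frame(chrom = "chr1", h = 30e3, threshold = a$threshold[1])
  base <- detect_cis(ins, g, scales = 30e3, thresholds = thr)
  more <- detect_cis(rbind(ins, make_insertions("T99", "chr1",
                                                round(base$peak[1]),
                                                lp_count = 2)),
                     g, scales = 30e3, thresholds = thr)
  expect_equal(nrow(more), nrow(base))
  expect_lte(more$start[1], base$start[1])
  expect_gte(more$end[1], base$end[1])
})

test_that("target assignment follows the nearest-gene heuristic with its tie rule", {
  ann <- data.frame(chrom = "chr1",
                    start = c(100e3, 300e3, 500e3),
                    end = c(150e3, 320e3, 540e3),
                    strand = "+", name = c("GeneA", "GeneB", "GeneC"))
  inside <- assign_target(make_cis("chr1", 301e3, 315e3), ann)
  expect_equal(inside$target, "GeneB")
  # peak at 230e3: 80 kb past GeneA's end, 70 kb before GeneB -> GeneB
  near <- assign_target(make_cis("chr1", 225e3, 235e3), ann)
  expect_equal(near$target, "GeneB")
  # equidistant peak at 235e3 (85 kb from A end 150e3... construct exact tie)
  tie_ann <- data.frame(chrom = "chr1", start = c(100e3, 300e3),
                        end = c(190e3, 390e3), strand = "+",
                        name = c("Left", "Right"))
  tie <- assign_target(make_cis("chr1", 240e3, 250e3), tie_ann)  # peak 245e3
  expect_equal(tie$target, "Left")  # ties break to the upstream gene
  # empty annotation leaves the target unset
  expect_true(is.na(assign_target(make_cis("chr1", 1e3, 2e3),
                                  ann[0, ])$target))
})

test_that("tumor and insertion CIS coverage fractions are exact on known patterns", {
  cis <- make_cis("chr1", 10e3, 20e3)
  ins <- make_insertions(sprintf("T%02d", 1:10), "chr1",
                         c(rep(15e3, 8), 50e3, 60e3), lp_count = 2)
  tumors <- data.frame(tumor_id = sprintf("T%02d", 1:10), strain = "FVB",
                       genotype = rep(c("wt", "mut"), each = 5))
  tab <- tumors_in_cis_fraction(ins, cis, tumors)
  tot <- tab[tab$genotype == "Total", ]
  expect_equal(tot$n_in_cis, 8L)
  expect_equal(tot$percent, 80)
  wt <- tab[tab$genotype == "wt", ]
  expect_equal(wt$n_in_cis, 5L)
  expect_equal(wt$percent, 100)

  cov <- insertions_in_cis_fraction(ins, cis)
  expect_equal(cov$n_in_cis, 8L)
  expect_equal(cov$percent, 80)
})
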