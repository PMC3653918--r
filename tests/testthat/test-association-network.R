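test_that("incidence cells hold the max LP clonality score per tumor and CIS", {
  cis <- make_cis(c("chr1", "chr2"), c(10e3, 50e3), c(20e3, 60e3),
                  target = c("GeneA", "GeneB"))
  ins <- rbind(make_insertions("T1", "chr1", c(12e3, 18e3), lp_count = c(3, 7)),
               make_insertions("T2", "chr2", 55e3, lp_count = 4),
               make_insertions("T3", "chr1", 900e3, lp_count = 5))
  tumors <- data.frame(tumor_id = c("T1", "T2", "T3"), strain = "FVB",
                       genotype = "wt")
  m <- build_incidence(ins, cis, tumors)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["T1", "GeneA"], 7)
  expect_equal(m["T2", "GeneB"], 4)
  expect_equal(unname(m["T3", ]), c(0, 0))   # no insertion in any CIS
  # presence is equivalent to clonality score >= 2
  expect_true(all((m > 0) == (m >= 2)))
})

test_that("incidence from a synthetic cohort equals the truth-derived matrix", {
  cfg <- tiny_config(n_tumors = 70, background_rate = 0, seed = 19)
  co <- simulate_cohort(cfg)
  ins <- filter_single_lp(call_insertions(co$fragments))
  w <- co$truth$windows
  cis <- make_cis(w$chrom, w$start, w$end, target = w$locus)
  tumors <- co$tumors[co$tumors$tumor_id %in% ins$tumor_id, ]
  m <- build_incidence(ins, cis, tumors)
  ev <- co$truth$events
  truth_m <- m * 0
  for (i in seq_len(nrow(ev))) {
    if (ev$lp_count[i] >= 2 && ev$tumor_id[i] %in% rownames(truth_m)) {
      truth_m[ev$tumor_id[i], ev$locus[i]] <-
        max(truth_m[ev$tumor_id[i], ev$locus[i]], ev$lp_count[i])
    }
  }
  expect_equal(unclass(m), unclass(truth_m), ignore_attr = "class")
})

test_that("pairwise Fisher tests match full hypergeometric enumeration", {
  cases <- list(c(10, 0, 0, 90), c(0, 30, 40, 30), c(5, 10, 15, 70),
                c(3, 3, 3, 3), c(12, 8, 2, 78))
  for (cs in cases) {
    pres_a <- rep(c(TRUE, TRUE, FALSE, FALSE), cs)
    pres_b <- rep(c(TRUE, FALSE, TRUE, FALSE), cs)
    m <- make_incidence(cbind(A = pres_a, B = pres_b))
    e <- test_pair(m, "A", "B")
    expect_equal(c(e$n11, e$n10, e$n01, e$n00), cs)
    oracle <- hyper_tails(cs[1], cs[2], cs[3], cs[4])
    expect_equal(e$p_cooccur, oracle$greater, tolerance = 1e-12)
    expect_equal(e$p_exclusive, oracle$less, tolerance = 1e-12)
    # one-sided tails overlap at the observed table
    expect_gte(e$p_cooccur + e$p_exclusive, 1)
    # symmetry under argument swap
    s <- test_pair(m, "B", "A")
    expect_equal(s$p_cooccur, e$p_cooccur)
    expect_equal(s$p_exclusive, e$p_exclusive)
    expect_equal(c(s$n11, s$n01, s$n10, s$n00), c(e$n11, e$n10, e$n01, e$n00))
  }
})

test_that("direction goes to the smaller one-sided tail and degenerate margins are untestable", {
  m <- make_incidence(cbind(A = rep(c(TRUE, FALSE), c(30, 70)),
                            B = rep(c(FALSE, TRUE, FALSE), c(30, 40, 30))))
  e <- test_pair(m, "A", "B")           # zero overlap
  expect_equal(e$n11, 0L)
  expect_equal(e$direction, "mutually-exclusive")
  expect_lt(e$p_exclusive, e$p_cooccur)

  deg <- make_incidence(cbind(A = rep(TRUE, 50), B = rep(c(TRUE, FALSE), 25)))
  d <- test_pair(deg, "A", "B")
  expect_false(d$testable)
  expect_true(is.na(d$p_value))
})

test_that("planted mutual exclusivity is recovered as a significant network edge", {
  set.seed(40)
  n <- 600
  a <- rep(FALSE, n); b <- rep(FALSE, n)
  # two CISs, each in ~40% of tumors, never together
  slot <- sample(c("a", "b", "none"), n, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  a[slot == "a"] <- TRUE; b[slot == "b"] <- TRUE
  noise <- replicate(4, runif(n) < 0.15)
  colnames(noise) <- paste0("N", 1:4)
  m <- make_incidence(cbind(A = a, B = b, noise))
  net <- build_network(m, alpha = 0.05)
  edge <- net$edges[net$edges$cis_a == "A" & net$edges$cis_b == "B", ]
  expect_equal(nrow(edge), 1L)
  expect_equal(edge$direction, "mutually-exclusive")
  expect_lte(edge$q_value, 0.05)

  # single pair at alpha = 1: always reported
  one <- build_network(m[, c("A", "N1")], alpha = 1)
  expect_equal(nrow(one$edges), 1L)
})

test_that("q-values are monotone in p-values and edges are a subset of tests", {
  set.seed(41)
  m <- make_incidence(replicate(6, runif(120) < 0.3))
  net <- build_network(m, alpha = 0.3)
  tt <- net$tests
  expect_true(all(net$edges$p_value %in% tt$p_value))
  pp <- c(tt$p_cooccur, tt$p_exclusive)
  qq <- c(tt$q_cooccur, tt$q_exclusive)
  oo <- order(pp)
  expect_true(all(diff(qq[oo]) >= -1e-12))
})

test_that("family exclusivity: planted patterns give small p, singletons are untestable", {
  set.seed(42)
  n <- 400
  slot <- sample(c("m1", "m2", "m3", "none"), n, replace = TRUE,
                 prob = c(0.25, 0.2, 0.15, 0.4))
  pres <- cbind(M1 = slot == "m1", M2 = slot == "m2", M3 = slot == "m3",
                Solo = runif(n) < 0.3)
  m <- make_incidence(pres)
  fp <- family_pattern(m, list(fam = c("M1", "M2", "M3"), solo = "Solo"),
                       n_perm = 1000, seed = 9)
  fam <- fp[fp$family == "fam", ]
  expect_equal(fam$n_multi, 0L)
  expect_lte(fam$p_value, 0.001)
  expect_gt(fam$expected_multi, 5)
  expect_false(fp$testable[fp$family == "solo"])
})

test_that("independent family members give calibrated permutation p-values", {
  set.seed(43)
  reps <- 100
  pvals <- vapply(seq_len(reps), function(i) {
    m <- make_incidence(cbind(A = runif(200) < 0.35, B = runif(200) < 0.3,
                              C = runif(200) < 0.25))
    family_pattern(m, list(f = c("A", "B", "C")), n_perm = 200,
                   seed = 1000 + i)$p_value
  }, numeric(1))
  # null p-values roughly uniform: no excess of small values, sane mean
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("genotype association detects stratum-specific CISs and not identical rates", {
  pres <- c(rep(TRUE, 20), rep(FALSE, 80), rep(FALSE, 100))
  m <- make_incidence(cbind(X = pres, Y = rep(c(TRUE, FALSE), 100)))
  tumors <- data.frame(tumor_id = rownames(m),
                       strain = "FVB",
                       genotype = rep(c("wt", "mut"), each = 100))
  tab <- genotype_association(m, tumors, "genotype", levels = c("wt", "mut"))
  expect_lt(tab$q_value[tab$cis == "X"], 0.01)
  expect_equal(tab$p_value[tab$cis == "Y"], 1)
  expect_error(genotype_association(m, within <- data.frame(
    tumor_id = rownames(m), strain = "FVB", genotype = "wt"), "genotype"),
    "levels|two")
})

test_that("network and incidence round-trip through their file formats", {
  set.seed(44)
  m <- make_incidence(replicate(3, runif(30) < 0.4),
                      scores = matrix(sample(2:9, 90, TRUE), 30))
  p1 <- tempfile(fileext = ".tsv")
  write_incidence(m, p1)
  back <- read_incidence(p1)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)

  net <- build_network(m, alpha = 1)
  p2 <- tempfile(fileext = ".tsv")
  write_network_edges(net, p2)
  edges <- read.delim(p2)
  expect_equal(nrow(edges), nrow(net$edges))
  p3 <- tempfile(fileext = ".graphml")
  write_network_graphml(net, p3)
  expect_true(file.size(p3) > 0)
  expect_no_error(igraph::read_graph(p3, format = "graphml"))
})
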