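test_that("CIS grouping pools families, counts distinct tumors and applies the support threshold", {
  pres <- matrix(FALSE, 20, 4, dimnames = list(sprintf("T%02d", 1:20),
                                               c("A1", "A2", "B", "C")))
  pres[1:6, "A1"] <- TRUE          # family members hit in disjoint tumors
  pres[7:11, "A2"] <- TRUE         # union: 11 tumors
  pres[1:9, "B"] <- TRUE           # singleton below threshold: 9 tumors
  pres[1:12, "C"] <- TRUE
  m <- make_incidence(pres)
  g <- group_cis(m, list(FamA = c("A1", "A2")), min_tumors = 10)
  expect_setequal(names(g$groups), c("FamA", "C"))
  expect_equal(unname(g$n_tumors["FamA"]), 11)
  expect_true("B" %in% g$dropped)
  # overlapping tumors count once
  pres2 <- pres; pres2[1:6, "A2"] <- TRUE
  g2 <- group_cis(make_incidence(pres2), list(FamA = c("A1", "A2")),
                  min_tumors = 10)
  expect_equal(unname(g2$n_tumors["FamA"]), 11)

  expect_error(group_cis(m, list(F1 = "A1", F2 = c("A1", "B"))), "two families")
})

test_that("synthetic truth groups are recovered from a clean cohort", {
  cfg <- tiny_config(n_tumors = 120, background_rate = 0, seed = 55)
  co <- simulate_cohort(cfg)
  ins <- filter_single_lp(call_insertions(co$fragments))
  w <- co$truth$windows
  cis <- make_cis(w$chrom, w$start, w$end, target = w$locus)
  m <- build_incidence(ins, cis, co$tumors)
  fam_map <- split(w$locus, w$group)
  fam_map <- fam_map[vapply(fam_map, length, 1L) > 1L]
  g <- group_cis(m, fam_map, min_tumors = 10)
  expect_setequal(g$groups$FamA, c("GeneA1", "GeneA2"))
  expect_setequal(g$groups$FamB, c("GeneB1", "GeneB2"))
})

test_that("clonality scores take the maximum LP over group members", {
  m <- make_incidence(matrix(TRUE, 2, 3,
                             dimnames = list(c("T1", "T2"),
                                             c("A1", "A2", "B"))),
                      scores = rbind(c(2, 9, 4), c(5, 0, 7)))
  g <- group_cis(m, list(Fam = c("A1", "A2")), min_tumors = 1)
  s <- clonality_scores(m, g)
  expect_equal(s["T1", "Fam"], 9)
  expect_equal(s["T2", "Fam"], 5)
  expect_equal(s["T1", "B"], 4)
  s_sum <- clonality_scores(m, g, method = "sum")
  expect_equal(s_sum["T1", "Fam"], 11)
})

test_that("binomial clonality comparison matches enumeration and the worked examples", {
  mk <- function(wa, wb, ties = 0) {
    n <- wa + wb + ties
    cbind(a = c(rep(10, wa), rep(2, wb), rep(5, ties)),
          b = c(rep(2, wa), rep(10, wb), rep(5, ties)))
  }
  # 47 wins to 0: one-sided 0.5^47, two-sided doubled
  s <- mk(47, 0)
  rownames(s) <- sprintf("T%02d", 1:47)
  cmp <- compare_groups(s, "a", "b")
  expect_equal(cmp$wins_a, 47L)
  expect_equal(cmp$n_informative, 47L)
  expect_equal(cmp$p_value, 2 * 0.5^47, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1.421085e-14, tolerance = 1e-6)

  even <- compare_groups(mk(5, 5), "a", "b")
  expect_equal(even$p_value, 1)

  nine <- compare_groups(mk(9, 1), "a", "b")
  expect_equal(nine$p_value, 22 / 1024, tolerance = 1e-12)

  # ties excluded from the test
  tied <- compare_groups(mk(3, 1, ties = 4), "a", "b")
  expect_equal(tied$ties, 4L)
  expect_equal(tied$n_informative, 4L)

  # full enumeration oracle for n <= 20, and antisymmetry
  for (n in c(1, 5, 12, 20)) {
    for (wa in 0:n) {
      cc <- compare_groups(mk(wa, n - wa), "a", "b")
      expect_equal(cc$p_value, binom_two_sided_oracle(wa, n - wa),
                   tolerance = 1e-12)
      sw <- compare_groups(mk(wa, n - wa), "b", "a")
      expect_equal(sw$wins_a, cc$wins_b)
      expect_equal(sw$p_value, cc$p_value)
    }
  }

  # monotonicity: more wins at fixed n never increases the one-sided p
  p_one <- vapply(10:20, function(wa)
    compare_groups(mk(wa, 20 - wa), "a", "b", two_sided = FALSE)$p_value,
    numeric(1))
  expect_true(all(diff(p_one) <= 1e-12))

  expect_error(compare_groups(mk(1, 1), "a", "zz"), "unknown group")
  # no co-mutated tumor -> untestable
  none <- compare_groups(cbind(a = c(5, 0), b = c(0, 3)), "a", "b")
  expect_true(is.na(none$p_value))
})

test_that("progression graph directs edges from the more clonal group and reports acyclicity", {
  set.seed(60)
  n <- 200
  # planted order: early > mid > late in expected LP
  early <- 1 + rpois(n, 30); mid <- 1 + rpois(n, 12); late <- 1 + rpois(n, 4)
  s <- cbind(early = early, mid = mid, late = late)
  rownames(s) <- sprintf("T%03d", 1:n)
  cmp <- compare_all_groups(s)
  g <- progression_graph(cmp, alpha = 0.05)
  expect_equal(nrow(g$edges), 3L)
  expect_true(g$acyclic)
  lab <- paste(g$edges$parent, g$edges$child, sep = ">")
  expect_setequal(lab, c("early>mid", "early>late", "mid>late"))
  expect_true(all(g$edges$wins_parent > g$edges$wins_child))
  expect_equal(g$edges$label,
               sprintf("%d/%d", g$edges$wins_parent, g$edges$wins_child))

  expect_equal(nrow(progression_graph(cmp, alpha = 0)$edges), 0L)
})

test_that("progression outputs round-trip and export to GraphML", {
  set.seed(61)
  s <- cbind(a = 1 + rpois(50, 20), b = 1 + rpois(50, 5))
  rownames(s) <- sprintf("T%02d", 1:50)
  cmp <- compare_all_groups(s)
  g <- progression_graph(cmp)
  p1 <- tempfile(fileext = ".tsv")
  write_comparisons(cmp, p1)
  expect_equal(read.delim(p1)$wins_a, cmp$wins_a)
  p2 <- tempfile(fileext = ".tsv")
  write_progression_edges(g, p2)
  expect_equal(read.delim(p2)$label,
               paste0(g$edges$wins_parent, "/", g$edges$wins_child))
  p3 <- tempfile(fileext = ".graphml")
  write_progression_graphml(g, p3)
  gg <- igraph::read_graph(p3, format = "graphml")
  expect_equal(igraph::ecount(gg), nrow(g$edges))
})
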