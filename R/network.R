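#' Tumor-by-CIS incidence matrix with clonality scores
#'
#' Rows are tumors, columns CISs. A cell holds the clonality score of the
#' tumor in that CIS -- the maximum LP count over the tumor's insertions
#' falling inside the CIS interval -- and 0 when the tumor has no insertion
#' there. Only insertions with `lp_count >= 2` enter the matrix (the
#' post-filter minimum), so presence (score > 0) is equivalent to a
#' clonality score of at least 2.
#'
#' @param insertions post-filter insertions.
#' @param cis `cis_set` (columns named by `cis_id`, or by `target` when
#'   assigned and unique).
#' @param tumors tumor metadata; rows of the matrix. Tumors without any CIS
#'   insertion get an all-zero row.
#' @return numeric matrix (class `ims_incidence`) with tumors as rownames
#'   and CIS labels as colnames.
#' @export
build_incidence <- function(insertions, cis, tumors) {
  assert_columns(tumors, "tumor_id", "tumors")
  ins <- insertions[insertions$lp_count >= 2L, , drop = FALSE]
  labels <- cis_labels(cis)
  m <- matrix(0, nrow = nrow(tumors), ncol = nrow(cis),
              dimnames = list(tumors$tumor_id, labels))
  for (i in seq_len(nrow(cis))) {
    idx <- points_in_interval(ins$chrom, ins$position,
                              cis$chrom[i], cis$start[i], cis$end[i])
    if (length(idx) == 0L) next
    sc <- tapply(ins$lp_count[idx], ins$tumor_id[idx], max)
    keep <- names(sc) %in% rownames(m)
    m[names(sc)[keep], i] <- sc[keep]
  }
  class(m) <- c("ims_incidence", class(m))
  m
}

cis_labels <- function(cis) {
  if (!all(is.na(cis$target)) && !anyDuplicated(cis$target[!is.na(cis$target)])) {
    ifelse(is.na(cis$target), cis$cis_id, cis$target)
  } else {
    cis$cis_id
  }
}

#' Test one CIS pair for co-occurrence / mutual exclusivity
#'
#' Builds the 2x2 presence table over tumors and computes both one-sided
#' Fisher exact (hypergeometric) p-values: enrichment of joint presence
#' (co-occurrence) and depletion (mutual exclusivity). The reported
#' direction is the smaller one-sided p; both are retained. Pairs with a
#' degenerate margin (a CIS present in no tumor or in every tumor) are
#' flagged untestable.
#'
#' @param matrix incidence matrix from [build_incidence()].
#' @param a,b column labels or indices, `a != b`.
#' @return one-row data.frame (class `assoc_edge`): `cis_a`, `cis_b`,
#'   `n11`, `n10`, `n01`, `n00`, `p_cooccur`, `p_exclusive`, `direction`
#'   (`"co-occurring"` / `"mutually-exclusive"` / `NA`), `p_value`,
#'   `testable`.
#' @export
test_pair <- function(matrix, a, b) {
  pa <- matrix[, a] > 0
  pb <- matrix[, b] > 0
  if (identical(a, b)) stop_ims("a and b must differ")
  n11 <- sum(pa & pb); n10 <- sum(pa & !pb)
  n01 <- sum(!pa & pb); n00 <- sum(!pa & !pb)
  tab <- base::matrix(c(n11, n01, n10, n00), nrow = 2)
  degenerate <- sum(pa) %in% c(0L, length(pa)) || sum(pb) %in% c(0L, length(pb))
  if (degenerate) {
    p_co <- NA_real_; p_ex <- NA_real_; dir <- NA_character_; p <- NA_real_
  } else {
    p_co <- fisher.test(tab, alternative = "greater")$p.value
    p_ex <- fisher.test(tab, alternative = "less")$p.value
    if (p_co <= p_ex) {
      dir <- "co-occurring"; p <- p_co
    } else {
      dir <- "mutually-exclusive"; p <- p_ex
    }
  }
  lab <- function(z) if (is.character(z)) z else colnames(matrix)[z]
  structure(data.frame(cis_a = lab(a), cis_b = lab(b), n11 = n11, n10 = n10,
                       n01 = n01, n00 = n00, p_cooccur = p_co,
                       p_exclusive = p_ex, direction = dir, p_value = p,
                       testable = !degenerate, stringsAsFactors = FALSE),
            class = c("assoc_edge", "data.frame"))
}

#' Co-occurrence / mutual-exclusivity network over all CIS pairs
#'
#' Tests every unordered CIS pair with [test_pair()], pools the two
#' one-sided p-value families (enrichment and depletion) of all testable
#' pairs, applies Benjamini-Hochberg correction across the pooled set, and
#' keeps edges whose better direction reaches `q <= alpha`. Edge weight is
#' `-log10(q)`. Pairs with degenerate margins are excluded before
#' correction.
#'
#' @param matrix incidence matrix.
#' @param alpha FDR level for retained edges.
#' @param correction multiple-testing method (only `"BH"` and `"none"`).
#' @return list of class `assoc_network`: `edges` (significant, with `q`),
#'   `tests` (all testable pairs with both q-values), `n_pairs`,
#'   `untestable` (labels of degenerate pairs).
#' @export
build_network <- function(matrix, alpha = 0.05, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  labels <- colnames(matrix)
  if (length(labels) < 2L) stop_ims("need >= 2 CISs to build a network")
  pairs <- utils::combn(labels, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    test_pair(matrix, pairs[1L, i], pairs[2L, i])
  }))
  untestable <- tests[!tests$testable, c("cis_a", "cis_b")]
  tt <- tests[tests$testable, , drop = FALSE]
  if (nrow(tt)) {
    pooled <- c(tt$p_cooccur, tt$p_exclusive)
    qq <- if (correction == "BH") p.adjust(pooled, "BH") else pooled
    tt$q_cooccur <- qq[seq_len(nrow(tt))]
    tt$q_exclusive <- qq[nrow(tt) + seq_len(nrow(tt))]
    tt$q_value <- ifelse(tt$direction == "co-occurring",
                         tt$q_cooccur, tt$q_exclusive)
  } else {
    tt$q_cooccur <- tt$q_exclusive <- tt$q_value <- numeric(0)
  }
  edges <- tt[!is.na(tt$q_value) & tt$q_value <= alpha, , drop = FALSE]
  if (nrow(edges)) edges$weight <- -log10(edges$q_value)
  rownames(tt) <- rownames(edges) <- NULL
  structure(list(edges = edges, tests = tt, n_pairs = ncol(pairs),
                 untestable = untestable, alpha = alpha,
                 correction = correction),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("CIS association network: %d pairs tested, %d significant edge(s) at q <= %g\n",
              x$n_pairs, nrow(x$edges), x$alpha))
  if (nrow(x$edges)) {
    print.data.frame(x$edges[, c("cis_a", "cis_b", "direction", "n11",
                                 "n10", "n01", "n00", "q_value")])
  }
  invisible(x)
}

#' Within-family mutual-exclusivity summary
#'
#' For each gene family: the number of tumors hitting at least one member,
#' the number hitting two or more members, and a permutation p-value for
#' exclusivity. The null shuffles each member's presence column
#' independently (preserving marginal frequencies) and asks whether the
#' observed multi-member overlap is lower than expected; p is the add-one
#' permutation estimate of `P(overlap_null <= overlap_obs)`.
#'
#' @param matrix incidence matrix.
#' @param families named list mapping family name to member column labels.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame: `family`, `n_members`, `n_any`, `n_multi`,
#'   `expected_multi`, `p_value` (NA with `testable = FALSE` for
#'   single-member families).
#' @export
family_pattern <- function(matrix, families, n_perm = 1000, seed = 1L) {
  set.seed(seed, kind = "Mersenne-Twister")
  n <- nrow(matrix)
  rows <- lapply(names(families), function(fam) {
    members <- intersect(families[[fam]], colnames(matrix))
    if (length(members) < 2L) {
      return(data.frame(family = fam, n_members = length(members),
                        n_any = if (length(members)) sum(matrix[, members] > 0) else 0L,
                        n_multi = NA_integer_, expected_multi = NA_real_,
                        p_value = NA_real_, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    pres <- matrix[, members, drop = FALSE] > 0
    hits <- rowSums(pres)
    obs <- sum(hits >= 2L)
    null_multi <- vapply(seq_len(n_perm), function(i) {
      perm <- vapply(seq_len(ncol(pres)),
                     function(j) pres[sample.int(n), j], logical(n))
      sum(rowSums(perm) >= 2L)
    }, numeric(1))
    data.frame(family = fam, n_members = length(members),
               n_any = sum(hits >= 1L), n_multi = obs,
               expected_multi = mean(null_multi),
               p_value = (1 + sum(null_multi <= obs)) / (n_perm + 1),
               testable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-CIS association with genotype or strain
#'
#' For a chosen pair of cohort arms (e.g. wild-type vs mutant within one
#' strain), each CIS is tested for differential presence with a two-sided
#' Fisher exact test on the 2x2 stratum-by-presence table, with BH
#' correction across CISs.
#'
#' @param matrix incidence matrix.
#' @param tumors tumor metadata (`tumor_id`, `strain`, `genotype`).
#' @param stratum_key `"genotype"` or `"strain"`.
#' @param levels optional length-2 character vector selecting the two arms
#'   to compare (default: the two most frequent levels).
#' @return data.frame: `cis`, counts per arm, `p_value`, `q_value`.
#' @export
genotype_association <- function(matrix, tumors, stratum_key = c("genotype", "strain"),
                                 levels = NULL) {
  stratum_key <- match.arg(stratum_key)
  assert_columns(tumors, c("tumor_id", stratum_key), "tumors")
  lab <- tumors[[stratum_key]][match(rownames(matrix), tumors$tumor_id)]
  if (is.null(levels)) {
    levels <- names(sort(table(lab), decreasing = TRUE))[1:2]
  }
  if (length(unique(levels)) < 2L || !all(levels %in% lab)) {
    stop_ims("stratum must have two represented levels to compare")
  }
  sel <- lab %in% levels
  m <- matrix[sel, , drop = FALSE]
  g <- factor(lab[sel], levels = levels)
  rows <- lapply(colnames(m), function(cc) {
    pres <- m[, cc] > 0
    tab <- table(g, factor(pres, levels = c(TRUE, FALSE)))
    p <- fisher.test(tab)$p.value
    data.frame(cis = cc,
               n_present_a = sum(pres & g == levels[1L]),
               n_a = sum(g == levels[1L]),
               n_present_b = sum(pres & g == levels[2L]),
               n_b = sum(g == levels[2L]),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, "BH")
  attr(out, "levels") <- levels
  attr(out, "stratum_key") <- stratum_key
  out
}

#' Write the incidence matrix / network edge list
#'
#' The incidence TSV has tumors as rows, CIS labels as columns and
#' clonality scores as entries (0 = absent). The edge list TSV carries one
#' row per significant edge; `write_network_graphml` exports the same graph
#' for network viewers.
#'
#' @param matrix incidence matrix.
#' @param network `assoc_network` from [build_network()].
#' @param path output path.
#' @export
write_incidence <- function(matrix, path) {
  df <- data.frame(tumor_id = rownames(matrix),
                   as.data.frame(unclass(matrix)[seq_len(nrow(matrix)), ,
                                                 drop = FALSE]),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence
#' @export
read_incidence <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$tumor_id
  class(m) <- c("ims_incidence", class(m))
  m
}

#' @rdname write_incidence
#' @export
write_network_edges <- function(network, path) {
  cols <- c("cis_a", "cis_b", "direction", "n11", "n10", "n01", "n00",
            "p_value", "q_value")
  write.table(network$edges[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence
#' @export
write_network_graphml <- function(network, path) {
  e <- network$edges
  if (nrow(e) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("cis_a", "cis_b", "direction", "q_value", "weight")],
      directed = FALSE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
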