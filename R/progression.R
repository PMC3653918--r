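#' Group CISs into gene families
#'
#' Pools member CISs into named families; CISs not covered by the family
#' map become singleton groups named after themselves. Groups affected in
#' fewer than `min_tumors` distinct tumors are dropped (the default of 10
#' keeps the comparison to well-supported groups). A tumor hitting two
#' members of one family counts once.
#'
#' @param matrix incidence matrix ([build_incidence()]).
#' @param family_map named list: family name -> member CIS labels. A label
#'   assigned to two families is a configuration error.
#' @param min_tumors minimum distinct-tumor support (>= 1, default 10).
#' @return list of class `cis_groups`: `groups` (named list of member
#'   labels), `n_tumors` (named vector), `dropped` (group names below
#'   threshold).
#' @export
group_cis <- function(matrix, family_map = list(), min_tumors = 10) {
  if (min_tumors < 1) stop_ims("min_tumors must be >= 1")
  members <- unlist(family_map, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop_ims("a CIS is assigned to two families: ",
             paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  family_map <- lapply(family_map, intersect, colnames(matrix))
  family_map <- family_map[vapply(family_map, length, 1L) > 0L]
  singles <- setdiff(colnames(matrix), unlist(family_map))
  groups <- c(family_map, setNames(as.list(singles), singles))
  n_tum <- vapply(groups, function(mm) {
    sum(rowSums(matrix[, mm, drop = FALSE] > 0) >= 1L)
  }, numeric(1))
  keep <- n_tum >= min_tumors
  structure(list(groups = groups[keep], n_tumors = n_tum[keep],
                 dropped = names(groups)[!keep], min_tumors = min_tumors),
            class = "cis_groups")
}

#' @export
print.cis_groups <- function(x, ...) {
  cat(sprintf("%d CIS group(s) with >= %d tumors (%d dropped)\n",
              length(x$groups), x$min_tumors, length(x$dropped)))
  for (g in names(x$groups)) {
    cat(sprintf("  %-10s n_tumors=%3d  members: %s\n", g, x$n_tumors[g],
                paste(x$groups[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Per-tumor clonality scores of CIS groups
#'
#' The clonality score of a tumor in a group is the maximum LP count over
#' the tumor's insertions in any member CIS (`method = "max"`), or the sum
#' over members (`method = "sum"`). Zero means the group is absent from
#' the tumor. LP scores are only ever compared within a tumor, never
#' across tumors.
#'
#' @param matrix incidence matrix.
#' @param groups `cis_groups` from [group_cis()].
#' @param method aggregation over member CISs.
#' @return numeric matrix, tumors x groups.
#' @export
clonality_scores <- function(matrix, groups, method = c("max", "sum")) {
  method <- match.arg(method)
  f <- if (method == "max") function(r) max(r) else function(r) sum(r)
  out <- vapply(groups$groups, function(mm) {
    apply(matrix[, mm, drop = FALSE], 1L, f)
  }, numeric(nrow(matrix)))
  rownames(out) <- rownames(matrix)
  out
}

#' Compare the clonality of two CIS groups across co-mutated tumors
#'
#' Over tumors carrying insertions in both groups, counts how often group
#' `a` has the higher clonality score (`wins_a`), how often `b` does
#' (`wins_b`), and the ties; ties are excluded from the test. The p-value
#' is the exact two-sided binomial probability of a split at least as
#' uneven under the null that either group is equally likely to be the
#' more clonal one: `p = min(1, 2 * P(X >= max(wins)))` with
#' `X ~ Binomial(wins_a + wins_b, 1/2)`. Symmetric in its arguments. With
#' no informative tumor the comparison is untestable (`p = NA`).
#'
#' @param scores tumors x groups score matrix ([clonality_scores()]).
#' @param a,b group names.
#' @param two_sided if `FALSE`, the one-sided tail toward the observed
#'   winner is reported instead.
#' @return one-row data.frame: `group_a`, `group_b`, `wins_a`, `wins_b`,
#'   `ties`, `n_informative`, `p_value`.
#' @examples
#' s <- cbind(early = c(40, 35, 20, 0), late = c(12, 9, 30, 5))
#' rownames(s) <- paste0("T", 1:4)
#' compare_groups(s, "early", "late")
#' @export
compare_groups <- function(scores, a, b, two_sided = TRUE) {
  if (!all(c(a, b) %in% colnames(scores))) {
    stop_ims("unknown group: ", paste(setdiff(c(a, b), colnames(scores)),
                                      collapse = ", "))
  }
  if (identical(a, b)) stop_ims("a and b must differ")
  both <- scores[, a] > 0 & scores[, b] > 0
  sa <- scores[both, a]; sb <- scores[both, b]
  wins_a <- sum(sa > sb); wins_b <- sum(sa < sb); ties <- sum(sa == sb)
  n <- wins_a + wins_b
  p <- if (n == 0L) NA_real_ else {
    tail <- pbinom(max(wins_a, wins_b) - 1L, n, 0.5, lower.tail = FALSE)
    if (two_sided) min(1, 2 * tail) else tail
  }
  data.frame(group_a = a, group_b = b, wins_a = wins_a, wins_b = wins_b,
             ties = ties, n_informative = n, p_value = p,
             stringsAsFactors = FALSE)
}

#' All pairwise clonality comparisons
#'
#' @param scores tumors x groups score matrix.
#' @param two_sided see [compare_groups()].
#' @return data.frame with one row per unordered group pair.
#' @export
compare_all_groups <- function(scores, two_sided = TRUE) {
  gs <- colnames(scores)
  if (length(gs) < 2L) stop_ims("need >= 2 groups")
  pairs <- utils::combn(gs, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    compare_groups(scores, pairs[1L, i], pairs[2L, i], two_sided = two_sided)
  }))
  rownames(out) <- NULL
  out
}

#' Directed progression graph from clonality comparisons
#'
#' Comparisons reaching `p <= alpha` become directed edges from the group
#' that was more clonal more often (the putative earlier event) to the
#' other; the edge label `"wins_parent/wins_child"` reports the split and
#' the weight is `-log10(p)`. Untestable pairs are omitted. Acyclicity of
#' the resulting graph is checked and reported, not enforced. No multiple
#' testing correction is applied by default (set `correction = "BH"` to
#' filter on BH-adjusted p-values instead).
#'
#' @param comparisons data.frame from [compare_all_groups()].
#' @param alpha significance threshold (default 0.05).
#' @param correction `"none"` (default) or `"BH"`.
#' @return list of class `progression_graph`: `edges` (with `parent`,
#'   `child`, `label`, `p_value`, `weight`), `comparisons`, `acyclic`.
#' @export
progression_graph <- function(comparisons, alpha = 0.05,
                              correction = c("none", "BH")) {
  correction <- match.arg(correction)
  cmp <- comparisons[!is.na(comparisons$p_value), , drop = FALSE]
  crit <- if (correction == "BH") p.adjust(cmp$p_value, "BH") else cmp$p_value
  sig <- cmp[crit <= alpha & cmp$wins_a != cmp$wins_b, , drop = FALSE]
  if (nrow(sig)) {
    a_wins <- sig$wins_a > sig$wins_b
    edges <- data.frame(
      parent = ifelse(a_wins, sig$group_a, sig$group_b),
      child = ifelse(a_wins, sig$group_b, sig$group_a),
      wins_parent = pmax(sig$wins_a, sig$wins_b),
      wins_child = pmin(sig$wins_a, sig$wins_b),
      ties = sig$ties, p_value = sig$p_value,
      weight = -log10(sig$p_value), stringsAsFactors = FALSE)
    edges$label <- sprintf("%d/%d", edges$wins_parent, edges$wins_child)
    g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                       directed = TRUE)
    acyclic <- igraph::is_dag(g)
  } else {
    edges <- data.frame(parent = character(0), child = character(0),
                        wins_parent = integer(0), wins_child = integer(0),
                        ties = integer(0), p_value = numeric(0),
                        weight = numeric(0), label = character(0))
    acyclic <- TRUE
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, comparisons = comparisons, alpha = alpha,
                 correction = correction, acyclic = acyclic),
            class = "progression_graph")
}

#' @export
print.progression_graph <- function(x, ...) {
  cat(sprintf("Progression graph: %d edge(s) at p <= %g (%s)\n",
              nrow(x$edges), x$alpha,
              if (x$acyclic) "acyclic" else "contains cycles"))
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -> %s  %s  p=%.3g\n", x$edges$parent[i],
                  x$edges$child[i], x$edges$label[i], x$edges$p_value[i]))
    }
  }
  invisible(x)
}

#' Write progression outputs
#'
#' `write_comparisons` writes the full pairwise comparison table as TSV;
#' `write_progression_graphml` exports the directed graph with the
#' `"wins_parent/wins_child"` fraction labels.
#'
#' @param comparisons data.frame from [compare_all_groups()].
#' @param graph `progression_graph`.
#' @param path output path.
#' @export
write_comparisons <- function(comparisons, path) {
  write.table(comparisons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparisons
#' @export
write_progression_edges <- function(graph, path) {
  write.table(graph$edges[, c("parent", "child", "label", "wins_parent",
                              "wins_child", "ties", "p_value", "weight")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparisons
#' @export
write_progression_graphml <- function(graph, path) {
  e <- graph$edges
  if (nrow(e) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("parent", "child", "label", "p_value", "weight")],
      directed = TRUE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
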