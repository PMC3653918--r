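#' Call insertions from junction fragments
#'
#' Fragments from the same tumor, chromosome and proviral orientation whose
#' junction positions lie within `merge_window` bp of each other (single
#' linkage on sorted positions) are clustered into one insertion. For each
#' insertion the LP count is the number of distinct ligation points in the
#' cluster -- the clonality proxy: an insertion with n unique LPs was present
#' in at least n independent cells -- and the read count is the cluster size.
#' The representative position is the most frequent junction coordinate in
#' the cluster (ties broken toward the smallest coordinate).
#'
#' The result is invariant to the order of the input fragments, and the
#' read counts over all called insertions sum to the number of input
#' fragments.
#'
#' @param fragments fragment data.frame (see [read_fragments()]).
#' @param merge_window maximum junction-position gap, in bp, joining two
#'   fragments into one insertion cluster. Default 5 bp absorbs mapping
#'   jitter; 0 requires exact coordinates.
#' @return data.frame with columns `tumor_id`, `chrom`, `position`,
#'   `orientation`, `lp_count`, `read_count`, sorted by tumor, chromosome
#'   and position.
#' @examples
#' fr <- data.frame(tumor_id = "T1", chrom = "chr1", position = 1000,
#'                  ligation_point = c(1500, 1500, 1812), orientation = "+")
#' call_insertions(fr)  # one insertion: lp_count 2, read_count 3
#' @export
call_insertions <- function(fragments, merge_window = 5) {
  if (merge_window < 0) stop_ims("merge_window must be >= 0")
  if (nrow(fragments) == 0L) {
    return(data.frame(tumor_id = character(0), chrom = character(0),
                      position = numeric(0), orientation = character(0),
                      lp_count = integer(0), read_count = integer(0)))
  }
  validate_fragments(fragments)
  o <- order(fragments$tumor_id, fragments$chrom, fragments$orientation,
             fragments$position, fragments$ligation_point)
  f <- fragments[o, ]
  key <- paste(f$tumor_id, f$chrom, f$orientation, sep = "\r")
  new_key <- c(TRUE, key[-1L] != key[-length(key)])
  gap <- c(Inf, diff(f$position))
  cluster <- cumsum(new_key | gap > merge_window)

  read_count <- as.integer(tabulate(cluster))
  lp_new <- !duplicated(cbind(cluster, f$ligation_point))
  lp_count <- as.integer(rowsum(as.integer(lp_new), cluster))

  # representative position: mode, ties -> smallest coordinate
  pos_tab <- aggregate(list(n = cluster),
                       by = list(cluster = cluster, position = f$position),
                       FUN = length)
  pos_tab <- pos_tab[order(pos_tab$cluster, -pos_tab$n, pos_tab$position), ]
  rep_pos <- pos_tab$position[!duplicated(pos_tab$cluster)]

  first <- !duplicated(cluster)
  out <- data.frame(tumor_id = f$tumor_id[first], chrom = f$chrom[first],
                    position = rep_pos, orientation = f$orientation[first],
                    lp_count = lp_count, read_count = read_count,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tumor_id, out$chrom, out$position, out$orientation), ]
  rownames(out) <- NULL
  out
}

#' Drop single-LP insertions (background filter)
#'
#' Insertions supported by a single ligation point are indistinguishable
#' from insertions present in one cell and are treated as background: only
#' records with `lp_count >= 2` are retained. Tumors whose insertions are
#' all single-LP drop out of the cohort entirely; their ids are recorded in
#' the `dropped_tumors` attribute of the result for the run report.
#'
#' @param insertions called insertions ([call_insertions()]).
#' @return filtered data.frame; attribute `dropped_tumors` lists tumor ids
#'   left with zero insertions.
#' @export
filter_single_lp <- function(insertions) {
  assert_columns(insertions, c("tumor_id", "lp_count"), "insertions")
  keep <- insertions$lp_count >= 2L
  out <- insertions[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_tumors") <-
    setdiff(unique(insertions$tumor_id), unique(out$tumor_id))
  out
}

#' Summarize the effect of insertion filtering
#'
#' Compares a cohort before and after filtering. Percent reductions are
#' `100 * (1 - after/before)`, reported both exactly and truncated to whole
#' percent (the convention for headline figures: a 78.65% site reduction is
#' reported as 78%). Read reductions use the summed `read_count`.
#'
#' @param after post-filter insertions.
#' @param before pre-filter insertions.
#' @return list of class `cohort_summary`: site/read/tumor counts before and
#'   after, exact reduction percentages (`site_reduction`,
#'   `read_reduction`), truncated integer percentages
#'   (`site_reduction_pct`, `read_reduction_pct`; `NA` when the
#'   denominator is empty), and `dropped_tumors`.
#' @examples
#' before <- data.frame(tumor_id = "T1", chrom = "chr1", position = 1:4,
#'                      orientation = "+", lp_count = c(1, 1, 2, 5),
#'                      read_count = c(1, 1, 3, 6))
#' cohort_summary(filter_single_lp(before), before)
#' @export
cohort_summary <- function(after, before) {
  assert_columns(after, c("tumor_id", "lp_count", "read_count"), "after")
  assert_columns(before, c("tumor_id", "lp_count", "read_count"), "before")
  n_before <- nrow(before); n_after <- nrow(after)
  r_before <- sum(before$read_count); r_after <- sum(after$read_count)
  site_red <- if (n_before > 0) 100 * (1 - n_after / n_before) else NA_real_
  read_red <- if (r_before > 0) 100 * (1 - r_after / r_before) else NA_real_
  structure(list(
    sites_before = n_before, sites_after = n_after,
    reads_before = r_before, reads_after = r_after,
    tumors_before = length(unique(before$tumor_id)),
    tumors_after = length(unique(after$tumor_id)),
    site_reduction = site_red, read_reduction = read_red,
    # small epsilon so exact-integer reductions survive floating point
    site_reduction_pct = if (is.na(site_red)) NA_integer_ else
      as.integer(floor(site_red + 1e-9)),
    read_reduction_pct = if (is.na(read_red)) NA_integer_ else
      as.integer(floor(read_red + 1e-9)),
    dropped_tumors = attr(after, "dropped_tumors") %||% character(0)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Insertion filtering summary\n")
  cat(sprintf("  sites: %d -> %d (%s%% reduction)\n", x$sites_before,
              x$sites_after,
              if (is.na(x$site_reduction_pct)) "NA" else x$site_reduction_pct))
  cat(sprintf("  reads: %d -> %d (%s%% reduction)\n", x$reads_before,
              x$reads_after,
              if (is.na(x$read_reduction_pct)) "NA" else x$read_reduction_pct))
  cat(sprintf("  tumors: %d -> %d", x$tumors_before, x$tumors_after))
  if (length(x$dropped_tumors)) {
    cat(sprintf(" (%d dropped: only single-LP insertions)",
                length(x$dropped_tumors)))
  }
  cat("\n")
  invisible(x)
}

#' Optional cross-contamination filter for pooled sequencing runs
#'
#' Identical `(chrom, position, ligation_point)` fragment triples observed
#' in more than one tumor of the same sequencing pool are almost certainly
#' barcode bleed-through; for each such triple only the tumor with the most
#' supporting reads keeps the fragments. This is an extension beyond the
#' single-LP filter and is off by default in [run_pipeline()].
#'
#' @param fragments fragment data.frame.
#' @param pools named vector mapping `tumor_id` to pool id; if `NULL` all
#'   tumors are treated as one pool.
#' @return filtered fragment data.frame.
#' @export
filter_cross_contamination <- function(fragments, pools = NULL) {
  validate_fragments(fragments)
  if (nrow(fragments) == 0L) return(fragments)
  pool <- if (is.null(pools)) rep("pool1", nrow(fragments)) else {
    p <- pools[fragments$tumor_id]
    if (anyNA(p)) stop_ims("pools must cover every tumor_id")
    as.character(p)
  }
  triple <- paste(pool, fragments$chrom, fragments$position,
                  fragments$ligation_point, sep = "\r")
  keep <- rep(TRUE, nrow(fragments))
  # for triples seen in >1 tumor keep only the best-supported tumor
  tt <- unique(data.frame(triple = triple, tumor = fragments$tumor_id,
                          stringsAsFactors = FALSE))
  multi <- names(which(table(tt$triple) > 1L))
  for (tr in multi) {
    tums <- tt$tumor[tt$triple == tr]
    support <- vapply(tums, function(tu)
      sum(fragments$tumor_id == tu & triple == tr), numeric(1))
    best <- tums[which.max(support)]
    keep[triple == tr & fragments$tumor_id != best] <- FALSE
  }
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
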