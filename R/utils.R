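# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ims <- function(...) stop(..., call. = FALSE)

# Truncating integer percentage: 100 * (1 - after/before) floored, the
# convention used for the screen's headline reduction figures.
pct_floor <- function(x) floor(100 * x)

# Standard half-up rounding used for coverage-style percentages.
pct_round <- function(x, digits = 0) round(100 * x, digits)

# Deterministic child seed derived from a user seed; kept well below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 100000L
}

# Merge possibly-overlapping 1-based inclusive intervals given as a
# data.frame with columns start, end (single chromosome). Returns a
# data.frame of merged intervals plus the indices of members per merge.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(list(start = numeric(0), end = numeric(0), members = list()))
  }
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  grp <- integer(length(s))
  grp[1L] <- 1L
  cur_end <- e[1L]
  g <- 1L
  if (length(s) > 1L) {
    for (i in 2L:length(s)) {
      if (s[i] <= cur_end) {        # touching/overlapping (inclusive coords)
        cur_end <- max(cur_end, e[i])
      } else {
        g <- g + 1L
        cur_end <- e[i]
      }
      grp[i] <- g
    }
  }
  list(
    start = as.numeric(tapply(s, grp, min)),
    end = as.numeric(tapply(e, grp, max)),
    members = split(o, grp)
  )
}

# Row indices of points (chrom, pos) falling inside interval
# [start, end] on `chrom` (1-based inclusive).
points_in_interval <- function(point_chrom, point_pos, chrom, start, end) {
  which(point_chrom == chrom & point_pos >= start & point_pos <= end)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_ims(sprintf("%s is missing column(s): %s", what,
                     paste(missing, collapse = ", ")))
  }
  invisible(df)
}
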