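#' Kernel scale for CIS detection
#'
#' `h` is the Gaussian kernel width (standard deviation) in bp and
#' `grid_step` the spacing of the evaluation grid; the grid must sample at
#' least as finely as the kernel width so peaks are resolved.
#'
#' @param h kernel width in bp (> 0).
#' @param grid_step evaluation spacing in bp; default `h / 10`, resolving
#'   peak positions to within 5% of `h`.
#' @return list of class `kernel_scale`.
#' @export
kernel_scale <- function(h, grid_step = h / 10) {
  if (!is.finite(h) || h <= 0) stop_ims("kernel width h must be > 0")
  if (!is.finite(grid_step) || grid_step <= 0 || grid_step > h) {
    stop_ims("grid_step must be in (0, h]")
  }
  structure(list(h = h, grid_step = grid_step), class = "kernel_scale")
}

as_kernel_scales <- function(scales) {
  if (inherits(scales, "kernel_scale")) return(list(scales))
  if (is.numeric(scales)) return(lapply(scales, kernel_scale))
  if (is.list(scales) && all(vapply(scales, inherits, TRUE, "kernel_scale"))) {
    return(scales)
  }
  stop_ims("scales must be numeric widths or kernel_scale objects")
}

#' Smoothed insertion density along a chromosome
#'
#' Convolves insertion coordinates with an unnormalized Gaussian kernel:
#' the density at grid point g is `sum_i exp(-(g - x_i)^2 / (2 h^2))` over
#' insertions within `4h` of g (contributions beyond `4h` are zero by
#' definition). An isolated insertion therefore contributes exactly 1.0 at
#' its own coordinate, and k coincident insertions give a peak of exactly k.
#' The grid is `1, 1 + grid_step, ...` up to the chromosome length.
#'
#' @param positions insertion coordinates in `[1, chrom_length]`.
#' @param scale a [kernel_scale()] (or numeric kernel width).
#' @param chrom_length chromosome length in bp.
#' @param chrom optional chromosome name carried in the result.
#' @return list of class `density_track`: `chrom`, `grid`, `density`, `h`,
#'   `grid_step`.
#' @examples
#' tr <- kernel_density(5000, kernel_scale(1000), 10000)
#' tr$density[tr$grid == 5000]  # exactly 1
#' @export
kernel_density <- function(positions, scale, chrom_length, chrom = NA_character_) {
  scale <- as_kernel_scales(scale)[[1L]]
  positions <- as.numeric(positions)
  if (any(positions < 1 | positions > chrom_length)) {
    stop_ims("insertion positions must lie within [1, chrom_length]")
  }
  dens <- .cpp_gkc_track(positions, scale$h, scale$grid_step, chrom_length)
  grid <- 1 + (seq_along(dens) - 1) * scale$grid_step
  structure(list(chrom = chrom, grid = grid, density = dens,
                 h = scale$h, grid_step = scale$grid_step),
            class = "density_track")
}

#' Permutation-calibrated peak significance threshold
#'
#' Null model: the observed number of insertions is placed uniformly on the
#' chromosome (on the evaluation grid, so a single null insertion peaks at
#' exactly 1.0); the maximum of the kernel density track is recorded for each
#' of `n_perm` permutations, and the threshold is the empirical
#' `1 - alpha` quantile of that max-peak distribution. Density peaks above
#' the threshold are then significant with per-chromosome (and per-scale)
#' family-wise error alpha. Deterministic given `seed`.
#'
#' @param n number of insertions on the chromosome (>= 1).
#' @param chrom_length chromosome length in bp.
#' @param scale a [kernel_scale()] or numeric width.
#' @param alpha FWER level in (0, 1).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return the threshold (numeric scalar) with the permutation maxima in
#'   attribute `max_peaks`.
#' @export
null_peak_threshold <- function(n, chrom_length, scale, alpha = 0.05,
                                n_perm = 1000, seed = 1L) {
  scale <- as_kernel_scales(scale)[[1L]]
  if (n < 1) stop_ims("n must be >= 1")
  if (n_perm < 100) stop_ims("n_perm must be >= 100")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_ims("alpha must be in (0, 1)")
  }
  set.seed(seed, kind = "Mersenne-Twister")
  peaks <- .cpp_gkc_null_max_peaks(as.integer(n), chrom_length, scale$h,
                                   scale$grid_step, as.integer(n_perm))
  thr <- as.numeric(quantile(peaks, probs = 1 - alpha, type = 1, names = FALSE))
  attr(thr, "max_peaks") <- peaks
  thr
}

#' Detect common insertion sites by multi-scale kernel convolution
#'
#' For every chromosome and kernel scale, insertion coordinates (pooled
#' across tumors and orientations, one kernel per insertion record) are
#' smoothed with [kernel_density()] and compared against the
#' permutation-calibrated threshold of [null_peak_threshold()] computed for
#' that chromosome's insertion count. Contiguous grid runs with density
#' strictly above the threshold become candidate regions whose boundaries
#' are the outermost grid points above threshold and whose peak is the
#' density argmax (ties toward the smallest coordinate). Candidate regions
#' from different scales that overlap are merged into one CIS spanning
#' their union; the reported peak, scale and threshold come from the
#' smallest contributing kernel width. Tumor support (`n_tumors`) counts
#' distinct tumors with at least one insertion inside `[start, end]`.
#'
#' @param insertions post-filter insertion data.frame (`tumor_id`, `chrom`,
#'   `position`; see [filter_single_lp()]).
#' @param genome [genome_layout()] giving chromosome lengths.
#' @param scales kernel widths in bp or list of [kernel_scale()]; default
#'   10 kb / 30 kb / 100 kb, spanning the observed width range of common
#'   insertion sites.
#' @param alpha per-chromosome, per-scale FWER level.
#' @param n_perm permutations per threshold.
#' @param seed integer seed; per-chromosome/scale thresholds use child
#'   seeds derived from it.
#' @param thresholds optional precomputed thresholds, a data.frame with
#'   columns `chrom`, `h`, `threshold` (e.g. to share a null across
#'   replicate analyses with identical insertion counts); missing
#'   combinations are computed.
#' @return data.frame of class `cis_set` with columns `cis_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), `peak`, `scale`, `threshold`,
#'   `n_insertions`, `n_tumors`, `target`.
#' @export
detect_cis <- function(insertions, genome, scales = c(10e3, 30e3, 100e3),
                       alpha = 0.05, n_perm = 1000, seed = 1L,
                       thresholds = NULL) {
  scales <- as_kernel_scales(scales)
  empty <- data.frame(cis_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      peak = numeric(0), scale = numeric(0),
                      threshold = numeric(0), n_insertions = integer(0),
                      n_tumors = integer(0), target = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cis_set", "data.frame")
  if (nrow(insertions) == 0L) return(empty)
  assert_columns(insertions, c("tumor_id", "chrom", "position"), "insertions")

  cand <- list()
  chroms <- intersect(genome$chrom, unique(insertions$chrom))
  k <- 0L
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    len <- chrom_len(genome, chrom)
    pos <- insertions$position[insertions$chrom == chrom]
    for (si in seq_along(scales)) {
      sc <- scales[[si]]
      thr <- NULL
      if (!is.null(thresholds)) {
        hit <- which(thresholds$chrom == chrom &
                     abs(thresholds$h - sc$h) < 1e-9)
        if (length(hit)) thr <- thresholds$threshold[hit[1L]]
      }
      if (is.null(thr)) {
        thr <- null_peak_threshold(length(pos), len, sc, alpha = alpha,
                                   n_perm = n_perm,
                                   seed = child_seed(seed, ci * 37L + si))
      }
      track <- kernel_density(pos, sc, len, chrom = chrom)
      above <- track$density > thr
      if (!any(above)) next
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        idx <- starts[j]:ends[j]
        pk <- idx[which.max(track$density[idx])]
        k <- k + 1L
        cand[[k]] <- data.frame(
          chrom = chrom, start = track$grid[starts[j]],
          end = track$grid[ends[j]], peak = track$grid[pk],
          scale = sc$h, threshold = as.numeric(thr),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty)
  cand <- do.call(rbind, cand)

  out <- list()
  for (chrom in unique(cand$chrom)) {
    cc <- cand[cand$chrom == chrom, , drop = FALSE]
    m <- merge_intervals(cc$start, cc$end)
    for (j in seq_along(m$start)) {
      members <- cc[m$members[[j]], , drop = FALSE]
      lead <- members[order(members$scale, members$peak), ][1L, ]
      inside <- points_in_interval(insertions$chrom, insertions$position,
                                   chrom, m$start[j], m$end[j])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = m$start[j], end = m$end[j],
        peak = lead$peak, scale = lead$scale, threshold = lead$threshold,
        n_insertions = length(inside),
        n_tumors = length(unique(insertions$tumor_id[inside])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(match(out$chrom, genome$chrom), out$start), ]
  out <- cbind(cis_id = sprintf("%s:%d-%d", out$chrom,
                                as.integer(out$start), as.integer(out$end)),
               out, target = NA_character_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cis_set", "data.frame")
  out
}

#' @export
print.cis_set <- function(x, ...) {
  cat(sprintf("%d common insertion site(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 20L))
  invisible(x)
}

#' Write / read a CIS table
#'
#' BED-like TSV with header: chrom, start, end (1-based inclusive), name
#' (target gene if assigned, else the CIS id), score (`n_tumors`), peak,
#' scale, threshold, n_insertions.
#'
#' @param cis a `cis_set` data.frame.
#' @param path file path.
#' @export
write_cis <- function(cis, path) {
  df <- data.frame(chrom = cis$chrom, start = cis$start, end = cis$end,
                   name = ifelse(is.na(cis$target), cis$cis_id, cis$target),
                   score = cis$n_tumors, peak = cis$peak, scale = cis$scale,
                   threshold = cis$threshold, n_insertions = cis$n_insertions)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cis
#' @export
read_cis <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("chrom", "start", "end", "name", "score", "peak",
                       "scale", "threshold", "n_insertions"), "CIS file")
  out <- data.frame(cis_id = sprintf("%s:%d-%d", df$chrom,
                                     as.integer(df$start), as.integer(df$end)),
                    chrom = df$chrom, start = df$start, end = df$end,
                    peak = df$peak, scale = df$scale,
                    threshold = df$threshold, n_insertions = df$n_insertions,
                    n_tumors = df$score,
                    target = ifelse(grepl(":", df$name), NA_character_, df$name),
                    stringsAsFactors = FALSE)
  class(out) <- c("cis_set", "data.frame")
  out
}
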