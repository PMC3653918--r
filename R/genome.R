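#' Define a genome layout
#'
#' A genome layout is the coordinate frame for the screen: a set of uniquely
#' named chromosomes with their lengths in base pairs. Real screens use the
#' reference assembly's chromosome sizes; synthetic screens use a scaled-down
#' stand-in.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length numeric vector of chromosome lengths in bp (all > 0).
#' @return An object of class `genome_layout`: a data.frame with columns
#'   `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(50e6, 30e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop_ims("chrom and length must have equal length")
  }
  if (base::length(chrom) == 0L) stop_ims("genome must have >= 1 chromosome")
  if (anyDuplicated(chrom)) stop_ims("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop_ims("all chromosome lengths must be positive")
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read / write chromosome sizes (UCSC chrom.sizes dialect)
#'
#' Two tab-separated columns, name and length, no header.
#'
#' @param path file path.
#' @return `read_chrom_sizes` returns a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_ims("chrom.sizes file must have two columns")
  genome_layout(df[[1L]], df[[2L]])
}

#' @rdname read_chrom_sizes
#' @param genome a [genome_layout()].
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_layout"))
  write.table(data.frame(genome$chrom, format(genome$length, scientific = FALSE,
                                              trim = TRUE)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_len <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop_ims("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$length[i]
}
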