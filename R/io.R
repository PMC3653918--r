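#' Read and write fragment-level junction records
#'
#' The fragment TSV dialect has a header line and the tab-separated columns
#' `tumor_id`, `chrom`, `position`, `ligation_point`, `orientation`
#' (`+`/`-`), with no quoting. `position` is the 1-based coordinate of the
#' virus-host junction; `ligation_point` is the 1-based coordinate where the
#' sheared fragment was ligated to the adapter. The round trip
#' write-then-read is lossless.
#'
#' @param fragments data.frame of fragment records.
#' @param path file path.
#' @return `read_fragments` returns the validated data.frame.
#' @export
write_fragments <- function(fragments, path) {
  validate_fragments(fragments)
  write.table(fragments[, fragment_cols()], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, fragment_cols(), "fragments file")
  df$tumor_id <- as.character(df$tumor_id)
  df$chrom <- as.character(df$chrom)
  df$orientation <- as.character(df$orientation)
  validate_fragments(df, path = path)
  df[, fragment_cols()]
}

fragment_cols <- function() {
  c("tumor_id", "chrom", "position", "ligation_point", "orientation")
}

# Schema check; `path` switches error messages to name the offending file
# line (data row + header).
validate_fragments <- function(df, path = NULL) {
  assert_columns(df, fragment_cols(), "fragments")
  bad <- which(!is.finite(df$position) | df$position < 1 |
               !is.finite(df$ligation_point) | df$ligation_point < 1 |
               df$ligation_point == df$position |
               !(df$orientation %in% c("+", "-")))
  if (length(bad)) {
    where <- if (is.null(path)) sprintf("row %d", bad[1L]) else
      sprintf("%s line %d", path, bad[1L] + 1L)
    stop_ims(sprintf(
      "malformed fragment record at %s: positions must be >= 1, ligation_point != position, orientation '+'/'-'",
      where))
  }
  invisible(df)
}

#' Read and write tumor metadata
#'
#' Tab-separated with header: `tumor_id`, `strain`, `genotype`.
#'
#' @param tumors metadata data.frame.
#' @param path file path.
#' @export
write_tumors <- function(tumors, path) {
  assert_columns(tumors, c("tumor_id", "strain", "genotype"), "tumor metadata")
  write.table(tumors[, c("tumor_id", "strain", "genotype")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tumors
#' @export
read_tumors <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("tumor_id", "strain", "genotype"), "tumor metadata file")
  df$tumor_id <- as.character(df$tumor_id)
  df
}

#' Read and write called insertions
#'
#' Tab-separated with header: `tumor_id`, `chrom`, `position`,
#' `orientation`, `lp_count`, `read_count`.
#'
#' @param insertions insertion data.frame (see [call_insertions()]).
#' @param path file path.
#' @export
write_insertions <- function(insertions, path) {
  assert_columns(insertions, insertion_cols(), "insertions")
  write.table(insertions[, insertion_cols()], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_insertions
#' @export
read_insertions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, insertion_cols(), "insertions file")
  df$tumor_id <- as.character(df$tumor_id)
  df$chrom <- as.character(df$chrom)
  df
}

insertion_cols <- function() {
  c("tumor_id", "chrom", "position", "orientation", "lp_count", "read_count")
}

#' Export insertions as BED6
#'
#' One single-base interval per insertion, 0-based half-open, with
#' `name = tumor_id`, `score = lp_count`, strand = orientation.
#'
#' @param insertions insertion data.frame.
#' @param path output path.
#' @export
write_insertions_bed <- function(insertions, path) {
  assert_columns(insertions, insertion_cols(), "insertions")
  bed <- data.frame(insertions$chrom,
                    format(insertions$position - 1, scientific = FALSE, trim = TRUE),
                    format(insertions$position, scientific = FALSE, trim = TRUE),
                    insertions$tumor_id, insertions$lp_count,
                    insertions$orientation)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
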