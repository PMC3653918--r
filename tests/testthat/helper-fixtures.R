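# Shared fixtures: all synthetic, built in code at test time.

tiny_genome <- function(n = 2, len = 50e6) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n))
}

# A small planted configuration: two 2-member families with a clear
# early -> late order plus one singleton.
tiny_loci <- function() {
  rbind(
    cis_locus("GeneA1", "chr1", 10e6, 5000, "FamA", 0.45),
    cis_locus("GeneA2", "chr1", 30e6, 5000, "FamA", 0.25),
    cis_locus("GeneB1", "chr2", 10e6, 5000, "FamB", 0.35),
    cis_locus("GeneB2", "chr2", 30e6, 5000, "FamB", 0.20),
    cis_locus("Solo1",  "chr2", 45e6, 5000, NA,     0.15))
}

tiny_config <- function(n_tumors = 80, background_rate = 10, seed = 42, ...) {
  sim_config(genome = tiny_genome(), loci = tiny_loci(),
             n_tumors = n_tumors, background_rate = background_rate,
             seed = seed, ...)
}

# Hand-built fragment table: one row per (tumor, position, ligation_point).
make_fragments <- function(tumor_id, chrom, position, ligation_point,
                           orientation = "+") {
  n <- max(length(tumor_id), length(position), length(ligation_point))
  if (length(position) == 0L) n <- 0L
  data.frame(tumor_id = rep_len2(tumor_id, n), chrom = rep_len2(chrom, n),
             position = rep_len2(position, n),
             ligation_point = rep_len2(ligation_point, n),
             orientation = rep_len2(orientation, n),
             stringsAsFactors = FALSE)
}

rep_len2 <- function(x, n) if (n == 0L) x[0] else rep(x, length.out = n)

# Insertion records without going through call_insertions().
make_insertions <- function(tumor_id, chrom, position, lp_count,
                            read_count = lp_count, orientation = "+") {
  data.frame(tumor_id = tumor_id, chrom = chrom, position = position,
             orientation = orientation, lp_count = lp_count,
             read_count = read_count, stringsAsFactors = FALSE)
}

# A cis_set from explicit intervals (bypassing detection).
make_cis <- function(chrom, start, end, target = NA_character_) {
  out <- data.frame(cis_id = sprintf("%s:%d-%d", chrom, as.integer(start),
                                     as.integer(end)),
                    chrom = chrom, start = start, end = end,
                    peak = (start + end) / 2, scale = 10e3, threshold = 0,
                    n_insertions = NA_integer_, n_tumors = NA_integer_,
                    target = target, stringsAsFactors = FALSE)
  class(out) <- c("cis_set", "data.frame")
  out
}

# Incidence matrix from a logical presence matrix; present cells get a
# clonality score of 2 unless scores are supplied.
make_incidence <- function(presence, scores = NULL) {
  m <- (presence > 0) * if (is.null(scores)) 2 else scores
  if (is.null(rownames(m))) rownames(m) <- sprintf("T%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("CIS%d", seq_len(ncol(m)))
  class(m) <- c("ims_incidence", class(m))
  m
}

# Brute-force GKC density: double loop with the same 4h truncation the
# kernel definition uses. Independent oracle for the vectorized track.
naive_gkc <- function(grid, positions, h) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (x in positions) {
      d <- grid[i] - x
      if (abs(d) <= 4 * h) s <- s + exp(-d^2 / (2 * h^2))
    }
    out[i] <- s
  }
  out
}

# Exact one-sided hypergeometric tail probabilities for a 2x2 table by
# full enumeration over the support; oracle for test_pair().
hyper_tails <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  ra <- n11 + n10          # tumors with CIS a
  ca <- n11 + n01          # tumors with CIS b
  ks <- max(0, ra + ca - n):min(ra, ca)
  pk <- vapply(ks, function(k) {
    exp(lchoose(ca, k) + lchoose(n - ca, ra - k) - lchoose(n, ra))
  }, numeric(1))
  list(greater = sum(pk[ks >= n11]), less = sum(pk[ks <= n11]))
}

# Exact two-sided equal-odds binomial p by direct enumeration.
binom_two_sided_oracle <- function(wins_a, wins_b) {
  n <- wins_a + wins_b
  k <- max(wins_a, wins_b)
  min(1, 2 * sum(choose(n, k:n)) / 2^n)
}
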