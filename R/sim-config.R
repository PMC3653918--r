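#' Specify a planted CIS locus
#'
#' A locus is a point on the genome around which insertions of selected
#' (driver) events are placed. `spread` is the standard deviation of the
#' Gaussian placement of insertion coordinates around `center`, so the bulk
#' of a locus's insertions fall within `center +/- 4 * spread` -- this
#' interval is recorded as the planted truth window. `hit_probability` is
#' the marginal per-tumor probability that the locus carries an insertion.
#' Loci sharing a non-empty `group` form a gene family; with family
#' exclusivity on, a tumor hits at most one member per family.
#'
#' @param name locus (gene) name, unique within a configuration.
#' @param chrom chromosome name.
#' @param center locus center in bp (1-based).
#' @param spread standard deviation of insertion placement, bp (> 0).
#' @param group family name; `NA` or `""` makes the locus its own
#'   singleton group.
#' @param hit_probability per-tumor hit probability in `[0, 1]`.
#' @return one-row data.frame.
#' @export
cis_locus <- function(name, chrom, center, spread, group = NA_character_,
                      hit_probability = 0.05) {
  if (!is.finite(spread) || spread <= 0) stop_ims("spread must be > 0")
  if (hit_probability < 0 || hit_probability > 1) {
    stop_ims("hit_probability must be in [0, 1]")
  }
  if (is.na(group) || !nzchar(group)) group <- name
  data.frame(name = name, chrom = chrom, center = as.numeric(center),
             spread = as.numeric(spread), group = group,
             hit_probability = hit_probability, stringsAsFactors = FALSE)
}

#' Default planted loci of the synthetic mammary-tumor screen
#'
#' Thirty loci mirroring the frequency spectrum of a large MMTV screen:
#' five gene families (Wnt, Fgf, Fgfr, Rspo, Pdgfr) whose members span hot
#' (~45% of tumors) to rare (~1%) hit rates, plus thirteen singleton loci.
#' Hit probabilities are per-tumor marginals; spreads scale with the
#' empirical width of frequently-hit loci (wider footprint for hotter loci).
#'
#' @param genome a [genome_layout()]; loci are placed on its chromosomes.
#' @return data.frame of loci (see [cis_locus()]).
#' @export
default_loci <- function(genome = default_genome()) {
  L <- rbind(
    cis_locus("Wnt1",   "chr1", 20e6, 24000, "Wnt",   0.447),
    cis_locus("Wnt3a",  "chr1", 55e6, 21000, "Wnt",   0.139),
    cis_locus("Wnt3",   "chr1", 80e6, 27000, "Wnt",   0.098),
    cis_locus("Fgf3",   "chr2", 15e6, 25000, "Fgf",   0.323),
    cis_locus("Fgf8",   "chr2", 45e6, 32000, "Fgf",   0.224),
    cis_locus("Hbegf",  "chr2", 70e6, 11000, "Fgf",   0.025),
    cis_locus("Fgf10",  "chr2", 90e6,  4000, "Fgf",   0.008),
    cis_locus("Fgf6",   "chr6", 85e6,  2500, "Fgf",   0.007),
    cis_locus("Fgfr2",  "chr3", 12e6, 34000, "Fgfr",  0.084),
    cis_locus("Fgfr1",  "chr3", 40e6, 33000, "Fgfr",  0.050),
    cis_locus("Fgfr3",  "chr3", 75e6,  3000, "Fgfr",  0.008),
    cis_locus("Rspo2",  "chr4", 10e6, 22000, "Rspo",  0.079),
    cis_locus("Rspo3",  "chr4", 35e6, 19000, "Rspo",  0.041),
    cis_locus("Rspo1",  "chr4", 60e6,  5500, "Rspo",  0.010),
    cis_locus("Pdgfra", "chr5", 18e6, 11500, "Pdgfr", 0.023),
    cis_locus("Pdgfrb", "chr5", 48e6,  7000, "Pdgfr", 0.012),
    cis_locus("Map3k8", "chr5", 78e6, 15000, NA,      0.050),
    cis_locus("Irs4",   "chr6", 10e6, 18500, NA,      0.038),
    cis_locus("Igf2",   "chr6", 30e6, 14500, NA,      0.031),
    cis_locus("Sfmbt2", "chr6", 50e6, 13500, NA,      0.028),
    cis_locus("Eras",   "chr6", 70e6, 11000, NA,      0.022),
    cis_locus("Myb",    "chr1", 35e6,  9500, NA,      0.015),
    cis_locus("Metrnl", "chr2", 30e6,  8000, NA,      0.013),
    cis_locus("Chl1",   "chr3", 60e6,  6000, NA,      0.010),
    cis_locus("Notch2", "chr4", 80e6,  5000, NA,      0.010),
    cis_locus("RegFeat","chr1", 92e6,  5000, NA,      0.010),
    cis_locus("Sfi1",   "chr5", 33e6,  2500, NA,      0.008),
    cis_locus("Dock5",  "chr5", 63e6,  4000, NA,      0.008),
    cis_locus("Fezf1",  "chr6", 92e6,  4500, NA,      0.008),
    cis_locus("Tbx3",   "chr4", 92e6,  4000, NA,      0.008)
  )
  len <- genome$length[match(L$chrom, genome$chrom)]
  keep <- !is.na(len) & L$center <= len
  out <- L[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname default_loci
#' @export
default_genome <- function() {
  genome_layout(paste0("chr", 1:6), rep(100e6, 6))
}

# Cohort composition: four genotype/strain arms of a full-size screen.
default_strata <- function() {
  data.frame(strain = c("FVB", "FVB", "BALBc", "BALBc"),
             genotype = c("wt", "Pten", "wt", "Trp53"),
             proportion = c(265, 200, 80, 59) / 604,
             stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Encodes the stated world of the synthetic screen. Defaults emulate a
#' 604-tumor cohort: ~30 planted CIS loci in 5 gene families plus
#' singletons, a heavy single-LP insertion background
#' (`background_rate = 49` per tumor, LP ~ 1 + Geometric(0.8) so ~80% of
#' background insertions carry a single LP), within-family mutual
#' exclusivity, and a planted early-to-late family order expressed through
#' LP counts: a tumor's earliest event has clonal fraction 1 and expected
#' LP count `lp_depth`, each later rank halves the clonal fraction.
#'
#' @param genome [genome_layout()].
#' @param loci data.frame of planted loci ([cis_locus()] rows).
#' @param group_order character vector of all group names, earliest first.
#'   Defaults to family declaration order with singletons after the named
#'   families.
#' @param n_tumors number of tumors.
#' @param strata data.frame with columns `strain`, `genotype`, `proportion`.
#' @param background_rate expected background insertions per tumor
#'   (Poisson).
#' @param clonal_fraction_by_rank strictly decreasing sequence in `(0, 1]`,
#'   first element 1; ranks beyond its length reuse the last value.
#' @param lp_depth expected unique-LP count of a fully clonal insertion.
#' @param exclusivity logical; if `TRUE` a tumor hits at most one locus per
#'   group.
#' @param seed integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(genome = default_genome(),
                       loci = default_loci(genome),
                       group_order = NULL,
                       n_tumors = 604,
                       strata = default_strata(),
                       background_rate = 49,
                       clonal_fraction_by_rank = c(1, 0.5, 0.25, 0.125, 0.0625),
                       lp_depth = 40,
                       exclusivity = TRUE,
                       seed = 1L) {
  if (n_tumors <= 0) stop_ims("n_tumors must be positive")
  if (nrow(loci) == 0L) stop_ims("loci list must not be empty")
  assert_columns(loci, c("name", "chrom", "center", "spread", "group",
                         "hit_probability"), "loci")
  if (anyDuplicated(loci$name)) stop_ims("locus names must be unique")
  if (any(loci$spread <= 0)) stop_ims("all locus spreads must be > 0")
  if (any(loci$hit_probability < 0 | loci$hit_probability > 1)) {
    stop_ims("hit probabilities must be in [0, 1]")
  }
  if (any(loci$center < 1) ||
      any(loci$center > chrom_len(genome, loci$chrom))) {
    stop_ims("locus centers must lie within their chromosome")
  }
  groups <- unique(loci$group)
  if (is.null(group_order)) group_order <- groups
  if (!setequal(groups, group_order) || anyDuplicated(group_order)) {
    stop_ims("group_order must list every locus group exactly once")
  }
  cf <- clonal_fraction_by_rank
  if (length(cf) == 0L || cf[1L] != 1 || any(cf <= 0) || any(cf > 1) ||
      any(diff(cf) >= 0)) {
    stop_ims("clonal_fraction_by_rank must start at 1 and be strictly decreasing in (0, 1]")
  }
  if (abs(sum(strata$proportion) - 1) > 1e-8) {
    stop_ims("strata proportions must sum to 1")
  }
  per_group <- tapply(loci$hit_probability, loci$group, sum)
  if (exclusivity && any(per_group > 1 + 1e-12)) {
    stop_ims("with exclusivity, summed hit probabilities within a group must be <= 1")
  }
  structure(list(
    genome = genome, loci = loci, group_order = as.character(group_order),
    n_tumors = as.integer(n_tumors), strata = strata,
    background_rate = background_rate,
    clonal_fraction_by_rank = cf, lp_depth = lp_depth,
    exclusivity = isTRUE(exclusivity), seed = as.integer(seed),
    # implied mean number of driver events per tumor (Poisson-binomial over
    # groups/loci); recorded for reporting, not an independent dial
    events_per_tumor = sum(loci$hit_probability)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic screen configuration\n")
  cat(sprintf("  %d tumors, %d planted loci in %d groups on %d chromosomes\n",
              x$n_tumors, nrow(x$loci), length(x$group_order),
              nrow(x$genome)))
  cat(sprintf("  background rate %.1f insertions/tumor; lp_depth %.0f; exclusivity %s\n",
              x$background_rate, x$lp_depth, x$exclusivity))
  cat(sprintf("  expected driver events/tumor %.2f; seed %d\n",
              x$events_per_tumor, x$seed))
  invisible(x)
}
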