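#' Simulate a fragment-level insertional mutagenesis screen
#'
#' Generates a synthetic cohort with known ground truth. For each tumor the
#' generator decides, per gene family, whether the family is hit (with the
#' summed member hit probabilities) and, if so, which single member carries
#' the insertion (probability proportional to member hit probability) --
#' with `exclusivity = FALSE` every locus is an independent Bernoulli draw
#' instead. Hit events are ranked by the position of their family in
#' `group_order` (earliest family = rank 1); the event at rank r gets clonal
#' fraction `clonal_fraction_by_rank[r]` and an LP count drawn as
#' `1 + Poisson(lp_depth * fraction - 1)` (floored at 1). Background
#' insertions are Poisson per tumor, placed uniformly on the genome with
#' LP ~ 1 + Geometric(0.8), so about 80% of them carry a single LP.
#'
#' Every insertion with LP count k emits k fragment records sharing one
#' junction coordinate but k distinct ligation points: shear offsets are
#' drawn without replacement from 100--1000 bp and applied on the side of
#' the junction opposite the viral sequence (downstream for `+`
#' insertions, upstream for `-`).
#'
#' All randomness flows from `config$seed`: the same configuration gives a
#' byte-identical fragment table on every run.
#'
#' @param config a [sim_config()].
#' @return list of class `ims_cohort` with elements
#'   \describe{
#'     \item{fragments}{data.frame with columns `tumor_id`, `chrom`,
#'       `position`, `ligation_point`, `orientation`.}
#'     \item{tumors}{metadata data.frame: `tumor_id`, `strain`, `genotype`.}
#'     \item{truth}{`sim_truth` object: planted events per tumor, planted
#'       locus windows (`center +/- 4 * spread`), planted group order.}
#'   }
#' @examples
#' cfg <- sim_config(n_tumors = 20, background_rate = 5, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' head(cohort$fragments)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")

  loci <- config$loci
  genome <- config$genome
  n <- config$n_tumors
  tumor_ids <- sprintf("T%04d", seq_len(n))
  rank_of_group <- setNames(seq_along(config$group_order), config$group_order)
  cf <- config$clonal_fraction_by_rank

  # cohort strata
  stratum <- sample.int(nrow(config$strata), n, replace = TRUE,
                        prob = config$strata$proportion)
  tumors <- data.frame(tumor_id = tumor_ids,
                       strain = config$strata$strain[stratum],
                       genotype = config$strata$genotype[stratum],
                       stringsAsFactors = FALSE)

  groups <- split(seq_len(nrow(loci)), loci$group)

  frag_list <- vector("list", n)
  event_list <- vector("list", n)
  for (t in seq_len(n)) {
    # --- driver events -------------------------------------------------
    if (config$exclusivity) {
      hit_idx <- integer(0)
      for (g in names(groups)) {
        members <- groups[[g]]
        p <- loci$hit_probability[members]
        if (runif(1) < sum(p)) {
          pick <- if (length(members) == 1L) members else
            members[sample.int(length(members), 1L, prob = p)]
          hit_idx <- c(hit_idx, pick)
        }
      }
    } else {
      hit_idx <- which(runif(nrow(loci)) < loci$hit_probability)
    }

    ev <- NULL
    if (length(hit_idx)) {
      g_rank <- rank_of_group[loci$group[hit_idx]]
      o <- order(g_rank, hit_idx)
      hit_idx <- hit_idx[o]
      rank <- seq_along(hit_idx)
      frac <- cf[pmin(rank, length(cf))]
      lam <- pmax(config$lp_depth * frac - 1, 0)
      lp <- 1L + rpois(length(hit_idx), lam)
      len <- chrom_len(genome, loci$chrom[hit_idx])
      pos <- round(rnorm(length(hit_idx), loci$center[hit_idx],
                         loci$spread[hit_idx]))
      pos <- pmin(pmax(pos, 1), len)
      ev <- data.frame(
        tumor_id = tumor_ids[t], locus = loci$name[hit_idx],
        group = loci$group[hit_idx], rank = rank, clonal_fraction = frac,
        lp_count = lp, chrom = loci$chrom[hit_idx], position = pos,
        stringsAsFactors = FALSE)
    }
    event_list[[t]] <- ev

    # --- background insertions ----------------------------------------
    nb <- rpois(1L, config$background_rate)
    bg <- NULL
    if (nb > 0L) {
      ci <- sample.int(nrow(genome), nb, replace = TRUE,
                       prob = genome$length)
      bpos <- floor(runif(nb, 1, genome$length[ci] + 1))
      blp <- 1L + rgeom(nb, 0.8)
      bg <- data.frame(chrom = genome$chrom[ci], position = bpos,
                       lp_count = blp, stringsAsFactors = FALSE)
    }

    # --- emit fragments ------------------------------------------------
    ins_chrom <- c(if (!is.null(ev)) ev$chrom, if (!is.null(bg)) bg$chrom)
    ins_pos <- c(if (!is.null(ev)) ev$position, if (!is.null(bg)) bg$position)
    ins_lp <- c(if (!is.null(ev)) ev$lp_count, if (!is.null(bg)) bg$lp_count)
    if (length(ins_pos) == 0L) {
      frag_list[[t]] <- NULL
      next
    }
    orient <- sample(c("+", "-"), length(ins_pos), replace = TRUE)
    ins_len <- chrom_len(genome, ins_chrom)
    side <- ifelse(orient == "+", 1, -1)
    # keep ligation points on-chromosome; flip side near an edge
    side[side > 0 & ins_pos + 1000 > ins_len] <- -1
    side[side < 0 & ins_pos - 1000 < 1] <- 1
    offsets <- unlist(lapply(ins_lp, function(k) sample(100:1000, k)))
    idx <- rep.int(seq_along(ins_pos), ins_lp)
    frag_list[[t]] <- data.frame(
      tumor_id = tumor_ids[t], chrom = ins_chrom[idx],
      position = ins_pos[idx],
      ligation_point = ins_pos[idx] + side[idx] * offsets,
      orientation = orient[idx], stringsAsFactors = FALSE)
  }

  fragments <- do.call(rbind, frag_list[!vapply(frag_list, is.null, TRUE)])
  rownames(fragments) <- NULL
  events <- do.call(rbind, event_list[!vapply(event_list, is.null, TRUE)])
  if (is.null(events)) {
    events <- data.frame(tumor_id = character(0), locus = character(0),
                         group = character(0), rank = integer(0),
                         clonal_fraction = numeric(0), lp_count = integer(0),
                         chrom = character(0), position = numeric(0))
  }
  rownames(events) <- NULL

  windows <- data.frame(
    locus = loci$name, group = loci$group, chrom = loci$chrom,
    start = pmax(1, loci$center - 4 * loci$spread),
    end = pmin(chrom_len(genome, loci$chrom), loci$center + 4 * loci$spread),
    hit_probability = loci$hit_probability, stringsAsFactors = FALSE)

  truth <- structure(list(events = events, windows = windows,
                          group_order = config$group_order,
                          seed = config$seed),
                     class = "sim_truth")
  structure(list(fragments = fragments, tumors = tumors, truth = truth),
            class = "ims_cohort")
}

#' @export
print.ims_cohort <- function(x, ...) {
  cat(sprintf("Synthetic screen: %d fragments, %d tumors, %d planted events\n",
              nrow(x$fragments), nrow(x$tumors), nrow(x$truth$events)))
  invisible(x)
}

#' Write / read planted ground truth as JSON
#'
#' @param truth a `sim_truth` object from [simulate_cohort()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(
    list(events = truth$events, windows = truth$windows,
         group_order = truth$group_order, seed = truth$seed),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(events = as.data.frame(x$events),
                 windows = as.data.frame(x$windows),
                 group_order = as.character(x$group_order),
                 seed = as.integer(x$seed)),
            class = "sim_truth")
}
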