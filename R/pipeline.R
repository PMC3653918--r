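#' Default gene-family map of the synthetic screen
#'
#' Maps target-gene names to the five gene families used for family-level
#' exclusivity and progression grouping.
#'
#' @return named list: family -> member gene names.
#' @export
default_family_map <- function() {
  list(Wnt   = c("Wnt1", "Wnt3a", "Wnt3"),
       Fgf   = c("Fgf3", "Fgf8", "Hbegf", "Fgf10", "Fgf6"),
       Fgfr  = c("Fgfr2", "Fgfr1", "Fgfr3"),
       Rspo  = c("Rspo2", "Rspo3", "Rspo1"),
       Pdgfr = c("Pdgfra", "Pdgfrb"))
}

#' Run the full insertional-mutagenesis analysis on a cohort
#'
#' The end-to-end analysis: insertion calling from fragments, the
#' single-LP background filter, multi-scale GKC common-insertion-site
#' detection, target-gene assignment, the tumor x CIS incidence matrix,
#' the co-occurrence / mutual-exclusivity network, family exclusivity,
#' genotype and strain association, and the binomial clonality-ordering
#' progression graph.
#'
#' @param fragments fragment records (data.frame or path readable by
#'   [read_fragments()]).
#' @param tumors tumor metadata (data.frame or path).
#' @param genome [genome_layout()] (or chrom.sizes path).
#' @param annotation optional gene annotation data.frame
#'   ([read_annotation()]) for target assignment.
#' @param family_map named list mapping family names to target-gene names;
#'   default [default_family_map()].
#' @param merge_window fragment clustering window, bp.
#' @param scales kernel widths for CIS detection, bp.
#' @param alpha_cis per-chromosome/scale FWER for CIS calling.
#' @param n_perm permutations per CIS threshold.
#' @param alpha_network FDR level for network edges.
#' @param alpha_progression p-value threshold for progression edges.
#' @param min_tumors minimum tumors per progression group.
#' @param contamination_filter apply
#'   [filter_cross_contamination()] before calling (off by default).
#' @param seed integer seed governing all randomness.
#' @return object of class `ims_screen` with components `insertions_raw`,
#'   `insertions`, `filter_summary`, `cis`, `incidence`, `network`,
#'   `family_exclusivity`, `associations`, `groups`, `scores`,
#'   `comparisons`, `progression`, `coverage`, `tumors_in_cis`, `report`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_tumors = 60, background_rate = 10, seed = 3)
#' cohort <- simulate_cohort(cfg)
#' fit <- ims_screen(cohort$fragments, cohort$tumors, cfg$genome,
#'                   annotation = loci_annotation(cfg$loci, cfg$genome),
#'                   n_perm = 100, seed = 3)
#' print(fit)
#' }
#' @export
ims_screen <- function(fragments, tumors, genome, annotation = NULL,
                       family_map = default_family_map(),
                       merge_window = 5, scales = c(10e3, 30e3, 100e3),
                       alpha_cis = 0.05, n_perm = 1000,
                       alpha_network = 0.05, alpha_progression = 0.05,
                       min_tumors = 10, contamination_filter = FALSE,
                       seed = 1L) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  if (is.character(tumors)) tumors <- read_tumors(tumors)
  if (is.character(genome)) genome <- read_chrom_sizes(genome)

  if (contamination_filter) fragments <- filter_cross_contamination(fragments)
  raw <- call_insertions(fragments, merge_window = merge_window)
  ins <- filter_single_lp(raw)
  fsum <- cohort_summary(ins, raw)

  cis <- detect_cis(ins, genome, scales = scales, alpha = alpha_cis,
                    n_perm = n_perm, seed = seed)
  if (!is.null(annotation)) cis <- assign_target(cis, annotation)

  post_tumors <- tumors[tumors$tumor_id %in% unique(ins$tumor_id), ,
                        drop = FALSE]
  coverage <- insertions_in_cis_fraction(ins, cis)
  in_cis_tab <- tumors_in_cis_fraction(ins, cis, tumors)

  incidence <- NULL; network <- NULL; fampat <- NULL; assoc <- list()
  groups <- NULL; scores <- NULL; comparisons <- NULL; progression <- NULL
  if (nrow(cis) >= 1L) {
    incidence <- build_incidence(ins, cis, post_tumors)
    fam_cols <- lapply(family_map, intersect, colnames(incidence))
    if (ncol(incidence) >= 2L) {
      network <- build_network(incidence, alpha = alpha_network)
      fampat <- family_pattern(incidence, fam_cols,
                               seed = child_seed(seed, 901L))
      assoc <- matched_associations(incidence, post_tumors)
    }
    groups <- group_cis(incidence, fam_cols, min_tumors = min_tumors)
    if (length(groups$groups) >= 2L) {
      scores <- clonality_scores(incidence, groups)
      comparisons <- compare_all_groups(scores)
      progression <- progression_graph(comparisons,
                                       alpha = alpha_progression)
    }
  }

  report <- list(
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("imscreen")),
    parameters = list(merge_window = merge_window,
                      scales = vapply(as_kernel_scales(scales),
                                      function(s) s$h, numeric(1)),
                      alpha_cis = alpha_cis, n_perm = n_perm,
                      alpha_network = alpha_network,
                      alpha_progression = alpha_progression,
                      min_tumors = min_tumors,
                      contamination_filter = contamination_filter),
    n_fragments = nrow(fragments),
    n_tumors = nrow(tumors),
    insertions_before_filter = fsum$sites_before,
    insertions_after_filter = fsum$sites_after,
    site_reduction_pct = fsum$site_reduction_pct,
    read_reduction_pct = fsum$read_reduction_pct,
    dropped_tumors = fsum$dropped_tumors,
    n_tumors_post_filter = fsum$tumors_after,
    n_cis = nrow(cis),
    insertions_in_cis_pct = coverage$percent,
    tumors_in_cis = in_cis_tab,
    n_network_edges = if (is.null(network)) 0L else nrow(network$edges),
    n_groups = if (is.null(groups)) 0L else length(groups$groups),
    n_progression_edges = if (is.null(progression)) 0L else
      nrow(progression$edges),
    progression_acyclic = if (is.null(progression)) NA else
      progression$acyclic
  )

  structure(list(insertions_raw = raw, insertions = ins,
                 filter_summary = fsum, cis = cis, incidence = incidence,
                 network = network, family_exclusivity = fampat,
                 associations = assoc, groups = groups, scores = scores,
                 comparisons = comparisons, progression = progression,
                 coverage = coverage, tumors_in_cis = in_cis_tab,
                 tumors = tumors, genome = genome, report = report),
            class = "ims_screen")
}

# Matched genotype/strain comparisons: wild-type vs mutant within each
# strain, plus wild-type vs wild-type across the two largest strains.
matched_associations <- function(incidence, tumors) {
  out <- list()
  tt <- tumors[tumors$tumor_id %in% rownames(incidence), , drop = FALSE]
  for (s in unique(tt$strain)) {
    sub <- tt[tt$strain == s, , drop = FALSE]
    gts <- unique(sub$genotype)
    if (length(gts) < 2L || !"wt" %in% gts) next
    for (mut in setdiff(gts, "wt")) {
      sel <- sub$tumor_id[sub$genotype %in% c("wt", mut)]
      tab <- try(genotype_association(incidence[sel, , drop = FALSE], sub,
                                      "genotype", levels = c("wt", mut)),
                 silent = TRUE)
      if (!inherits(tab, "try-error")) {
        out[[sprintf("%s:wt-vs-%s", s, mut)]] <- tab
      }
    }
  }
  wt <- tt[tt$genotype == "wt", , drop = FALSE]
  if (length(unique(wt$strain)) >= 2L) {
    lv <- names(sort(table(wt$strain), decreasing = TRUE))[1:2]
    tab <- try(genotype_association(incidence[wt$tumor_id, , drop = FALSE],
                                    wt, "strain", levels = lv),
               silent = TRUE)
    if (!inherits(tab, "try-error")) {
      out[[sprintf("wt:%s-vs-%s", lv[1L], lv[2L])]] <- tab
    }
  }
  out
}

#' @export
print.ims_screen <- function(x, ...) {
  r <- x$report
  cat("Insertional mutagenesis screen analysis\n")
  cat(sprintf("  fragments: %d from %d tumors\n", r$n_fragments, r$n_tumors))
  cat(sprintf("  insertions: %d -> %d after single-LP filter (%s%% of sites, %s%% of reads removed)\n",
              r$insertions_before_filter, r$insertions_after_filter,
              r$site_reduction_pct, r$read_reduction_pct))
  cat(sprintf("  common insertion sites: %d (%.1f%% of insertions inside a CIS)\n",
              r$n_cis, r$insertions_in_cis_pct))
  cat(sprintf("  network edges: %d; progression groups: %d; progression edges: %d%s\n",
              r$n_network_edges, r$n_groups, r$n_progression_edges,
              if (isTRUE(r$progression_acyclic)) " (acyclic)" else ""))
  invisible(x)
}

#' @export
summary.ims_screen <- function(object, ...) {
  print(object)
  cat("\nTumors contributing an insertion to a CIS:\n")
  print.data.frame(object$tumors_in_cis)
  if (!is.null(object$cis) && nrow(object$cis)) {
    cat("\nTop CISs by tumor support:\n")
    o <- order(object$cis$n_tumors, decreasing = TRUE)
    print.data.frame(head(as.data.frame(object$cis)[o, c(
      "chrom", "start", "end", "target", "n_insertions", "n_tumors")], 10L))
  }
  if (!is.null(object$network) && nrow(object$network$edges)) {
    cat("\nSignificant CIS associations:\n")
    print.data.frame(head(object$network$edges[, c(
      "cis_a", "cis_b", "direction", "n11", "q_value")], 10L))
  }
  if (!is.null(object$progression)) print(object$progression)
  invisible(object)
}

#' Plot an analyzed screen
#'
#' `type = "genome"` draws per-chromosome insertion coordinates (jittered
#' by LP count on the y axis) with detected CIS intervals shaded;
#' `type = "progression"` draws the directed progression graph;
#' `type = "incidence"` draws a presence heatmap of tumors by CIS.
#'
#' @param x `ims_screen` object.
#' @param type plot flavor.
#' @param ... passed to underlying plot calls.
#' @export
plot.ims_screen <- function(x, type = c("genome", "progression", "incidence"),
                            ...) {
  type <- match.arg(type)
  if (type == "genome") {
    ins <- x$insertions
    chroms <- x$genome$chrom
    op <- par(mfrow = c(length(chroms), 1), mar = c(2, 4, 1, 1))
    on.exit(par(op))
    for (ch in chroms) {
      sel <- ins$chrom == ch
      plot(ins$position[sel], ins$lp_count[sel], pch = 16, cex = 0.4,
           col = adjustcolor("grey30", 0.5), xlab = "", ylab = ch,
           xlim = c(1, chrom_len(x$genome, ch)), log = "y", ...)
      cc <- x$cis[x$cis$chrom == ch, , drop = FALSE]
      if (nrow(cc)) {
        rect(cc$start, 1, cc$end, max(ins$lp_count[sel], 2),
             col = adjustcolor("firebrick", 0.25), border = NA)
      }
    }
  } else if (type == "progression") {
    if (is.null(x$progression) || nrow(x$progression$edges) == 0L) {
      stop_ims("no progression edges to plot")
    }
    e <- x$progression$edges
    g <- igraph::graph_from_data_frame(e[, c("parent", "child")],
                                       directed = TRUE)
    igraph::plot.igraph(g, edge.width = 1 + e$weight / 4,
                        edge.label = e$label, vertex.color = "lightsteelblue",
                        vertex.label.color = "black", ...)
  } else {
    m <- (x$incidence > 0) + 0
    o <- order(colSums(m), decreasing = TRUE)
    graphics::image(t(m[order(m %*% (2^pmin(seq_along(o), 30))[o]), o,
                        drop = FALSE]),
                    col = c("white", "grey20"), axes = FALSE, ...)
    axis(1, at = seq(0, 1, length.out = length(o)),
         labels = colnames(m)[o], las = 2, cex.axis = 0.6)
  }
  invisible(x)
}

#' Run the pipeline from a configuration (file-based orchestration)
#'
#' Executes simulate (optional) -> call -> filter -> CIS -> network ->
#' progression, writing every intermediate artifact to `out_dir` and a
#' machine-readable JSON run report with stage counts and provenance
#' (parameters, seed, package version). Any stage failure aborts with the
#' stage name; artifacts written so far are retained.
#'
#' @param config named list. Either `simulate = TRUE` with an optional
#'   `sim` sub-list of [sim_config()] arguments, or paths `fragments`,
#'   `tumors`, `chrom_sizes` (plus optional `annotation`). Optional stage
#'   parameters as in [ims_screen()]; `out_dir` (required); `seed`.
#' @return the `ims_screen` object, invisibly; the report is at
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  for (field in c("out_dir")) {
    if (is.null(config[[field]])) stop_ims("config is missing field: ", field)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ims(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)))
    })
  }

  if (isTRUE(config$simulate)) {
    sim_args <- config$sim %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    cfg <- stage("simulate", do.call(sim_config, sim_args))
    cohort <- stage("simulate", simulate_cohort(cfg))
    fragments <- cohort$fragments
    tumors <- cohort$tumors
    genome <- cfg$genome
    annotation <- loci_annotation(cfg$loci, genome)
    write_fragments(fragments, file.path(out_dir, "fragments.tsv"))
    write_tumors(tumors, file.path(out_dir, "tumors.tsv"))
    write_chrom_sizes(genome, file.path(out_dir, "genome.chrom.sizes"))
    write_truth(cohort$truth, file.path(out_dir, "truth.json"))
  } else {
    for (field in c("fragments", "tumors", "chrom_sizes")) {
      if (is.null(config[[field]])) {
        stop_ims("config is missing field: ", field)
      }
      if (!file.exists(config[[field]])) {
        stop_ims(sprintf("config field '%s': file not found: %s", field,
                         config[[field]]))
      }
    }
    fragments <- stage("read", read_fragments(config$fragments))
    tumors <- stage("read", read_tumors(config$tumors))
    genome <- stage("read", read_chrom_sizes(config$chrom_sizes))
    annotation <- if (!is.null(config$annotation)) {
      stage("read", read_annotation(config$annotation))
    } else NULL
  }

  fit <- stage("analyze", ims_screen(
    fragments, tumors, genome, annotation = annotation,
    family_map = config$family_map %||% default_family_map(),
    merge_window = config$merge_window %||% 5,
    scales = config$scales %||% c(10e3, 30e3, 100e3),
    alpha_cis = config$alpha_cis %||% 0.05,
    n_perm = config$n_perm %||% 1000,
    alpha_network = config$alpha_network %||% 0.05,
    alpha_progression = config$alpha_progression %||% 0.05,
    min_tumors = config$min_tumors %||% 10,
    contamination_filter = isTRUE(config$contamination_filter),
    seed = seed))

  stage("write", {
    write_insertions(fit$insertions_raw, file.path(out_dir, "insertions_raw.tsv"))
    write_insertions(fit$insertions, file.path(out_dir, "insertions.tsv"))
    write_insertions_bed(fit$insertions, file.path(out_dir, "insertions.bed"))
    write_cis(fit$cis, file.path(out_dir, "cis.tsv"))
    if (!is.null(fit$incidence)) {
      write_incidence(fit$incidence, file.path(out_dir, "incidence.tsv"))
    }
    if (!is.null(fit$network)) {
      write_network_edges(fit$network, file.path(out_dir, "network_edges.tsv"))
      write_network_graphml(fit$network, file.path(out_dir, "network.graphml"))
    }
    if (!is.null(fit$comparisons)) {
      write_comparisons(fit$comparisons, file.path(out_dir, "comparisons.tsv"))
    }
    if (!is.null(fit$progression)) {
      write_progression_edges(fit$progression,
                              file.path(out_dir, "progression_edges.tsv"))
      write_progression_graphml(fit$progression,
                                file.path(out_dir, "progression.graphml"))
    }
    jsonlite::write_json(fit$report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  })
  invisible(fit)
}
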