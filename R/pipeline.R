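# End-to-end pipeline: simulate -> score -> peaks -> calls -> comparisons ->
# DE -> concordance, with optional on-disk outputs.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full promoter-methylome pipeline on a simulated study
#'
#' Generates a seeded synthetic study ([sim_config()]), scores every
#' condition's probe track with the windowed one-sided KS test, calls peaks
#' and gene-level methylation, summarizes MaxTen intensities and positional
#' classes, compares methylated-gene sets across cell types (Venn, sharing
#' matrix) and across the quiescent-to-activated transition (lost / gained /
#' retained), classifies cell-type-selective and differentially expressed
#' genes, and reports methylation-expression concordance. All stages are
#' deterministic given the config seed.
#'
#' @param config A [sim_config()], or the path of a YAML file whose fields
#'   are `sim_config()` arguments.
#' @param outdir Optional output directory; when given, all tables are
#'   written (probe track TSV, promoter BED6, truth TSV, per-condition peak
#'   BED5 and call TSVs, comparison and DE and concordance TSVs, plus a
#'   `run_log.yaml` with every parameter).
#' @param p_cutoff,min_peak_probes,max_gap_bp Peak-calling parameters.
#' @param window_bp,min_probes Probe-scoring parameters.
#' @param fold,alpha Expression classification thresholds.
#' @param region_breaks,region_labels Positional class regions (promoter-
#'   relative breaks).
#' @return A list with all intermediate and final tables: `layout`, `truth`,
#'   `track`, `expression`, `peaks`, `calls`, `maxten`, `sets`, `venn`,
#'   `sharing`, `transition`, `position_counts`, `position_test`,
#'   `selective`, `de`, `concordance`, `params`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         p_cutoff = 0.01, window_bp = 750, min_probes = 4,
                         min_peak_probes = 2, max_gap_bp = 500,
                         fold = 2, alpha = 0.05,
                         region_breaks = c(-3000, -500, 500, 1000),
                         region_labels = c("upstream", "TSS", "downstream")) {
  if (is.character(config)) {
    config <- run_stage("config", do.call(sim_config, yaml::read_yaml(config)))
  }
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")

  layout <- run_stage("layout", generate_layout(config))
  sim <- run_stage("simulate_methylome", simulate_methylome(config, layout))
  expr <- run_stage("simulate_expression", simulate_expression(config, sim$truth))
  conds <- sim$conditions
  cts <- conds[-length(conds)]
  qcond <- cts[1L]
  acond <- conds[length(conds)]

  scored <- run_stage("score", lapply(stats::setNames(conds, conds), function(cn) {
    windowed_ks_score(sim$track, cn, window_bp = window_bp,
                      min_probes = min_probes)
  }))
  peaks <- run_stage("callpeaks", lapply(scored, call_peaks,
                                         p_cutoff = p_cutoff,
                                         min_peak_probes = min_peak_probes,
                                         max_gap_bp = max_gap_bp))
  calls <- run_stage("callgenes", lapply(peaks, call_promoter_methylation,
                                         promoters = layout$promoters))
  mx <- run_stage("maxten", lapply(stats::setNames(conds, conds), function(cn) {
    maxten(sim$track, layout$promoters, cn)
  }))
  sets <- lapply(calls, function(cc) cc$gene[cc$methylated])

  venn <- run_stage("compare", if (length(cts) >= 2L) venn_counts(sets[cts]))
  sharing <- run_stage("compare", if (all(lengths(sets) > 0L)) sharing_matrix(sets))
  transition <- run_stage("compare", transition_summary(sets[[qcond]], sets[[acond]]))

  position_counts <- list()
  for (cn in c(qcond, acond)) {
    meth_genes <- sets[[cn]]
    position_counts[[cn]] <- if (length(meth_genes)) {
      prom <- layout$promoters[layout$promoters$gene %in% meth_genes, ]
      cls <- classify_position(peaks[[cn]], prom, breaks = region_breaks,
                               labels = region_labels)
      counts <- vapply(region_labels, function(l) {
        sum(vapply(strsplit(cls$class, ","), function(x) l %in% x, logical(1)))
      }, integer(1))
      counts
    } else stats::setNames(integer(length(region_labels)), region_labels)
  }
  position_test <- if (all(position_counts[[qcond]] + position_counts[[acond]] > 0) &&
                       sum(position_counts[[qcond]]) > 0 &&
                       sum(position_counts[[acond]]) > 0) {
    run_stage("position_shift",
              position_shift_test(position_counts[[qcond]],
                                  position_counts[[acond]]))
  }

  groups <- expr$groups
  selective <- run_stage("selective", if (length(cts) >= 3L) {
    ct_cols <- groups$sample[groups$group %in% cts]
    celltype_selective(expr$matrix[, ct_cols],
                       factor(groups$group[match(ct_cols, groups$sample)],
                              levels = cts),
                       fold = fold, alpha = alpha)
  })
  de_cols <- groups$sample[groups$group %in% c(qcond, acond)]
  de <- run_stage("de", differential_expression(
    expr$matrix[, de_cols],
    factor(groups$group[match(de_cols, groups$sample)],
           levels = c(qcond, acond)),
    fold = fold, alpha = alpha))
  concordance <- run_stage("concordance", concordant_genes(
    de, calls[[qcond]], calls[[acond]],
    maxten_before = mx[[qcond]], maxten_after = mx[[acond]]))

  params <- list(p_cutoff = p_cutoff, window_bp = window_bp,
                 min_probes = min_probes, min_peak_probes = min_peak_probes,
                 max_gap_bp = max_gap_bp, fold = fold, alpha = alpha,
                 region_breaks = region_breaks,
                 region_labels = region_labels,
                 seed = config$seed)

  result <- list(layout = layout, truth = sim$truth, track = sim$track,
                 expression = expr, peaks = peaks, calls = calls,
                 maxten = mx, sets = sets, venn = venn, sharing = sharing,
                 transition = transition, position_counts = position_counts,
                 position_test = position_test, selective = selective,
                 de = de, concordance = concordance, params = params,
                 config = config)

  if (!is.null(outdir)) run_stage("write_outputs", {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
    write_probe_track(sim$track, file.path(outdir, "probe_track.tsv"))
    write_promoters(layout$promoters, file.path(outdir, "promoters.bed"))
    tsv(sim$truth, "truth.tsv")
    write_expression_matrix(expr$matrix, file.path(outdir, "expression.tsv"))
    tsv(groups, "groups.tsv")
    for (cn in conds) {
      write_peaks_bed(peaks[[cn]], file.path(outdir, paste0("peaks_", cn, ".bed")))
      tsv(calls[[cn]], paste0("calls_", cn, ".tsv"))
      tsv(mx[[cn]], paste0("maxten_", cn, ".tsv"))
    }
    if (!is.null(venn)) tsv(venn, "venn_celltypes.tsv")
    if (!is.null(sharing)) {
      write.table(data.frame(set = rownames(sharing), sharing,
                             check.names = FALSE),
                  file.path(outdir, "sharing_matrix.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tsv(data.frame(metric = c("n_before", "n_after", "n_lost", "n_gained",
                              "n_retained", "pct_lost", "pct_gained"),
                   value = c(transition$n_before, transition$n_after,
                             transition$n_lost, transition$n_gained,
                             transition$n_retained, transition$pct_lost,
                             transition$pct_gained)),
        "transition.tsv")
    tsv(de$records, "de.tsv")
    if (!is.null(selective)) tsv(selective$records, "selective.tsv")
    tsv(concordance$table, "concordance.tsv")
    yaml::write_yaml(c(params, list(config = unclass(config))),
                     file.path(outdir, "run_log.yaml"))
  })
  result
}
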