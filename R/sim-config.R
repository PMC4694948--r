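#' Simulation configuration for the synthetic MeDIP-chip study
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' defaults describe the study conditions the generator emulates: promoter
#' tiling from -3 kb to +1 kb around each TSS at 100 bp spacing (40 probes),
#' Gaussian background log2(MeDIP/input) noise, an additive signal on probes
#' inside a planted methylation peak, three liver cell types with partially
#' shared methylated-promoter sets, a quiescent-to-activated transition that
#' loses 53% of methylated promoters and gains enough for ~47% of the
#' activated set to be novel, and a planted expression program (3.6% of genes
#' up, 6.1% down upon activation, 50 selective genes per cell type, 4-fold
#' planted effects) of which a fifth of DE genes get an opposing methylation
#' change.
#'
#' @param n_genes Number of simulated genes/promoters.
#' @param probes_per_promoter Probes tiled across each promoter window.
#' @param probe_spacing Distance between successive probe starts (bp).
#' @param window_up,window_down Promoter window extent upstream/downstream of
#'   the TSS (bp); probes cover `[TSS - window_up, TSS + window_down)`.
#' @param background_sd SD of the background log2-ratio noise.
#' @param effect_mean,effect_sd Mean/SD of the additive log2-ratio shift on
#'   probes inside a planted peak of a methylated promoter.
#' @param peak_width Width of each planted methylated region (bp).
#' @param celltype_meth_fractions Named vector: fraction of genes with a
#'   methylated promoter in each cell type. The first name is the quiescent
#'   cell type that undergoes activation.
#' @param core_fraction Fraction of genes methylated in every cell type.
#' @param transition_loss_rate Per-gene probability that a promoter methylated
#'   in the quiescent state is demethylated upon activation.
#' @param transition_gain_rate Per-gene probability that a promoter
#'   unmethylated in the quiescent state gains methylation upon activation.
#' @param concordant_fraction Fraction of planted DE genes whose methylation
#'   transition is forced to oppose their expression change.
#' @param n_replicates Replicates per expression group (>= 2).
#' @param expr_noise_sd Replicate noise SD on log2 expression values.
#' @param de_fold Planted linear fold change for DE and selective genes.
#' @param de_up_fraction,de_down_fraction Fractions of genes planted as up-
#'   or down-regulated upon activation.
#' @param selective_per_group Selective genes planted per cell type.
#' @param seed Master seed; all stage-level randomness is derived from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 7)
sim_config <- function(n_genes = 500L,
                       probes_per_promoter = 40L,
                       probe_spacing = 100L,
                       window_up = 3000L,
                       window_down = 1000L,
                       background_sd = 0.3,
                       effect_mean = 2.0,
                       effect_sd = 0.25,
                       peak_width = 800L,
                       celltype_meth_fractions = c(qHSC = 0.28, LSEC = 0.35, HEP = 0.36),
                       core_fraction = 0.21,
                       transition_loss_rate = 0.53,
                       transition_gain_rate = 0.163,
                       concordant_fraction = 0.2,
                       n_replicates = 3L,
                       expr_noise_sd = 0.25,
                       de_fold = 4,
                       de_up_fraction = 0.036,
                       de_down_fraction = 0.061,
                       selective_per_group = 50L,
                       seed = 1L) {
  for (nm in c("n_genes", "probes_per_promoter", "probe_spacing", "peak_width",
               "n_replicates", "window_up")) {
    if (!is_count(get(nm))) stop("'", nm, "' must be a positive integer")
  }
  if (!(length(window_down) == 1L && is.numeric(window_down) &&
        window_down >= 0 && window_down == round(window_down))) {
    stop("'window_down' must be a non-negative integer")
  }
  if (n_replicates < 2) stop("'n_replicates' must be >= 2 (tests are undefined otherwise)")
  fr <- c(celltype_meth_fractions, core_fraction = core_fraction,
          transition_loss_rate = transition_loss_rate,
          transition_gain_rate = transition_gain_rate,
          concordant_fraction = concordant_fraction,
          de_up_fraction = de_up_fraction, de_down_fraction = de_down_fraction)
  if (!is_fraction(fr)) stop("all fractions must lie in [0, 1]")
  nms <- names(celltype_meth_fractions)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms))) {
    stop("'celltype_meth_fractions' must have unique non-empty names")
  }
  if (any(celltype_meth_fractions < core_fraction)) {
    stop("every cell-type methylation fraction must be >= 'core_fraction'")
  }
  if (probes_per_promoter * probe_spacing > window_up + window_down) {
    stop("probes_per_promoter * probe_spacing must fit in the promoter window")
  }
  if (peak_width > window_up + window_down) {
    stop("'peak_width' exceeds the promoter window")
  }
  if (de_up_fraction + de_down_fraction > 1) {
    stop("de_up_fraction + de_down_fraction must be <= 1")
  }
  if (!(length(seed) == 1L && is.numeric(seed) && !is.na(seed) &&
        seed == round(seed))) stop("'seed' must be a single integer")
  if (background_sd < 0 || effect_sd < 0 || expr_noise_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (de_fold <= 0) stop("'de_fold' must be positive")
  structure(list(
    n_genes = as.integer(n_genes),
    probes_per_promoter = as.integer(probes_per_promoter),
    probe_spacing = as.integer(probe_spacing),
    window_up = as.integer(window_up),
    window_down = as.integer(window_down),
    background_sd = background_sd,
    effect_mean = effect_mean,
    effect_sd = effect_sd,
    peak_width = as.integer(peak_width),
    celltype_meth_fractions = celltype_meth_fractions,
    core_fraction = core_fraction,
    transition_loss_rate = transition_loss_rate,
    transition_gain_rate = transition_gain_rate,
    concordant_fraction = concordant_fraction,
    n_replicates = as.integer(n_replicates),
    expr_noise_sd = expr_noise_sd,
    de_fold = de_fold,
    de_up_fraction = de_up_fraction,
    de_down_fraction = de_down_fraction,
    selective_per_group = as.integer(selective_per_group),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$probes_per_promoter,
      "probes/promoter @", x$probe_spacing, "bp, window -", x$window_up,
      "/+", x$window_down, "bp, seed", x$seed, "\n")
  invisible(x)
}
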