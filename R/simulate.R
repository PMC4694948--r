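# Synthetic-data generator: promoter/probe layout, methylome with planted
# truth, expression matrix, and bisulfite clone matrices.

#' Generate the promoter and probe layout of a synthetic tiling array
#'
#' Tiles `probes_per_promoter` probes at `probe_spacing` bp across the
#' strand-aware promoter window `[TSS - window_up, TSS + window_down)` of each
#' simulated gene. Genes are placed 10 kb apart (up to 500 per synthetic
#' chromosome) so promoter windows never overlap; strand is drawn from the
#' seeded generator. Probes are 50 bp (or one spacing, if smaller) and the
#' probe track is returned position-sorted.
#'
#' @param config A [sim_config()].
#' @return A list with elements `promoters` (gene, chrom, strand, tss,
#'   window_start, window_end; 0-based half-open genomic window), `probes`
#'   (chrom, start, end, probe_id, gene, rel_start, rel_mid; `rel_*` are
#'   promoter-relative, 0 = TSS, negative = upstream) and `config`.
#' @export
generate_layout <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  n <- config$n_genes
  up <- config$window_up
  ppp <- config$probes_per_promoter
  probe_len <- min(50L, config$probe_spacing)

  set.seed(stage_seed(config$seed, "layout"))
  gene <- sprintf("G%05d", seq_len(n))
  chrom <- paste0("chr", (seq_len(n) - 1L) %/% 500L + 1L)
  tss <- 10000L + ((seq_len(n) - 1L) %% 500L) * 10000L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  promoters <- data.frame(gene = gene, chrom = chrom, strand = strand,
                          tss = tss, stringsAsFactors = FALSE)
  promoters <- promoter_windows(promoters, config$window_up, config$window_down)

  rel_start <- -up + (seq_len(ppp) - 1L) * config$probe_spacing
  gi <- rep(seq_len(n), each = ppp)
  rs <- rep(rel_start, times = n)
  plus <- strand[gi] == "+"
  start <- ifelse(plus, tss[gi] + rs, tss[gi] - rs - probe_len + 1L)
  probes <- data.frame(
    chrom = chrom[gi],
    start = as.integer(start),
    end = as.integer(start + probe_len),
    probe_id = sprintf("%s_p%02d", gene[gi], rep(seq_len(ppp), times = n)),
    gene = gene[gi],
    rel_start = rs,
    rel_mid = rs + probe_len / 2,
    stringsAsFactors = FALSE
  )
  probes <- probes[order(chrom_factor(probes$chrom), probes$start), ]
  rownames(probes) <- NULL
  list(promoters = promoters, probes = probes, config = config)
}

#' Compute strand-aware genomic promoter windows
#'
#' Maps the promoter-relative window `[-window_up, +window_down)` (0 = TSS,
#' negative = upstream) onto 0-based half-open genomic coordinates:
#' `[tss - window_up, tss + window_down)` on the plus strand and the mirror
#' `[tss - window_down + 1, tss + window_up + 1)` on the minus strand.
#'
#' @param promoters Data frame with columns `chrom`, `strand`, `tss` (and
#'   typically `gene`).
#' @param window_up,window_down Window extent in bp.
#' @return `promoters` with `window_start` and `window_end` columns replaced.
#' @export
promoter_windows <- function(promoters, window_up = 3000, window_down = 1000) {
  stopifnot(is.data.frame(promoters),
            all(c("strand", "tss") %in% names(promoters)))
  if (!all(promoters$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for every promoter")
  }
  plus <- promoters$strand == "+"
  promoters$window_start <- ifelse(plus, promoters$tss - window_up,
                                   promoters$tss - window_down + 1)
  promoters$window_end <- ifelse(plus, promoters$tss + window_down,
                                 promoters$tss + window_up + 1)
  promoters
}

#' Simulate a promoter methylome with planted ground truth
#'
#' Draws per-condition methylation states (cell-type core plus per-type unique
#' promoters; a quiescent-to-activated transition with configured loss and
#' gain rates), plants one fixed methylated region per ever-methylated gene
#' (uniform-random placement within the promoter window), and renders one
#' log2-ratio probe track column per condition: background noise
#' `N(0, background_sd)` plus an additive `N(effect_mean, effect_sd)` shift on
#' probes whose midpoint falls inside the planted region of a methylated
#' promoter.
#'
#' The truth table also carries the planted expression program (up/down/flat
#' direction, planted log2 fold change, selective cell type) and a concordant
#' flag. Flagged DE genes get the opposing methylation transition forced
#' (up-regulated: methylated only in the quiescent state; down-regulated:
#' methylated only in the activated state); non-flagged DE genes are forced
#' to be non-concordant so the flag is exactly the definitional set.
#'
#' @param config A [sim_config()].
#' @param layout The layout from [generate_layout()] for the same config.
#' @return A list with `track` (probe track with one log2-ratio column per
#'   condition), `truth` (per-gene truth table), `conditions` (condition
#'   labels; the last is the activated state) and `layout`.
#' @export
simulate_methylome <- function(config, layout) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  if (!identical(layout$config, config)) {
    stop("'layout' was not generated from this 'config'")
  }
  n <- config$n_genes
  cts <- names(config$celltype_meth_fractions)
  act <- activated_label(cts[1L])
  conds <- c(cts, act)

  # Cell-type states: shared core plus independent per-type extras.
  set.seed(stage_seed(config$seed, "meth_states"))
  core_n <- round(config$core_fraction * n)
  core <- sample.int(n, core_n)
  meth <- matrix(FALSE, n, length(conds), dimnames = list(NULL, conds))
  pool <- setdiff(seq_len(n), core)
  for (ct in cts) {
    target <- round(config$celltype_meth_fractions[[ct]] * n)
    extra <- target - core_n
    idx <- c(core, if (extra > 0) resample(pool, extra))
    meth[idx, ct] <- TRUE
  }

  # Quiescent -> activated transition.
  set.seed(stage_seed(config$seed, "transition"))
  q <- meth[, cts[1L]]
  lost <- q & runif(n) < config$transition_loss_rate
  gained <- !q & runif(n) < config$transition_gain_rate
  meth[, act] <- (q & !lost) | gained

  # Planted expression program.
  set.seed(stage_seed(config$seed, "expr_truth"))
  n_up <- round(config$de_up_fraction * n)
  n_down <- round(config$de_down_fraction * n)
  de <- sample.int(n, n_up + n_down)
  direction <- rep("flat", n)
  direction[de[seq_len(n_up)]] <- "up"
  direction[de[n_up + seq_len(n_down)]] <- "down"
  lfc <- numeric(n)
  lfc[direction == "up"] <- log2(config$de_fold)
  lfc[direction == "down"] <- -log2(config$de_fold)
  selective <- rep(NA_character_, n)
  flat_pool <- which(direction == "flat")
  for (ct in cts) {
    k <- min(config$selective_per_group, length(flat_pool))
    pick <- resample(flat_pool, k)
    selective[pick] <- ct
    flat_pool <- setdiff(flat_pool, pick)
  }

  # Concordance: force flagged DE genes into the opposing transition and
  # break accidental concordance of unflagged DE genes.
  set.seed(stage_seed(config$seed, "concordance"))
  concordant <- rep(FALSE, n)
  ups <- which(direction == "up")
  downs <- which(direction == "down")
  conc_up <- if (length(ups)) resample(ups, round(config$concordant_fraction * length(ups)))
  conc_dn <- if (length(downs)) resample(downs, round(config$concordant_fraction * length(downs)))
  concordant[c(conc_up, conc_dn)] <- TRUE
  meth[conc_up, cts[1L]] <- TRUE;  meth[conc_up, act] <- FALSE
  meth[conc_dn, cts[1L]] <- FALSE; meth[conc_dn, act] <- TRUE
  acc_up <- setdiff(ups, conc_up)
  acc_up <- acc_up[meth[acc_up, cts[1L]] & !meth[acc_up, act]]
  meth[acc_up, act] <- TRUE
  acc_dn <- setdiff(downs, conc_dn)
  acc_dn <- acc_dn[!meth[acc_dn, cts[1L]] & meth[acc_dn, act]]
  meth[acc_dn, act] <- FALSE

  # One planted peak per ever-methylated gene, fixed across conditions.
  set.seed(stage_seed(config$seed, "peaks"))
  ever <- rowSums(meth) > 0
  peak_start <- rep(NA_real_, n)
  lo <- -config$window_up
  hi <- config$window_down - config$peak_width
  peak_start[ever] <- floor(runif(sum(ever), lo, hi + 1))
  peak_end <- peak_start + config$peak_width

  # Probe signal per condition.
  probes <- layout$probes
  gi <- match(probes$gene, layout$promoters$gene)
  track <- probes[, c("chrom", "start", "end", "probe_id")]
  in_peak <- !is.na(peak_start[gi]) &
    probes$rel_mid >= peak_start[gi] & probes$rel_mid < peak_end[gi]
  for (cond in conds) {
    set.seed(stage_seed(config$seed, paste0("signal_", cond)))
    v <- rnorm(nrow(probes), 0, config$background_sd)
    sh <- in_peak & meth[gi, cond]
    if (any(sh)) v[sh] <- v[sh] + rnorm(sum(sh), config$effect_mean, config$effect_sd)
    track[[cond]] <- v
  }

  truth <- data.frame(gene = layout$promoters$gene, stringsAsFactors = FALSE)
  for (cond in conds) truth[[paste0("meth_", cond)]] <- meth[, cond]
  truth$peak_start <- peak_start
  truth$peak_end <- peak_end
  truth$expr_direction <- direction
  truth$planted_lfc <- lfc
  truth$selective_group <- selective
  truth$concordant <- concordant
  attr(truth, "conditions") <- conds

  list(track = track, truth = truth, conditions = conds, layout = layout)
}

#' Simulate a normalized log2 expression matrix from planted truth
#'
#' Renders per-gene group means (baseline `N(8, 1.5)` log2 units) with the
#' planted effects from the truth table: selective genes are raised by
#' `log2(de_fold)` in their cell type, and the activated group mean equals the
#' quiescent mean plus the planted log2 fold change. Each group gets
#' `n_replicates` samples with `N(0, expr_noise_sd)` replicate noise.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_methylome()].
#' @return A list with `matrix` (genes x samples log2 expression) and
#'   `groups` (data frame mapping sample to group).
#' @export
simulate_expression <- function(config, truth) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  if (config$n_replicates < 2) stop("'n_replicates' must be >= 2")
  conds <- attr(truth, "conditions")
  if (is.null(conds)) stop("'truth' must come from simulate_methylome()")
  if (nrow(truth) != config$n_genes) stop("truth/config gene count mismatch")
  cts <- conds[-length(conds)]
  act <- conds[length(conds)]
  n <- nrow(truth)
  reps <- config$n_replicates

  set.seed(stage_seed(config$seed, "expression"))
  base <- rnorm(n, 8, 1.5)
  gm <- matrix(base, n, length(conds), dimnames = list(truth$gene, conds))
  for (ct in cts) {
    sel <- !is.na(truth$selective_group) & truth$selective_group == ct
    gm[sel, ct] <- gm[sel, ct] + log2(config$de_fold)
  }
  gm[, act] <- gm[, cts[1L]] + truth$planted_lfc

  samples <- paste(rep(conds, each = reps), seq_len(reps), sep = "_")
  mat <- gm[, rep(seq_along(conds), each = reps)] +
    matrix(rnorm(n * length(samples), 0, config$expr_noise_sd), n)
  colnames(mat) <- samples
  groups <- data.frame(sample = samples, group = rep(conds, each = reps),
                       stringsAsFactors = FALSE)
  list(matrix = mat, groups = groups)
}

#' Simulate a bisulfite clone-by-CpG binary matrix
#'
#' Independent Bernoulli entries: 1 = methylated CpG call in that clone.
#'
#' @param n_clones,n_cpgs Matrix dimensions.
#' @param meth_prob Per-entry methylation probability.
#' @param seed Optional seed.
#' @return Integer matrix (`n_clones` x `n_cpgs`) of 0/1 entries.
#' @export
simulate_bisulfite <- function(n_clones, n_cpgs, meth_prob, seed = NULL) {
  if (!is_count(n_clones) || !is_count(n_cpgs)) {
    stop("'n_clones' and 'n_cpgs' must be positive integers")
  }
  if (!is_fraction(meth_prob) || length(meth_prob) != 1L) {
    stop("'meth_prob' must be a single probability in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(n_clones * n_cpgs, 1L, meth_prob), n_clones, n_cpgs,
         dimnames = list(paste0("clone", seq_len(n_clones)),
                         paste0("CpG", seq_len(n_cpgs))))
}
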