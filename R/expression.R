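# Expression analysis: ANOVA screen, cell-type-selective genes, two-group
# differential expression, cross-list overlap.

group_mean_matrix <- function(mat, groups) {
  vapply(levels(groups), function(l) {
    rowMeans(mat[, groups == l, drop = FALSE])
  }, numeric(nrow(mat)))
}

check_groups <- function(mat, groups, min_levels = 2L) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != ncol(mat)) stop("'groups' must map one group per column")
  if (nlevels(groups) < min_levels) stop("need at least ", min_levels, " groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 replicates")
  groups
}

#' Per-gene one-way ANOVA screen
#'
#' One-way ANOVA on log2 expression values, vectorized across genes.
#' Genes with zero between-group sum of squares get `F = 0`, `p = 1`.
#'
#' @param mat Numeric matrix, genes x samples (log2 values), with rownames.
#' @param groups Factor (or coercible) assigning each column to a group;
#'   >= 2 groups with >= 2 replicates each.
#' @return Data frame: `gene`, `f`, `p`.
#' @export
anova_screen <- function(mat, groups) {
  mat <- as.matrix(mat)
  groups <- check_groups(mat, groups)
  n <- ncol(mat)
  g <- nlevels(groups)
  gm <- group_mean_matrix(mat, groups)
  sizes <- as.integer(table(groups)[levels(groups)])
  grand <- rowMeans(mat)
  ssb <- as.numeric((gm - grand)^2 %*% sizes)
  fitted <- gm[, as.integer(groups), drop = FALSE]
  ssw <- rowSums((mat - fitted)^2)
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  p <- pf(f, g - 1, n - g, lower.tail = FALSE)
  zero <- ssb <= .Machine$double.eps * pmax(1, rowSums(mat^2))
  f[zero] <- 0
  p[zero] <- 1
  data.frame(gene = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             f = f, p = p, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell-type-selective gene classification
#'
#' A gene is selective for group `g` iff its ANOVA p-value is at most `alpha`
#' and its linear fold change over EVERY other group is at least `fold`
#' (folds computed as `2^(mean_log2(g) - mean_log2(h))`). With `fold > 1` the
#' selective sets of different groups are disjoint by construction.
#'
#' @param mat Genes x samples log2 matrix.
#' @param groups Column group factor; >= 3 groups required.
#' @param fold Linear fold-change threshold (> 1; default 2).
#' @param alpha ANOVA p-value threshold (default 0.05).
#' @return List with `sets` (named list of selective genes per group) and
#'   `records` (per-gene data frame: group means, ANOVA p, `selective_for`).
#' @export
celltype_selective <- function(mat, groups, fold = 2, alpha = 0.05) {
  mat <- as.matrix(mat)
  groups <- check_groups(mat, groups, min_levels = 3L)
  if (fold <= 1) stop("'fold' must exceed 1")
  an <- anova_screen(mat, groups)
  gm <- group_mean_matrix(mat, groups)
  lab <- rep(NA_character_, nrow(mat))
  sets <- list()
  for (g in levels(groups)) {
    others <- gm[, setdiff(levels(groups), g), drop = FALSE]
    sel <- an$p <= alpha & (gm[, g] - apply(others, 1L, max)) >= log2(fold)
    sets[[g]] <- an$gene[sel]
    lab[sel] <- g
  }
  records <- data.frame(gene = an$gene, stringsAsFactors = FALSE)
  for (g in levels(groups)) records[[paste0("mean_", g)]] <- gm[, g]
  records$anova_p <- an$p
  records$selective_for <- lab
  list(sets = sets, records = records)
}

#' Two-group differential expression classification
#'
#' Per-gene two-sample t-test (equal-variance by default, Welch optional) on
#' log2 values, combined with a linear fold-change threshold. Direction is
#' toward the second factor level: `up` means fold >= `fold` and p <= `alpha`
#' in the second group relative to the first; `down` analogous; everything
#' else is `unchanged`. Benjamini-Hochberg adjusted p-values are emitted for
#' transparency but do not enter the classification.
#'
#' @param mat Genes x samples log2 matrix.
#' @param groups Two-level factor over the columns (>= 2 replicates each).
#' @param fold Linear fold-change cutoff (default 2).
#' @param alpha p-value cutoff (default 0.05).
#' @param var_equal Use the pooled-variance t-test (default) or Welch.
#' @return List with `records` (per-gene data frame: means, `log2_fc`,
#'   `fold_change` toward the second level, `t`, `p_value`, `p_adj`, `class`)
#'   and the `up`, `down`, `unchanged` gene vectors.
#' @export
differential_expression <- function(mat, groups, fold = 2, alpha = 0.05,
                                    var_equal = TRUE) {
  mat <- as.matrix(mat)
  groups <- check_groups(mat, groups)
  if (nlevels(groups) != 2L) stop("need exactly 2 groups")
  if (fold < 1) stop("'fold' must be >= 1")
  l1 <- levels(groups)[1L]
  l2 <- levels(groups)[2L]
  x1 <- mat[, groups == l1, drop = FALSE]
  x2 <- mat[, groups == l2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(mat))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  delta <- m2 - m1
  t <- delta / se
  t[se == 0 & delta == 0] <- 0
  p <- 2 * pt(-abs(t), df)
  p[is.nan(p)] <- 1  # zero variance, zero difference
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  fc <- 2^delta
  class <- rep("unchanged", nrow(mat))
  class[p <= alpha & fc >= fold] <- "up"
  class[p <= alpha & fc <= 1 / fold] <- "down"
  gene <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  records <- data.frame(gene = gene, stringsAsFactors = FALSE)
  records[[paste0("mean_", l1)]] <- m1
  records[[paste0("mean_", l2)]] <- m2
  records$log2_fc <- delta
  records$fold_change <- fc
  records$t <- t
  records$p_value <- p
  records$p_adj <- p.adjust(p, method = "BH")
  records$class <- class
  list(records = records,
       up = gene[class == "up"],
       down = gene[class == "down"],
       unchanged = gene[class == "unchanged"],
       groups = c(l1, l2))
}

#' Overlap between two gene lists across an ortholog mapping
#'
#' Maps `list_a` through a strict 1:1 symbol mapping (rows with duplicated
#' source or target symbols are an error), drops unmapped symbols (counted),
#' and reports the overlap with `list_b` as a percentage of each list.
#'
#' @param list_a,list_b Character vectors of gene symbols; `list_b` is taken
#'   to be in the target namespace of the mapping.
#' @param ortholog_map Optional data frame whose first two columns map
#'   `list_a` symbols to `list_b` symbols; `NULL` for identity.
#' @return List with `n_a`, `n_b`, `n_overlap`, `pct_of_a`, `pct_of_b` and
#'   `n_unmapped_a`.
#' @export
list_overlap <- function(list_a, list_b, ortholog_map = NULL) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  n_unmapped <- 0L
  if (!is.null(ortholog_map)) {
    if (ncol(ortholog_map) < 2L) stop("'ortholog_map' needs two columns (from, to)")
    from <- as.character(ortholog_map[[1L]])
    to <- as.character(ortholog_map[[2L]])
    if (anyDuplicated(from) || anyDuplicated(to)) {
      stop("many-to-many rows in 'ortholog_map': mapping must be 1:1")
    }
    mapped <- to[match(a, from)]
    n_unmapped <- sum(is.na(mapped))
    a <- mapped[!is.na(mapped)]
  }
  ov <- intersect(a, b)
  list(n_a = length(a), n_b = length(b), n_overlap = length(ov),
       pct_of_a = if (length(a)) 100 * length(ov) / length(a) else NA_real_,
       pct_of_b = if (length(b)) 100 * length(ov) / length(b) else NA_real_,
       n_unmapped_a = n_unmapped)
}
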