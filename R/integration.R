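# Methylation-expression concordance upon activation.

#' Identify genes with concordant methylation and expression changes
#'
#' In the default binary mode, a gene is concordant-up when it is up-regulated
#' and its promoter is methylated before but not after the transition (loss),
#' and concordant-down when it is down-regulated and gains promoter
#' methylation. The alternative `"delta_maxten"` mode thresholds the MaxTen
#' difference instead of requiring a binary call flip, capturing reduction
#' (not just abrogation) of methylation.
#'
#' @param de_records DE result from [differential_expression()] (the list or
#'   its `records` data frame; needs `gene`, `class`, `log2_fc`, `p_value`).
#' @param calls_before,calls_after Gene-level call tables from
#'   [call_promoter_methylation()] for the two conditions.
#' @param mode `"binary"` (call flip) or `"delta_maxten"`.
#' @param maxten_before,maxten_after Optional MaxTen tables ([maxten()]);
#'   attached as supporting values and required for `"delta_maxten"`. Genes
#'   with several promoters are collapsed to their maximum MaxTen.
#' @param min_delta Minimum MaxTen decrease (up genes) / increase (down
#'   genes) in `"delta_maxten"` mode.
#' @return List with `table` (all DE genes with methylation states,
#'   transition, concordant flag and supporting values) and `summary`
#'   (`n_de`, `n_concordant`, `n_concordant_up`, `n_concordant_down`,
#'   `n_excluded` DE genes absent from the methylation universe).
#' @export
concordant_genes <- function(de_records, calls_before, calls_after,
                             mode = c("binary", "delta_maxten"),
                             maxten_before = NULL, maxten_after = NULL,
                             min_delta = 0) {
  mode <- match.arg(mode)
  if (is.list(de_records) && !is.data.frame(de_records) &&
      !is.null(de_records$records)) {
    de_records <- de_records$records
  }
  stopifnot(is.data.frame(de_records),
            all(c("gene", "class") %in% names(de_records)))
  de <- de_records[de_records$class %in% c("up", "down"), , drop = FALSE]
  universe <- intersect(calls_before$gene, calls_after$gene)
  n_excluded <- sum(!de$gene %in% universe)
  de <- de[de$gene %in% universe, , drop = FALSE]

  mb <- calls_before$methylated[match(de$gene, calls_before$gene)]
  ma <- calls_after$methylated[match(de$gene, calls_after$gene)]
  transition <- ifelse(mb & !ma, "lost", ifelse(!mb & ma, "gained", "stable"))

  collapse_maxten <- function(mx) {
    if (is.null(mx)) return(NULL)
    agg <- tapply(mx$maxten, mx$gene, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    as.numeric(agg[de$gene])
  }
  mxb <- collapse_maxten(maxten_before)
  mxa <- collapse_maxten(maxten_after)

  if (mode == "binary") {
    conc <- (de$class == "up" & transition == "lost") |
      (de$class == "down" & transition == "gained")
  } else {
    if (is.null(mxb) || is.null(mxa)) {
      stop("'delta_maxten' mode needs maxten_before and maxten_after")
    }
    dm <- mxb - mxa
    conc <- (de$class == "up" & !is.na(dm) & dm >= min_delta) |
      (de$class == "down" & !is.na(dm) & -dm >= min_delta)
  }

  tab <- data.frame(gene = de$gene, expr_class = de$class,
                    meth_before = mb, meth_after = ma,
                    meth_transition = transition, concordant = conc,
                    stringsAsFactors = FALSE)
  if (!is.null(de$log2_fc)) tab$log2_fc <- de$log2_fc
  if (!is.null(de$p_value)) tab$p_value <- de$p_value
  if (!is.null(mxb)) tab$maxten_before <- mxb
  if (!is.null(mxa)) tab$maxten_after <- mxa
  list(table = tab,
       summary = list(n_de = nrow(tab),
                      n_concordant = sum(conc),
                      n_concordant_up = sum(conc & de$class == "up"),
                      n_concordant_down = sum(conc & de$class == "down"),
                      n_excluded = n_excluded))
}
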