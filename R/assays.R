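# Single-locus assay calculators: ChIP-qPCR percent input and bisulfite
# clone-matrix summaries.

#' ChIP-qPCR enrichment as percent of input
#'
#' Adjusts the input Ct for the fraction of chromatin used as input
#' (`Ct_input - log_E(1 / input_fraction)`) and converts the Ct difference to
#' a percentage: `100 * E^(adjusted_input_Ct - Ct_IP)`, with amplification
#' efficiency `E` (2 = perfect doubling per cycle). Vectorized.
#'
#' @param ct_ip,ct_input Positive Ct values for the IP and input reactions.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1]
#'   (default 0.1, i.e. a 1/10 input).
#' @param efficiency Per-cycle amplification factor (default 2).
#' @return Percent-input enrichment values.
#' @export
#' @examples
#' percent_input(25 - log2(10), 25)  # 100% by construction
percent_input <- function(ct_ip, ct_input, input_fraction = 0.1,
                          efficiency = 2) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("'input_fraction' must lie in (0, 1]")
  }
  if (any(efficiency <= 1)) stop("'efficiency' must exceed 1")
  if (any(ct_ip <= 0) || any(ct_input <= 0)) stop("Ct values must be positive")
  adjusted <- ct_input - log(1 / input_fraction, base = efficiency)
  100 * efficiency^(adjusted - ct_ip)
}

#' Summarize a bisulfite clone-by-CpG matrix
#'
#' Per-CpG percent methylation (column means), overall percent, and one
#' lollipop-style pattern string per clone (filled circle = methylated,
#' open circle = unmethylated).
#'
#' @param m Non-empty binary matrix, clones x CpGs (1 = methylated).
#' @return List with `per_cpg_pct`, `overall_pct`, `patterns`, `n_clones`,
#'   `n_cpgs`.
#' @export
bisulfite_summary <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L) stop("empty clone matrix")
  if (!all(m %in% c(0, 1))) stop("entries must be 0/1")
  patterns <- apply(m, 1L, function(r) {
    paste(ifelse(r == 1, "\u25cf", "\u25cb"), collapse = "")
  })
  list(per_cpg_pct = 100 * colMeans(m),
       overall_pct = 100 * mean(m),
       patterns = unname(patterns),
       n_clones = nrow(m),
       n_cpgs = ncol(m))
}
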