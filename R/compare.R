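# Set-level comparisons of methylated-gene sets across cell types/conditions.

#' Venn region counts for labelled gene sets
#'
#' Counts, for every non-empty combination of set memberships, the elements
#' belonging to exactly those sets. Counts sum to the size of the union.
#'
#' @param sets Named list (unique labels) of >= 2 character vectors.
#' @return Data frame with `combo` (labels joined by `&`) and `count`,
#'   covering all non-empty combinations (including zero counts).
#' @export
venn_counts <- function(sets) {
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) stop("sets must be named")
  if (anyDuplicated(labels)) stop("duplicate set labels")
  if (length(sets) < 2L) stop("need at least two sets")
  sets <- lapply(sets, unique)
  elems <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) elems %in% s, logical(length(elems)))
  if (length(elems) == 1L) member <- matrix(member, nrow = 1L)
  n <- length(sets)
  combos <- lapply(seq_len(2L^n - 1L), function(mask) {
    as.logical(bitwAnd(mask, 2L^(seq_len(n) - 1L)))
  })
  combo_lab <- vapply(combos, function(b) paste(labels[b], collapse = "&"), "")
  counts <- vapply(combos, function(b) {
    if (length(elems) == 0L) return(0L)
    sum(apply(member, 1L, function(r) identical(unname(r), b)))
  }, integer(1))
  data.frame(combo = combo_lab, count = counts, stringsAsFactors = FALSE)
}

#' Pairwise sharing matrix between gene sets
#'
#' Entry `(row r, column c)` is the percentage of set `c` also present in set
#' `r`: `100 * |S_c intersect S_r| / |S_c|`. Asymmetric in general; diagonal
#' is 100. Empty sets give an `NA` column with a warning.
#'
#' @param sets Named list of character vectors.
#' @return Numeric matrix of percentages with set labels as dimnames.
#' @export
sharing_matrix <- function(sets) {
  labels <- names(sets)
  if (is.null(labels) || anyDuplicated(labels)) stop("sets must have unique names")
  sets <- lapply(sets, unique)
  m <- matrix(NA_real_, length(sets), length(sets),
              dimnames = list(labels, labels))
  for (cc in seq_along(sets)) {
    nc <- length(sets[[cc]])
    if (nc == 0L) {
      warning("empty set '", labels[cc], "': sharing undefined for its column")
      next
    }
    for (rr in seq_along(sets)) {
      m[rr, cc] <- 100 * length(intersect(sets[[rr]], sets[[cc]])) / nc
    }
  }
  m
}

#' Summarize a methylation transition between two conditions
#'
#' Splits the before/after methylated-gene sets into lost (`before \\ after`),
#' gained (`after \\ before`) and retained (intersection) genes.
#' `pct_lost = 100 * n_lost / n_before` and
#' `pct_gained = 100 * n_gained / n_after`, rounded to the nearest integer;
#' the raw fractions are retained alongside.
#'
#' @param set_before,set_after Character vectors of methylated genes.
#' @return List with the three gene vectors, their counts, `n_before`,
#'   `n_after`, integer `pct_lost` / `pct_gained` and raw `frac_lost` /
#'   `frac_gained` (`NA` with a warning when the reference set is empty).
#' @export
transition_summary <- function(set_before, set_after) {
  b <- unique(set_before)
  a <- unique(set_after)
  lost <- setdiff(b, a)
  gained <- setdiff(a, b)
  retained <- intersect(b, a)
  frac_lost <- if (length(b)) length(lost) / length(b) else NA_real_
  frac_gained <- if (length(a)) length(gained) / length(a) else NA_real_
  if (length(b) == 0L) warning("empty before-set: pct_lost undefined")
  if (length(a) == 0L) warning("empty after-set: pct_gained undefined")
  list(lost = lost, gained = gained, retained = retained,
       n_before = length(b), n_after = length(a),
       n_lost = length(lost), n_gained = length(gained),
       n_retained = length(retained),
       pct_lost = if (is.na(frac_lost)) NA_real_ else round(100 * frac_lost),
       pct_gained = if (is.na(frac_gained)) NA_real_ else round(100 * frac_gained),
       frac_lost = frac_lost, frac_gained = frac_gained)
}

#' Cross-study comparison in a restricted promoter window
#'
#' Re-derives gene-level methylation calls using a narrower promoter window
#' (default -2.2 kb to +0.5 kb around the TSS) from each sample's peaks, then
#' compares the resulting methylated-gene sets with [sharing_matrix()]. The
#' restricted call set of every sample is a subset of its full-window set.
#'
#' @param peaks_per_set Named list of peak tables ([call_peaks()]).
#' @param promoters Promoter annotation (gene, chrom, strand, tss).
#' @param up_bp,down_bp Restricted window extent (bp).
#' @return List with `calls` (per sample), `sets` (methylated genes per
#'   sample) and `sharing` (percentage matrix).
#' @export
restricted_window_comparison <- function(peaks_per_set, promoters,
                                         up_bp = 2200, down_bp = 500) {
  if (is.null(names(peaks_per_set))) stop("'peaks_per_set' must be named")
  prom <- promoter_windows(promoters, up_bp, down_bp)
  calls <- lapply(peaks_per_set, call_promoter_methylation, promoters = prom)
  sets <- lapply(calls, function(cc) cc$gene[cc$methylated])
  list(calls = calls, sets = sets, sharing = sharing_matrix(sets))
}
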