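# Methylation calls: peaks, gene-level calls, MaxTen, positional classes.

#' Call methylation peaks from a scored probe track
#'
#' Candidate probes (`p <= p_cutoff`) are grouped into maximal runs of
#' consecutive candidates on the same chromosome - no intervening
#' non-candidate probe, successive midpoints at most `max_gap_bp` apart.
#' Runs of at least `min_peak_probes` probes become peaks spanning the first
#' probe's start to the last probe's end.
#'
#' @param scored Track scored with [windowed_ks_score()] (needs a `p` column).
#' @param p_cutoff Per-probe significance cutoff (default 0.01).
#' @param min_peak_probes Minimum probes per peak (default 2).
#' @param max_gap_bp Maximum midpoint gap between successive candidate probes.
#' @return Data frame of peaks: `chrom`, `start`, `end` (0-based half-open),
#'   `n_probes`, `min_p`.
#' @export
call_peaks <- function(scored, p_cutoff = 0.01, min_peak_probes = 2,
                       max_gap_bp = 500) {
  stopifnot(is.data.frame(scored))
  if (is.null(scored$p)) stop("no 'p' column: score the track first")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_probes = integer(), min_p = numeric(),
                      stringsAsFactors = FALSE)
  cand <- which(scored$p <= p_cutoff)
  if (length(cand) == 0L) return(empty)
  mid <- (scored$start + scored$end) / 2
  ch <- as.integer(chrom_factor(scored$chrom))
  new_run <- c(TRUE, diff(cand) != 1L |
                 ch[cand[-1L]] != ch[cand[-length(cand)]] |
                 (mid[cand[-1L]] - mid[cand[-length(cand)]]) > max_gap_bp)
  run <- cumsum(new_run)
  keep <- as.integer(names(which(table(run) >= min_peak_probes)))
  if (length(keep) == 0L) return(empty)
  out <- do.call(rbind, lapply(keep, function(r) {
    i <- cand[run == r]
    data.frame(chrom = scored$chrom[i[1L]],
               start = min(scored$start[i]),
               end = max(scored$end[i]),
               n_probes = length(i),
               min_p = min(scored$p[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call gene-level promoter methylation from peaks
#'
#' A gene is methylated iff at least one peak shares at least one base with
#' its half-open promoter window. Genes with several annotated promoters are
#' collapsed to "methylated if any promoter is methylated".
#'
#' @param peaks Peak table from [call_peaks()].
#' @param promoters Promoter annotation with genomic `window_start` /
#'   `window_end` columns (see [promoter_windows()] / [read_promoters()]).
#' @return Data frame with one row per gene: `gene`, `methylated`, `n_peaks`,
#'   `peak_ids` (comma-separated row indices into `peaks`).
#' @export
call_promoter_methylation <- function(peaks, promoters) {
  stopifnot(is.data.frame(peaks), is.data.frame(promoters))
  if (!all(c("window_start", "window_end") %in% names(promoters))) {
    stop("promoters lack window columns; apply promoter_windows() first")
  }
  genes <- unique(promoters$gene)
  hit_peaks <- vector("list", nrow(promoters))
  if (nrow(peaks) > 0L) {
    pk <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L, peaks$end))
    pr <- GenomicRanges::GRanges(promoters$chrom,
                                 IRanges::IRanges(promoters$window_start + 1L,
                                                  promoters$window_end))
    hits <- GenomicRanges::findOverlaps(pr, pk)
    hl <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    hit_peaks[as.integer(names(hl))] <- hl
  }
  by_gene <- split(hit_peaks, factor(promoters$gene, levels = genes))
  pk_ids <- lapply(by_gene, function(x) sort(unique(unlist(x))))
  data.frame(gene = genes,
             methylated = lengths(pk_ids) > 0L,
             n_peaks = lengths(pk_ids),
             peak_ids = vapply(pk_ids, paste, "", collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' MaxTen promoter methylation intensity
#'
#' Mean of the `n_top` (default 10) largest log2 ratios among the probes whose
#' midpoint lies in the promoter window. Promoters with fewer than `n_top`
#' probes get the mean of all present values and a low-coverage flag; with no
#' probes, `NA`.
#'
#' @param track Probe track with the sample column.
#' @param promoters Promoter annotation with genomic window columns.
#' @param sample Sample column name.
#' @param n_top Number of top probes averaged.
#' @return Data frame: `gene`, `maxten`, `n_probes`, `low_coverage` (one row
#'   per promoter; genes with several promoters repeat).
#' @export
maxten <- function(track, promoters, sample, n_top = 10) {
  stopifnot(is.data.frame(track), is.data.frame(promoters))
  if (!sample %in% names(track)) stop("unknown sample: ", sample)
  if (!all(c("window_start", "window_end") %in% names(promoters))) {
    stop("promoters lack window columns; apply promoter_windows() first")
  }
  v <- track[[sample]]
  mid <- (track$start + track$end) / 2
  res <- vapply(seq_len(nrow(promoters)), function(i) {
    inw <- track$chrom == promoters$chrom[i] &
      mid >= promoters$window_start[i] & mid < promoters$window_end[i]
    vv <- v[inw]
    if (length(vv) == 0L) return(c(NA_real_, 0))
    c(mean(sort(vv, decreasing = TRUE)[seq_len(min(n_top, length(vv)))]),
      length(vv))
  }, numeric(2))
  data.frame(gene = promoters$gene,
             maxten = res[1L, ],
             n_probes = as.integer(res[2L, ]),
             low_coverage = res[2L, ] < n_top,
             stringsAsFactors = FALSE)
}

#' Classify promoter methylation position relative to the TSS
#'
#' Maps each overlapping peak into strand-aware promoter-relative coordinates
#' and reports the set of regions it touches. Default regions partition the
#' -3 kb / +1 kb window into upstream `[-3000, -500)`, TSS `[-500, +500)` and
#' downstream `[+500, +1000)`.
#'
#' @param peaks Peak table ([call_peaks()]).
#' @param promoters Promoter annotation (with window columns) restricted to
#'   methylated genes; an unmethylated promoter (no overlapping peak) is an
#'   error because its positional class is undefined.
#' @param breaks Increasing promoter-relative region boundaries (length
#'   `length(labels) + 1`).
#' @param labels Region labels.
#' @return Data frame: `gene`, `class` (comma-separated region set),
#'   `upstream_only`.
#' @export
classify_position <- function(peaks, promoters,
                              breaks = c(-3000, -500, 500, 1000),
                              labels = c("upstream", "TSS", "downstream")) {
  stopifnot(length(breaks) == length(labels) + 1L, !is.unsorted(breaks, strictly = TRUE))
  if (!all(c("window_start", "window_end", "strand", "tss") %in% names(promoters))) {
    stop("promoters need strand, tss and window columns")
  }
  if (nrow(peaks) == 0L) stop("no peaks: positional class is defined only for methylated promoters")
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  pr <- GenomicRanges::GRanges(promoters$chrom,
                               IRanges::IRanges(promoters$window_start + 1L,
                                                promoters$window_end))
  hits <- GenomicRanges::findOverlaps(pr, pk)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  miss <- setdiff(seq_len(nrow(promoters)), unique(qh))
  if (length(miss)) {
    stop("unmethylated promoter(s) passed to classify_position(): ",
         paste(utils::head(promoters$gene[miss], 5L), collapse = ", "))
  }
  cls <- character(nrow(promoters))
  for (i in unique(qh)) {
    js <- sh[qh == i]
    if (promoters$strand[i] == "+") {
      rs <- peaks$start[js] - promoters$tss[i]
      re <- peaks$end[js] - promoters$tss[i]
    } else {
      rs <- promoters$tss[i] - peaks$end[js] + 1
      re <- promoters$tss[i] - peaks$start[js] + 1
    }
    touched <- vapply(seq_along(labels), function(r) {
      any(rs < breaks[r + 1L] & re > breaks[r])
    }, logical(1))
    cls[i] <- paste(labels[touched], collapse = ",")
  }
  data.frame(gene = promoters$gene, class = cls,
             upstream_only = cls == labels[1L],
             stringsAsFactors = FALSE)
}

#' Chi-square test for a shift in positional class composition
#'
#' Pearson chi-square (no continuity correction) on the k x 2 table of class
#' counts from two conditions.
#'
#' @param class_counts_a,class_counts_b Non-negative count vectors over the
#'   same class labels.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
position_shift_test <- function(class_counts_a, class_counts_b) {
  a <- class_counts_a
  b <- class_counts_b
  if (length(a) != length(b) || length(a) < 2L) {
    stop("need two count vectors of equal length >= 2")
  }
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    stop("count vectors must share the same class labels")
  }
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  tab <- cbind(a = a, b = b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("zero expected count; merge sparse categories before testing")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
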