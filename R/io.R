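# On-disk formats: probe tracks (TSV), promoters (BED6), peaks (BED5),
# expression matrices and group maps (TSV).

#' Read a probe track TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `start`, `end`,
#' `probe_id` followed by one numeric log2-ratio column per sample.
#' Coordinates are 0-based half-open. Malformed rows are rejected with their
#' line number; duplicate probe ids are an error. An unsorted track is
#' re-sorted with a warning.
#'
#' @param path File path.
#' @return Probe track data frame.
#' @export
read_probe_track <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  req <- c("chrom", "start", "end", "probe_id")
  if (!all(req %in% names(df))) {
    stop("probe track needs columns: ", paste(req, collapse = ", "))
  }
  samples <- setdiff(names(df), req)
  if (length(samples) == 0L) stop("probe track has no sample columns")
  bad_line <- function(col, what) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | (what == "coord" & (x < 0 | x != round(x))))
    if (length(bad)) {
      stop("malformed row at line ", bad[1L] + 1L, ": bad '", col, "' value")
    }
    x
  }
  df$start <- as.integer(bad_line("start", "coord"))
  df$end <- as.integer(bad_line("end", "coord"))
  for (s in samples) df[[s]] <- bad_line(s, "ratio")
  if (any(df$end <= df$start)) {
    stop("malformed row at line ",
         which(df$end <= df$start)[1L] + 1L, ": end <= start")
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id: ", df$probe_id[duplicated(df$probe_id)][1L])
  }
  ch <- chrom_factor(df$chrom)
  if (is.unsorted(as.integer(ch)) ||
      any(unlist(tapply(df$start, ch, is.unsorted, simplify = FALSE)))) {
    warning("probe track was not position-sorted; sorting")
    df <- df[order(chrom_factor(df$chrom), df$start), ]
    rownames(df) <- NULL
  }
  df
}

#' Write a probe track TSV
#'
#' @param track Probe track data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read promoter annotations from a BED6 file
#'
#' The TSS is the BED `start` for `+` genes and `end - 1` for `-` genes.
#' Strand-aware promoter windows (`[-window_up, +window_down)` around the
#' TSS) are computed via [promoter_windows()]. A file without a strand column
#' is rejected.
#'
#' @param path BED6 file path.
#' @param window_up,window_down Promoter window extent in bp.
#' @return Data frame: `gene`, `chrom`, `strand`, `tss`, `window_start`,
#'   `window_end`.
#' @export
read_promoters <- function(path, window_up = 3000, window_down = 1000) {
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BED6 with a strand column is required")
  if (!all(df[[6L]] %in% c("+", "-"))) {
    stop("strand column must be '+' or '-' for every promoter")
  }
  out <- data.frame(gene = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    strand = df[[6L]],
                    tss = ifelse(df[[6L]] == "+", df[[2L]], df[[3L]] - 1L),
                    stringsAsFactors = FALSE)
  promoter_windows(out, window_up, window_down)
}

#' Write promoter annotations as BED6
#'
#' Each promoter is written as the single-base TSS interval `[tss, tss + 1)`,
#' which round-trips the TSS under both strand conventions.
#'
#' @param promoters Promoter data frame (`gene`, `chrom`, `strand`, `tss`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  bed <- data.frame(promoters$chrom, promoters$tss, promoters$tss + 1L,
                    promoters$gene, 0L, promoters$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write peaks as BED5
#'
#' Score is `-10 * log10(min probe p)`, rounded and capped at 1000.
#'
#' @param peaks Peak table from [call_peaks()].
#' @param path Output path.
#' @param name_prefix Peak name prefix.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path, name_prefix = "peak") {
  score <- if (nrow(peaks)) {
    pmin(1000, round(-10 * log10(pmax(peaks$min_p, .Machine$double.xmin))))
  } else integer()
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    if (nrow(peaks)) paste0(name_prefix, seq_len(nrow(peaks))) else character(),
                    score)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write a log2 expression matrix TSV
#'
#' The file has a `gene` first column followed by one numeric column per
#' sample.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (names(df)[1L] != "gene") stop("first column must be 'gene'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("expression values must be numeric")
  rownames(m) <- df$gene
  m
}

#' @rdname read_expression_matrix
#' @param mat Numeric matrix with gene rownames.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
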