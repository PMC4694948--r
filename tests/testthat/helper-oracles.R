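# Independent brute-force oracles used across tests.

# One-sided KS D+ by exhaustive evaluation over all pooled points.
brute_d_plus <- function(w, b) {
  xs <- c(w, b)
  max(0, max(vapply(xs, function(x) mean(b <= x) - mean(w <= x), numeric(1))))
}

# Naive peak scan: walk candidate probes, open a run whenever continuity
# breaks (index gap, chromosome change, midpoint gap), keep long-enough runs.
brute_peaks <- function(chrom, start, end, p, p_cutoff = 0.01,
                        min_peak_probes = 2, max_gap_bp = 500) {
  mid <- (start + end) / 2
  runs <- list()
  cur <- integer()
  for (i in seq_along(p)) {
    if (p[i] <= p_cutoff) {
      if (length(cur) &&
          (chrom[i] != chrom[cur[length(cur)]] ||
           i != cur[length(cur)] + 1L ||
           mid[i] - mid[cur[length(cur)]] > max_gap_bp)) {
        runs[[length(runs) + 1L]] <- cur
        cur <- integer()
      }
      cur <- c(cur, i)
    } else if (length(cur)) {
      runs[[length(runs) + 1L]] <- cur
      cur <- integer()
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs <- Filter(function(r) length(r) >= min_peak_probes, runs)
  if (!length(runs)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_probes = integer(), min_p = numeric()))
  }
  do.call(rbind, lapply(runs, function(r) {
    data.frame(chrom = chrom[r[1]], start = min(start[r]), end = max(end[r]),
               n_probes = length(r), min_p = min(p[r]),
               stringsAsFactors = FALSE)
  }))
}

# Membership-enumeration Venn oracle.
brute_venn <- function(sets) {
  sets <- lapply(sets, unique)
  labels <- names(sets)
  elems <- unique(unlist(sets))
  out <- list()
  for (e in elems) {
    inset <- labels[vapply(sets, function(s) e %in% s, logical(1))]
    key <- paste(inset, collapse = "&")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small single-chromosome probe track at fixed spacing.
toy_track <- function(values, spacing = 100, chrom = "chr1", len = 50) {
  n <- length(values)
  start <- seq(0L, by = as.integer(spacing), length.out = n)
  data.frame(chrom = chrom, start = start, end = start + as.integer(len),
             probe_id = sprintf("p%04d", seq_len(n)), s1 = values,
             stringsAsFactors = FALSE)
}
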