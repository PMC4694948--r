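# Internal helpers shared across modules.

# Deterministic per-stage seed derived from the master seed, kept < 2^31.
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((as.numeric(seed) %% 2096993 * 7919 + h * 131) %% 2147483646) + 1L
}

# Chromosome factor preserving order of first appearance (track block order).
chrom_factor <- function(chrom) factor(chrom, levels = unique(chrom))

# sample() without the length-1 surprise.
resample <- function(x, k) x[sample.int(length(x), k)]

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x > 0 && x == round(x)

is_fraction <- function(x) is.numeric(x) && !anyNA(x) && all(x >= 0 & x <= 1)

# Activated-condition label: qHSC -> aHSC, otherwise prefix "a".
activated_label <- function(x) {
  if (grepl("^q", x)) sub("^q", "a", x) else paste0("a", x)
}
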