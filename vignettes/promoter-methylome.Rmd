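---
title: "Inferring promoter methylomes from MeDIP tiling arrays"
author: "promedip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring promoter methylomes from MeDIP tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promedip)
```

## The problem

Methylated-DNA immunoprecipitation followed by promoter tiling-array
hybridization (MeDIP-chip) measures DNA methylation as a log2(MeDIP/input)
ratio at each probe of a window around every annotated transcription start
site (TSS). Turning those probe-level ratios into biology requires a chain of
inferences: which probes carry signal, which runs of probes form a methylated
region, which promoters count as methylated, how intensely, where relative to
the TSS — and, once two conditions or several cell types are profiled, how
the methylated-promoter sets compare and whether methylation changes track
expression changes. `promedip` implements that chain for studies of purified
liver cell types (hepatocytes, liver sinusoidal endothelial cells, hepatic
stellate cells) and of the quiescent-to-activated stellate-cell transition
that drives liver fibrosis, but every stage is generic tiling-array
arithmetic.

## The probe score: a windowed one-sided KS test

Each probe is scored by asking whether the log2 ratios in its local window
are stochastically larger than the rest of the array. For a window sample
$w$ (size $n_1$) and background $b$ (size $n_2$, all probes outside the
window), the one-sided statistic is

$$D^+ = \sup_x\left[F_b(x) - F_w(x)\right]$$

evaluated over the pooled sample points with right-continuous empirical
CDFs, and the probe's score is the asymptotic p-value

$$p = \exp(-2\,n_\mathrm{eff}\,{D^+}^2),\qquad
  n_\mathrm{eff} = \frac{n_1 n_2}{n_1 + n_2},$$

clipped into $(0, 1]$. Choices that matter:

* **Window width** (`window_bp`, default 750 bp). At the default 100 bp probe
  spacing this puts ~7 probes in an interior window, the scale at which a
  planted few-hundred-bp methylated region dominates its window. Windows
  holding fewer than `min_probes` (default 4) probes get $p = 1$ and a
  low-coverage flag: a KS test on fewer points is noise.
* **Background = the whole array minus the window**, not a local flank. The
  null being tested is "this window looks like the array-wide signal
  distribution". Because the background also contains truly methylated
  probes, the test is slightly conservative, which is the safe direction.
* **The asymptotic p-value is used as a ranking score**, not as a calibrated
  tail probability. On a pure-noise array the realized rate of $p \le 0.01$
  probes sits near 0.005 (the acceptance suite asserts the band
  $[0.001, 0.03]$): the closed form is conservative for window-sized samples.
  No probe-level multiple-testing correction is applied — the peak criterion
  below is the error-control device.
* **Edge behaviour.** A probe at the edge of a shifted run has a half-shifted
  window; its $D^+$ is capped near $k_\text{shifted}/k$ and its p-value
  straddles 0.01 by arithmetic, not by noise. Detection of region edges is
  therefore delegated to the peak criterion, which only needs the interior
  probes.

The implementation evaluates $D^+$ in a vectorized pass per window size
(row-sorted window values, cumulative counts against the sorted array), and
is tested probe-by-probe against the standalone `ks_one_sided()` and against
brute-force enumeration of the supremum for all sample sizes up to 8.

## Peaks, gene calls, MaxTen, position

A **peak** is a maximal run of at least `min_peak_probes = 2` consecutive
candidate probes ($p \le 0.01$) with no intervening non-candidate probe and
successive midpoints at most `max_gap_bp = 500` apart. The strict
no-gap-probe reading is deliberate: two independently significant adjacent
probes are the minimal reproducible evidence unit, and 500 bp prevents runs
from jumping tiling gaps between promoters.

A **gene is methylated** iff any peak overlaps (shares at least one base
with) its half-open promoter window, by default $[-3000, +1000)$ around the
TSS, strand-aware. Genes with several annotated promoters are collapsed to
"methylated if any".

**MaxTen** summarizes a promoter's methylation intensity as the mean of its
10 largest probe ratios. Averaging the 10 highest (rather than 10
consecutive) probes is robust to single-probe spikes and insensitive to probe
order; promoters with fewer than 10 probes are averaged over what is present
and flagged.

**Positional classes** partition the promoter window into upstream
$[-3000, -500)$, TSS $[-500, +500)$ and downstream $[+500, +1000)$ and
report, per methylated gene, the set of regions its peaks touch. The
$\pm 500$ bp TSS flank is a convention, not a measurement; all bounds are
arguments. Because classes are sets, both an exclusive ("upstream only") and
an inclusive reading can be recovered downstream, and a Pearson chi-square on
the class-count table (`position_shift_test()`) compares two conditions.

## Set comparisons and concordance

`venn_counts()`, `sharing_matrix()` and `transition_summary()` are exact set
arithmetic with the identities $|B| = \text{lost} + \text{retained}$ and
$|A| = \text{gained} + \text{retained}$ asserted property-style in the tests.
Sharing percentages are column-relative ($100\,|S_c \cap S_r|/|S_c|$), hence
asymmetric; transition percentages are reported rounded to integers with the
raw fractions retained. `restricted_window_comparison()` re-derives calls in
a narrower window (default $-2.2$ kb to $+0.5$ kb) for comparisons against
older datasets scored on that window; restriction can only shrink call sets.

Expression analysis follows the classical array recipe: per-gene one-way
ANOVA screen across three cell types, selectivity = ANOVA $p \le 0.05$ plus
a $\ge 2$-fold higher linear mean than *every* other group (which makes
selective sets disjoint by construction); two-condition differential
expression = pooled-variance t-test plus the 2-fold cutoff, with
Benjamini-Hochberg columns emitted for transparency but not used in the
classification, matching the cut-off-based convention of array-era studies.
Folds are computed as $2^{\bar{x}_g - \bar{x}_h}$ on group means of log2
values. Welch's test is available by flag.

A gene is **concordant** when its expression and promoter methylation move
oppositely upon activation: up-regulated and demethylated (call lost), or
down-regulated and de-novo methylated (call gained). The binary-flip
definition matches the peak-based call framework; a `delta_maxten` mode
instead thresholds the MaxTen difference, capturing *reduction* rather than
abrogation of methylation.

## The synthetic-data generator

The generator exists so every stage is testable with known truth and no
array data. It emulates:

* promoter tiling geometry: 40 probes of 50 bp at 100 bp spacing across
  $[-3000, +1000)$, strand-aware, genes 10 kb apart;
* background probe noise: additive Gaussian ($\sigma = 0.3$ log2 units) —
  the simplest model matching log-ratio data; heavier tails are deliberately
  not modelled;
* methylated promoters: one planted region of 800 bp per ever-methylated
  gene, placed uniformly at random within the window (so the positional
  classifier is exercised over all three regions), with an additive
  $N(2.0, 0.25)$ shift on the probes inside;
* cross-cell-type sharing: a core fraction (0.21) methylated in all three
  cell types plus independent per-type extras up to the per-type fractions
  (0.28 / 0.35 / 0.36);
* the activation transition: each quiescently methylated promoter is lost
  with probability 0.53; each unmethylated one gained with probability
  0.163, tuned so the novel fraction of the activated set is ~0.47;
* an expression program: 3.6% of genes up, 6.1% down at a planted 4-fold,
  50 selective genes per cell type, 3 replicates per group with
  $N(0, 0.25)$ replicate noise on a $N(8, 1.5)$ baseline;
* concordance: 20% of planted DE genes get the opposing methylation
  transition forced. Non-flagged DE genes are forced *non*-concordant (their
  activated state is reset to the quiescent state when a chance flip would
  make them concordant), so the truth flag equals the definitional set
  exactly — this is what lets the concordance recovery test demand exact
  equality under truth-substituted calls.

All randomness flows from one master seed through deterministic per-stage
sub-seeds, so outputs are byte-identical across runs. What the generator does
**not** emulate: sequence composition and CpG density, hybridization physics,
amplification bias, spatially correlated noise, and donor-to-donor
variability. Passing recovery tests therefore demonstrate that the inference
chain is correct under its own signal model, not that the thresholds are
optimal for any particular array platform.

## Numerical and degenerate-input choices

* p-values are clipped to $[\,2^{-1074}, 1]$; $D^+$ is floored at 0.
* Ties in the KS statistic are handled by evaluating both one-sided limits
  at every window value against exact $\le$ / $<$ counts, so integer-valued
  toy inputs reproduce the enumeration oracle bit-for-bit.
* Zero-variance genes: ANOVA returns $F = 0, p = 1$ when the between-group
  sum of squares vanishes; the t-test returns $t = 0, p = 1$ when both
  difference and pooled variance vanish.
* A `p_cutoff` of 0 yields zero peaks and empty, but structurally valid,
  downstream tables; empty sets make sharing/transition percentages `NA`
  with a warning rather than an error.
* Chi-square with a zero expected count stops with advice to merge
  categories.
* Unsorted probe tracks are sorted on read with a warning; malformed rows
  and duplicate probe ids are rejected with line numbers.

## Problem sizes used by the test and acceptance runs

The shipped suites run at desk scale, chosen to make binomial tolerances
meaningful while keeping the full suite under a minute: 100,000 probes
(2,500 genes) for null calibration, 500 genes for call recovery
(sensitivity $\ge 0.90$, false-positive rate $\le 0.05$ at a 2.0 log2
effect), 1,000-2,000 genes for concordance and expression calibration, and
1,000 random set pairs for the set-identity properties.
`scripts/acceptance.R` re-runs these from scratch against the installed
package and writes the resulting rates as JSON.

## Known limitations

* The windowed test's p-values are approximate and intentionally used only
  through the rank-like cutoff 0.01; absolute methylation percentages cannot
  be inferred from MeDIP ratios and are not attempted.
* Gene identity is the annotation's symbol; transcript-level resolution is
  out of scope.
* The DE module assumes a pre-normalized log2 matrix; normalization,
  probe-set summarization and batch correction belong upstream.
* The concordance table reports discordant genes but offers no mechanism for
  them (enhancer-level regulation, hydroxymethylation ambiguity of
  MeDIP, ...).

## A worked miniature

```{r example, eval = FALSE}
library(promedip)
res <- run_pipeline(sim_config(n_genes = 200, seed = 7))
res$transition$pct_lost     # % of quiescently methylated promoters lost
res$concordance$summary     # concordant-up / concordant-down counts
```
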