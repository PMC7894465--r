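---
title: "Screening probe-level expression arrays for reprogramming master regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening probe-level expression arrays for reprogramming master regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The screening problem

Direct reprogramming converts one differentiated cell type into another by
forced expression of a small set of transcription factors ("master
regulators"). Finding that set by trial transduction is slow; a comparative
expression screen narrows the candidates first. The design implemented here
compares four cell populations on expression microarrays:

* **source** — the cells to be reprogrammed (e.g. dedifferentiated fat,
  DFAT, cells);
* **source-origin** — the population the source cells derive from (mature
  adipocytes), used to remove differentiation regulators the source lineage
  already shares with the target;
* **target** — the desired mature cell type (hepatocytes);
* **target-stem** — the target lineage's stem/progenitor population
  (resident liver stem cells), used to restrict candidates to *commitment*
  factors rather than mature-function genes.

A candidate master regulator must be (i) strongly up-regulated in target
and target-stem cells relative to *both* source populations, (ii) reliably
*detected* (Present) in every target and target-stem replicate, (iii)
undetected (Absent) in every source and source-origin replicate, and (iv) a
transcription factor. The package runs this screen from raw probe-level
data, with every preprocessing algorithm implemented in the package itself.

## Input model

Arrays of the emulated type interrogate each transcript with a *probe set*
of (typically 11) probe pairs; each pair has a perfect-match (PM) probe and
a mismatch (MM) probe whose central base is substituted, so MM estimates
nonspecific hybridization. The package exchanges probe-level data as a
plain tab-separated dialect (`read_probe_table()`): binary CEL parsing is
deliberately out of scope, since the algorithms need only PM/MM pairs per
probe set and CEL conversion is a solved external step. Group membership
lives in a separate design file and is never inferred from sample names.

## Expression: RMA

`rma()` composes four steps, all implemented here:

1. **Background correction.** Observed PM intensity is modeled as
   `X = B + S` with `B ~ N(mu, sigma^2)` background and `S ~ Exp(mean
   alpha)` signal. `normexp_fit()` maximizes the convolution likelihood per
   array (BFGS with an analytic gradient in `(mu, log sigma, log alpha)`
   from a method-of-moments start; the third central moment identifies
   `alpha`). The direct log-density loses all precision when
   `sigma/alpha` is large — two terms of order `(sigma/alpha)^2` must
   cancel — so the implementation switches to a Mills-ratio asymptotic
   expansion that performs the cancellation analytically. Convergence uses
   a fixed relative tolerance of 1e-8, so fits are deterministic.
   `normexp_adjust()` then replaces each PM value by `E[S | X = x]`, which
   is strictly positive and strictly increasing in `x`.
2. **Quantile normalization** across arrays: every column is replaced by
   the vector of row means of the column-wise sorted matrix, assigned back
   in rank order. Ties are broken by original row order, which makes the
   operation deterministic and idempotent.
3. **log2 transformation.**
4. **Median polish** per probe set: the additive model
   `log2 value = overall + probe effect + sample effect` is fitted by
   alternately sweeping row and column medians (rows first; even-length
   medians are the mean of the central pair), and the summary is
   `overall + sample effect`. The polish runs to numerical convergence
   (residual change below 1e-12, at most 1000 sweeps) rather than stopping
   after a fixed few sweeps: typical blocks converge in a handful of
   sweeps anyway, and a converged fixed point makes the summary
   well-defined independently of the iteration budget.

MM values never enter the expression path.

## Detection: MAS5-style Present/Marginal/Absent calls

Fold changes on background-corrected values are meaningless for probe sets
near the detection floor, so the screen additionally requires detection
calls, computed on the *raw* PM/MM data (`mas5_calls()`); the expression
and call paths are independent computations over the same dataset.

For one probe set in one sample, each pair contributes a discrimination
score `(PM - MM)/(PM + MM)`. A one-sided Wilcoxon signed-rank test of
`median(score) > tau` yields a p-value, and the call is **P** if
`p < alpha1`, **A** if `p > alpha2`, **M** otherwise (strict
inequalities). Defaults `tau = 0.015`, `alpha1 = 0.04`, `alpha2 = 0.06`
are the classic Statistical Algorithms defaults; the source publication of
the screen does not print them, so all three are exposed as parameters and
recorded in the run manifest. Saturation handling and probe-pair
discarding are intentionally not implemented: every pair enters the test.

Scores equal to `tau` are discarded (the zero-removal convention; if all
are discarded, `p = 1`). Tied absolute differences receive average ranks.
For up to 12 remaining scores the tail probability is exact — a dynamic
program over the doubled-rank-sum distribution, equivalent to enumerating
all `2^n` sign assignments — so with the standard 11 pairs per probe set
every real call is exact. Larger inputs use the normal approximation with
tie correction and a 0.5 continuity correction. With 11 pairs the smallest
attainable p-value is `1/2048`, comfortably below `alpha1`; with 4 pairs
the minimum is `1/16 = 0.0625 > alpha2`, so small probe sets can never be
called Present — a structural property of the test, not a bug.

## The screen

`run_screen()` intersects eight criteria:

* four fold-change **up-sets** (target > source-origin, target-stem >
  source-origin, target > source, target-stem > source), each the set of
  probe sets whose group-mean log2 difference exceeds `fold_threshold`
  (default 2, i.e. fourfold). The comparator is strict `>` by default; the
  published description uses ">log2 2" in one place and ">= fourfold" in
  another, so the strictness is configurable (`strict = FALSE` for `>=`).
* Present-sets for target and target-stem and Absent-sets for source and
  source-origin, aggregated over replicates. Default aggregation is
  `"all"` (every replicate must carry the wanted call); `"majority"` is
  provided for designs in which one public group has a single array.
  Marginal counts as neither P nor A unless explicitly included.

The combined overlap is mapped to gene symbols and intersected with a
transcription-factor list (such as the PANTHER protein class PC00218 for
mouse). Genes, not probe sets, are the output unit: a gene passes if *any*
of its probe sets passes, so genes represented by several probe sets
collapse to one candidate. Probe sets without annotation are dropped only
at this final stage, keeping all probe-set-level stage counts faithful to
the published Venn diagrams. Symbols match case-sensitively after
whitespace trimming — mouse capitalization (Foxa2 vs FOXA2) is meaningful.

Useful monotonicity invariants hold by construction and are enforced by
tests: raising `fold_threshold` never enlarges any stage; switching
aggregation from majority to all never enlarges the call intersection; the
combined set is always contained in both intersections; results are
invariant to row and column order.

## The synthetic study generator

`simulate_dataset()` generates the full artifact set for a four-group
study with a planted truth, so the entire pipeline is testable without any
download. Per probe pair and sample,

```
PM = B + s * a * e        B, B' ~ N(background_mean, background_sd^2)
MM = B' + mm_leak * s * a * e'   e, e' log-normal, CV = noise_cv
```

where `s` is the gene's true signal — `signal_scale` when the gene is off
in that sample's group, `signal_scale * 2^effect_log2` when on — and `a`
is a per-probe affinity (log-normal, median 1) drawn once and shared
across samples, emulating sequence-dependent probe behavior. MM receives a
small leak of true signal rather than a cross-hybridization model, which
is enough to keep discrimination scores positive for expressed genes.

Three regulator genes carry the target pattern (off, off, on, on) over
(source, source-origin, target, target-stem); every one of the 15 other
on/off patterns receives 20 confounder genes, so each elimination path of
the screen is exercised and every Venn region is populated; remaining
genes are background (off everywhere). The TF list contains all regulators
plus half of the confounders, so the TF filter does real work. About 10%
of genes own two probe sets, exercising gene collapsing.

Default intensity scales (`background_mean = 1000`, `background_sd = 10`,
`signal_scale = 10`, `effect_log2 = 4`, `mm_leak = 0.05`,
`noise_cv = 0.1`) were chosen once so that the generator's calibration
properties hold with margin: an off gene contributes a mean discrimination
score of about `s/(2*mu) ~ 0.005`, safely below `tau = 0.015` relative to
the score noise `sigma*sqrt(2)/(2*mu) ~ 0.007`, making Absent calls
reliable per cell at well beyond the 99% level, while an on gene scores
about 0.1 and is Present essentially always. After background correction
the off-gene expression floor sits near the corrected signal scale, so the
planted +4 log2 effect survives RMA with group-mean estimates
concentrated around 4. These are deliberately *clean* arrays: real data
add spatial artifacts, saturation, batch effects and sequence-dependent
cross-hybridization that the generator does not model, so passing the
recovery study demonstrates correctness of the algorithms and the screen
logic, not robustness to every real-world pathology.

All draws occur in a documented fixed order under one seeded generator
(probe sets per gene; TF decoy sample; affinities; then per sample: PM
background, MM background, PM noise, MM noise), so datasets are
reproducible across machines, and the caller's RNG state is restored.

## Numerical and degenerate-input choices

* All-identical intensities make the background model unidentifiable:
  `normexp_fit()` refuses them with instructions to skip correction.
* `quantile_normalize()` requires a complete rectangular matrix; a single
  column is returned unchanged.
* An empty probe-set block is an error; a single-probe block summarizes to
  that row unchanged; a constant block summarizes to the constant.
* An empty TF list produces an empty final gene list with all upstream
  stages intact, and is a warning (not an error) when read from file.
* Screen outputs are sorted lexicographically everywhere, so repeated runs
  write byte-identical artifacts.

## Problem sizes used by the validation suite

The recovery study runs the full pipeline on 100 independently seeded
default-scale studies (2,000 genes, ~2,200 probe sets, 24,000 probe pairs,
12 arrays each). Oracle comparisons use 200 random score vectors for the
signed-rank test (every n from 1 to 12, with ties and zeros), 500 random
probe-set blocks for median polish, matrices up to 10,000 x 12 for
quantile normalization, and an exhaustive 2^4-pattern fixture for the
screen set logic. The reproduction harness for the deposited GEO arrays
(`reproduce_geo()`) is validated structurally on synthetic stand-ins; the
published stage counts themselves can only be recomputed after externally
converting the deposited CEL files, which requires a download and is kept
outside the test suite by design.

## Known limitations

* Bit-level agreement with other RMA implementations is not guaranteed:
  background-estimator details differ between implementations, which is
  why `reproduce_geo()` reports per-stage deltas instead of asserting.
* MAS5 signal values (Tukey-biweight expression estimates), GC-RMA, PLIER
  and array-level quality control are out of scope.
* The fold-change stage operates on RMA log2 values; analyses performed
  with other software on other transforms may shift individual stage
  counts.
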