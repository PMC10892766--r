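---
title: "CNVR construction and mixed-model association: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNVR construction and mixed-model association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrgwas)
```

## The problem

Copy number variations (CNVs) — deletions (losses) and tandem duplications
(gains) of genomic segments — segregate in livestock populations and can be
used as molecular markers for quantitative traits. Population callers emit
per-sample CNV calls in a structural-variant VCF; because breakpoints are
noisy and calls are private to samples, the unit of association analysis is
the **copy number variation region (CNVR)**: the span obtained by merging
overlapping calls across all samples. `cnvrgwas` covers the full path from a
multi-sample structural-variant VCF to per-CNVR association statistics,
landscape summaries and proximal-gene annotation.

## CNVR construction

**Call filtering.** Records must carry `SVTYPE` (`DEL`/`DUP` retained;
inversions and breakends are skipped with a count) and `END`. The FILTER
column is matched case-insensitively against the substring "pass", the
convention of the upstream caller. A sample is a carrier of a record when its
GT contains at least one alternate allele; copy-number FORMAT fields are
ignored because the downstream genotype coding is three-state only. Calls are
restricted to lengths in the inclusive window 50 bp – 5 Mb, the usual working
range for short-read CNV calls (coordinates are 1-based inclusive with
length = end − start + 1, so the smallest retainable call is exactly 50 bp;
observed minimum sizes of 51 bp in real landscapes are consistent with this
inclusive convention).

**Merging.** Per chromosome, CNVRs are the connected components of the
interval-overlap graph, where overlap means sharing at least one base.
Book-ended intervals (one ends at the base before the next starts) share no
base and are deliberately *not* merged — "overlapping" is taken literally.
Components are computed with `IRanges::reduce(min.gapwidth = 0)`; a
sweep-line and a per-base boolean-track oracle back this in the tests. Each
CNVR spans min(start)–max(end) of its component, and the size window is
re-applied after merging because a chain of overlapping calls can exceed the
per-call maximum. A CNVR is *loss* if all its supporting calls are
deletions, *gain* if all are duplications, *mixed* otherwise. Identifiers are
assigned deterministically in (chromosome, start) order as `DEL`/`DUP`/`MIX`
plus a zero-padded 8-digit index, so output is independent of input order.

**Genotype coding.** Sample × CNVR cells are coded +1 (gain), 0 (normal
diploid), −1 (loss). When one sample carries both call types inside one
region — which the merging rule permits — the type covering more total bases
wins, and an exact tie codes −1 because losses dominate every reported CNV
landscape; each tie is reported. CNVRs with carrier frequency not strictly
above 0.5% (carriers / all samples) are removed before testing; the strict
inequality follows the usual "above 0.5%" phrasing of this filter.

## The relationship matrix

No standard exists for a CNV-derived genomic relationship matrix, so the
package uses the VanRaden construction adapted to three-state codes: with
`C` the column-mean-centered code matrix,

```
G = C C' / sum_j var_j
```

where `var_j` is the empirical variance (denominator n) of column j. This
normalisation forces `mean(diag(G)) = 1` exactly, and centering forces zero
row sums, so G has a null eigenvector along the intercept — harmless under
REML, which profiles the intercept out. Zero-variance columns are dropped
with a count. This is a design choice, not a reproduction of any published
formula: alternatives (allele-frequency centering as in SNP GRMs) are not
well defined for three-state CNV codes. A configurable ridge (default 1e-6)
is added to the diagonal before decomposition because CNV GRMs built from few
informative columns can be rank-deficient.

## The mixed model and the per-CNVR test

For each trait, after listwise deletion of missing phenotypes,

```
y = X b + W g + Z u + e,  u ~ N(0, G sigma2_a),  e ~ N(0, I sigma2_e)
```

with X an intercept (plus optional covariates) and Z the identity — the
design assumes one record per individual, appropriate for birds measured once
in a common environment; no further fixed effects are modeled by default.

**Null fit.** G (plus ridge) is eigendecomposed once, `G = U D U'`; rotating
y and X by `U'` diagonalises the covariance to
`sigma2 * (h2 D + (1 - h2) I)` with `h2 = sigma2_a / (sigma2_a + sigma2_e)`.
The restricted likelihood, profiled over the total variance `sigma2` with
denominator n − p, is maximized over h2 in [1e-6, 1 − 1e-6] by a 64-point
coarse grid followed by Brent search to a tolerance of 1e-8; the coarse grid
guards against the rare multi-modal profile, and a 1000-point grid oracle in
the tests confirms the optimum dominates.

**Per-marker test.** Each CNVR column is rotated once and tested by weighted
least squares with the variance *ratio* (h2, hence the weights) fixed at the
null estimate — the one-decomposition strategy of EMMAX-class software. The
total scale is re-profiled per marker with denominator n − p, so that when
the estimated genetic variance is zero the statistic reduces *exactly* to the
ordinary least-squares t-statistic (fixing both components, the textbook
EMMAX choice, cannot reproduce OLS exactly because the null residual variance
is estimated without the marker). The test statistic is the Wald chi-square
`(beta/se)^2` on 1 df. A constant (post-subsetting) code vector is flagged
degenerate and reported with p = 1 rather than failing the scan. An `exact`
mode re-estimates h2 with the marker in the model; at markers with large
effects the refit legitimately moves h2, so the two modes are compared in the
tests under a polygenic-only regime, where they agree to well within 0.3
log10 units.

**Multiple testing.** The default genome-wide threshold is Bonferroni,
alpha / N with N the number of CNVRs tested (0.05/11,035 = 4.53e-6 at the
scale of a real chicken landscape). Benjamini–Hochberg q-values are available
behind `correction = "bh"`; both conventions appear in practice and the
package makes Bonferroni — the stricter, Methods-section convention — the
default. Genomic inflation is summarized as `median(chi2) / 0.4549`.

## The simulator

The simulator exists so that every stage, including the statistics, is
testable against known truth without sequencing data. Its defaults emulate a
real laying-hen CNVR landscape:

* 834 samples (the configurable default matches the reference population
  size; tests and the acceptance script scale n down to 300–800 to keep
  runtimes in seconds);
* type proportions 94.7% loss / 4.4% gain / 0.9% mixed;
* sizes drawn log-uniformly within bins 50 bp–1 kb / 1–5 kb / 5–10 kb /
  10–50 kb / >50 kb with masses 87.4 / 9.6 / 1.3 / 1.5 / 0.2% (top bin capped
  at 642,753 bp, the largest reported region);
* carrier frequencies Beta(1, 19) rescaled to (0.001, 0.5) — median ≈ 1.8%,
  so most regions are rare, as observed;
* 38 autosomes with the shipped chicken lengths
  (`chicken_autosomes()`).

Regions are placed by rejection sampling (chromosome ∝ length, start
uniform) with no overlap; mixed regions are emitted as genuinely overlapping
DEL + DUP records with disjoint carrier subsets, so the classifier and the
tie-break are exercised, never short-circuited. Phenotypes follow the model
exactly: `y = mu + W beta + u + e` with u drawn from the eigendecomposition
of the *same* GRM used for fitting, `sigma2_a = h2_polygenic`, and causal
effect sizes back-computed from empirical code variances so each causal CNVR
explains exactly its configured variance fraction; the residual absorbs the
rest of a unit total variance. The default polygenic heritability is 0.3, a
mid-range value for poultry growth and egg traits.

What the simulator does **not** emulate: linkage disequilibrium between
CNVRs, genotyping error, population structure beyond what the CNV codes
themselves induce, breakpoint uncertainty beyond the optional uniform jitter,
and non-Gaussian trait distributions. Passing tests therefore demonstrate
correctness of the machinery under the stated model, not robustness to every
property of real data.

## Calibration and power choices

The test suite checks, among others: type-I error at alpha = 0.05 within
[0.040, 0.060] over 2,000 simulated null CNVRs (n = 500); mean REML
heritability within ±0.1 of a true 0.5 at n = 800 over 10 seeds; and
end-to-end detection of a causal CNVR at the Bonferroni threshold in at
least 8 of 10 seeded pipeline runs (n = 300, 500 regions). For the detection
demonstration the causal region is set to explain 15% of phenotypic
variance: because the causal column is itself part of the GRM, the polygenic
term absorbs part of its signal (the standard proximal-contamination effect
of one-decomposition tests), and a design power calculation — requiring an
expected chi-square above ~22 after that absorption — puts the clearly
detectable effect at ~15% for n = 300 under a 1e-4 threshold. Rank recovery
(causal attains the smallest p) is separately exercised at 10% variance.
These problem sizes are the package's chosen demonstration scales; the same
code runs unchanged at full population scale.

## Numerical and formatting conventions

* Summary percentages and mean sizes are rounded half-up to one decimal
  (`round_half_up()`), matching how published landscape tables are formatted;
  base `round()` would round ties to even.
* Size bins are left-closed, right-open, with an unbounded top bin; regions
  below the first edge land in a reported `underflow` bin.
* BED output is 0-based half-open; VCF and GFF3 coordinates are 1-based
  inclusive throughout the package's internals.
* Annotation windows are closed intervals `[max(1, start − flank), end +
  flank]` with any-overlap semantics (a gene touching the window boundary by
  one base is reported); strand is ignored since the window is symmetric.
  Overlap classes distinguish genes inside the CNVR, overlapping it, or only
  its flank.
* All generators are pure functions of (configuration, seed); the pipeline
  itself is deterministic, and a rerun with identical inputs is bit-identical
  (the run manifest records a configuration hash).

## Known limitations

* The GRM formula is a defensible choice among several; results can shift
  with allele-frequency-weighted alternatives.
* The one-decomposition test loses power relative to leave-one-out
  (LOCO-style) strategies when individual markers carry large effects,
  because the tested marker contributes to the GRM.
* The carrier/type contract for VCF genotypes (any GT containing allele 1 is
  a carrier) matches DELLY-style output but may need adaptation for callers
  that encode copy number in GT.
* Only autosomes are modeled; sex chromosomes need dosage handling the
  three-state coding does not provide.
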