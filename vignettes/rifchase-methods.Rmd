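---
title: "Methods and modelling choices in rifchase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in rifchase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifchase)
```

# Scope

`rifchase` packages the computational side of a bacterial RNA-decay study
design: a rifampicin-chase transcriptome stability classification, a
threshold-based differential-expression (DE) selection on read-count
matrices, mutation-rate estimation from Luria–Delbrück fluctuation assays,
and a set of phenotype quantifications (growth rate, protein half-life,
ROS normalization, densitometry ratios, molecules-per-cell arithmetic).
Everything upstream of a count table — read mapping, feature counting,
bench protocols — is out of scope. A seeded synthetic-data generator with
recorded ground truth makes every stage verifiable without downloads.

# The stability model

Rifampicin blocks transcription initiation, so transcript abundance after
addition reflects pure decay. For each gene and strain we compute

\[ \mathrm{pct} = 100 \cdot \frac{\overline{\mathrm{CPM}}_{T4}}{\overline{\mathrm{CPM}}_{T0}} \]

with replicate CPMs averaged per timepoint (the arithmetic mean is the
simplest reading of "percentage of the CPM values at T0 maintained at
T4"), and classify genes into four categories: 1 for pct ≥ 75, 2 for
[50, 75), 3 for [25, 50), 4 for < 25.

Numerical choices:

* **Boundary convention.** The verbal class definitions use strict
  inequalities that leave 25/50/75 unassigned; we adopt half-open
  intervals closed on the lower bound so the partition is total and
  deterministic.
* **Cap.** Apparent stabilization (pct > 100) is capped at 100 by default
  — the scheme has no class above 100 — with the raw value kept in a
  `pct_raw_*` column. Set `pct_cap = Inf` to keep raw values.
* **Assessability floor.** Genes with mean T0 CPM below
  `t0_cpm_floor` (default 1) are flagged not assessable rather than
  classified: a ratio of near-zero CPMs is noise, and division by zero is
  never raised as an error.
* **CPM, not TMM, for the chase.** Chase libraries are normalized by
  library size only; TMM is reserved for the DE stage. This mirrors the
  convention of treating stability as a within-strain ratio.
* A back-calculated half-life `decay_time / -log2(pct/100)` is provided
  as a clearly-marked auxiliary column; the categorical scheme is the
  deliverable.

Pairwise strain comparisons call a gene `H` (higher stability in X),
`L` (lower) or `=` by comparing categories, not raw percents. The
category-based rule is our documented choice where the convention was
ambiguous; it makes the comparison exactly antisymmetric. Distributions
across strains are compared by Pearson's chi-square on the
strains-by-categories contingency table, with an error when any expected
count is non-positive.

# Differential expression

The DE stage is deliberately simple: its scientific content is the
thresholding — a gene is differentially expressed iff FDR < 0.01 **and**
|log2 fold change| ≥ 1 — and the downstream set logic (Venn regions,
Fisher-exact regulon enrichment). Components:

* **CPM** with optional TMM effective library sizes.
* **TMM** with the conventional defaults (trim 30% of the M tails, 5% of
  the A tails, delta-method binomial precision weights, factors centered
  to geometric mean 1, reference chosen by the upper-quartile rule). The
  test suite checks our implementation against an independent reference
  implementation to 1e-10.
* **A conditional NB exact-style two-group test** replaces a
  quasi-likelihood GLM: replicate counts are scaled to a common
  pseudo-library, summed within groups, and the two-sided p-value is the
  total conditional probability (given the gene's total) of splits no
  more likely than the observed one, under sums of iid NB variables at a
  common dispersion. The common dispersion is estimated by method of
  moments on normalized counts pooled within groups, floored at 1e-8.
  This choice trades exact replication of a specific tool for a
  transparent test whose type-I error we can verify: on 2000 simulated
  null genes (3 vs 3, library 5e6) the empirical rejection rate at 0.05
  stays within ±0.015 across seeds (asserted in the acceptance suite).
* **Fold change** is `log2(meanB/meanA)` on normalized means — exact for
  exact ratios. A pseudo-count (half the smallest nonzero normalized
  group mean in the contrast) is added to *both* means only when one of
  them is zero; applying it unconditionally would distort finite ratios,
  which contradicts the definition of fold change the thresholds rely on.
* **BH step-up** FDR, with ties resolved by a stable sort; verified
  against `stats::p.adjust` and hand-derived cases.
* **Enrichment** is a generic one-sided Fisher exact test per regulon
  over a user-supplied universe, BH-adjusted across regulons — a
  simplified, curated-database-free stand-in for pathway-tool enrichment.

Low-count pre-filtering is deliberately absent (no `min_count` default):
the exact test handles zeros, and filtering would silently change the BH
universe. Dispersion shrinkage, covariates and batch correction are
non-goals.

# Fluctuation analysis

The estimator is the Lea–Coulson median method: solve

\[ r - 1.24\,m - m\ln m = 0 \]

for the expected mutations per culture \(m\) at the observed median
mutant-colony count \(r\), then \(\mu = m / N\) with \(N\) the median
viable titer. \(f(m)\) is strictly decreasing on the admissible branch
\(m > e^{-1.24}\); we bracket (starting `[max(r/10, 1e-6), max(10r, 10)]`
and expanding geometrically), bisect, and Newton-polish to 1e-10 relative.
A non-positive median \(r\) raises an estimator-undefined error — the
median method has no zero-median form; the remedy is more cultures. With
an even number of cultures the median is the mean of the central order
statistics. The Ma–Sandri–Sarkar MLE and plating-efficiency corrections
are noted extensions, not implemented; plating-fraction invariance is
*not* claimed (a known limitation of the median method).

The forward simulator uses a synchronous-doubling model: every generation
each cell divides; a wild-type division mutates with probability µ, in
which case both daughters are mutant; mutants breed true. Generations are
`round(log2(nf/n0))` and the realized final population is recorded. This
discrete model admits an exact first/second-moment recursion, coded
independently in the test helpers as the oracle for the simulator's mean
and variance. Because mutant clones are founded by two cells and growth
is synchronous, the median estimator applied to this world runs somewhat
hot (median estimated µ ≈ 1.5× truth at the default design in our
acceptance run) — within the stated factor-2 recovery band, and a useful
reminder that the estimator's constants were derived for asynchronous
growth with single-cell mutant clones.

# The synthetic world

The generator encodes the assumed real-data structure: three strains
(`pnp+`, `dpnp`, `PNPT1Ec`), three replicate cultures each, a T0/T4
rifampicin pair per replicate, gamma-Poisson counts.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| genes | 4000 | an *E. coli*-sized transcriptome |
| NB dispersion | 0.05 | standard bulk RNA-Seq biological-replicate overdispersion (BCV ≈ 22%) |
| library size | 5e6 | assigned-read depth of a small bacterial RNA-Seq library |
| abundance law | log-normal, sdlog 1.5 | ~4–5 orders of magnitude dynamic range |
| DEG fraction / effect | 0.1 / 1 log2 unit | matches the thresholds under test |
| fluctuation design | 12 cultures, n0 = 100, nf = 1e5, µ = 1e-4 | the common 12-culture bench design at a desk-simulable scale |
| decay categories | strain presets, e.g. `PNPT1Ec` rich in category 1, `pnp+` in category 4 | qualitative shape of a strain whose exonuclease is inactive vs. active |
| half-life ranges | `[12,40]`, `[4.4,9]`, `[2.1,3.8]`, `[0.5,1.9]` min | map through `2^(-4/t½)` strictly inside the four percent ranges, with margin |

Three modelling decisions deserve emphasis:

1. **Only T4 is resampled in the chase.** T0 replicate columns carry the
   baseline expectation unchanged; the decayed timepoint is drawn
   NB(mean = T0·2^(−t/t½), dispersion = `noise`). The chase is anchored
   at the measured T0 profile; the contract names the noise "T4
   resampling".
2. **Noiseless means expectation, not a rounded draw.** With `noise = 0`
   the generator emits real-valued expected counts so that noiseless
   percent remaining is *exactly* `100·2^(−t/t½)` and category recovery
   is exactly 100%. Rounding to integers would corrupt boundary genes at
   low counts. Real read counts are integers; the file readers still
   enforce that — the real-valued path exists only inside simulations.
3. **Chase library sizes are pinned to the baseline depth** for both
   timepoints (explicitly supplied library sizes may exceed column sums).
   Without an absolute anchor, CPM re-normalization at T4 would express
   each gene relative to the *decayed* pool and distort percent
   remaining — the same caveat applies to real chase experiments
   normalized by library size alone.

What the generator does **not** emulate: operon structure and correlated
decay, rRNA depletion artefacts, length bias, batch effects, or
culture-to-culture biological drift beyond NB dispersion. A green
recovery test therefore establishes correctness of the pipeline's
arithmetic and calibration under the stated stochastic model, not
robustness to real-data pathologies.

## A stated limitation the tests surface

With dispersion 0.05 and 3 replicates, the T4/T0 ratio of replicate means
carries a CV ≳ 13%, i.e. ~8–10 percentage points at mid-range percent
remaining, while the two middle categories are only 25 points wide and
the simulated half-life ranges run close to the category edges. Genes
adjacent to a boundary flip categories with probability 0.1–0.25, which
caps overall truth-category agreement near 86% (measured: 0.863 over
three seeds at T0 CPM ≥ 10). The acceptance suite states ≥ 90%; that
criterion is left red rather than met by quietly lowering the dispersion,
adding replicates, or pulling the half-life ranges toward category
centres. The noiseless recovery criterion (100%) passes exactly.

# Phenotype quantifications

* **Generation time**: least-squares fit of log2(OD) vs time; g =
  1/slope. The exponential window is either a user OD range or automatic:
  the longest contiguous run of ≥ 4 points with log-linear R² ≥ 0.99
  (ties: better R²) — the convention the source data leave unstated.
  Flat or declining series raise an error rather than a negative g.
* **Protein half-life**: signal/loading-control ratios normalized to the
  first time point, ln(ratio) fitted unweighted vs time, t½ = ln 2 /
  |slope| in hours; a non-negative slope reports "stable" instead of a
  finite half-life.
* **ROS**: fluorescence / OD600, a pure ratio.
* **Relative densitometry**: signal / reference signal; the reference
  maps to exactly 1.
* **Molecules per cell**: exact arithmetic
  `deficit = tagged_fold / untagged_fold`,
  `estimate = benchmark_molecules / deficit`.
* **Group statistics**: two groups dispatch to the pooled two-tailed
  t-test (so the two-group ANOVA identity F = t² holds); three or more
  use one-way ANOVA with Tukey HSD. The compact letter display is built
  greedily from the means sorted in decreasing order: each maximal run of
  mutually non-significant groups is one letter, subset runs dropped.
  Groups with identical values short-circuit to F = 0, p = 1 (the F
  ratio is otherwise 0/0).

# Determinism and tolerances

All randomness flows from integer seeds; `run_pipeline()` derives
per-stage sub-seeds from one master seed (kept inside 32-bit range) and
writes a manifest of MD5 digests — re-running with the same seed is
byte-identical. TSV output rounds reals at 17 significant digits, so
writer/reader round-trips are exact for integers and better than 1e-9
relative for reals. The Lea–Coulson solver targets 1e-10 relative; its
round-trip property is asserted at 1e-8 over m ∈ [0.5, 50]. The NB exact
test enumerates the full conditional support below totals of 5000 and a
1e-14-quantile window above.

# Known limitations

* The DE test assumes a common dispersion across genes; per-gene or
  shrunken dispersions are out of scope, and power at very low counts is
  limited by the discreteness of the conditional support.
* Stability classification inherits the compositional caveat of CPM: it
  is exact in the simulator only because the depth anchor is known.
* The median fluctuation estimator is biased under synchronous growth
  and no plating-fraction correction is attempted.
* The compact letter display is the greedy sorted-means construction; it
  reproduces the usual reporting convention but is not guaranteed minimal
  in pathological significance patterns.
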