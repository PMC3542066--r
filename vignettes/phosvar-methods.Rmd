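---
title: "Phosphorylation variability and structural context: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphorylation variability and structural context: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosvar)
```

## The scientific question

Quantitative phosphoproteomics time courses measure, for thousands of
phospho-sites, a normalized phosphorylation ratio at each sampled state —
here six cell-cycle phases (G1, G1/S, early S, late S, G2, M), with
ratios already normalized by the protein-level change so they reflect
modification, not abundance. Some sites keep a nearly constant ratio
across the cycle; others swing strongly. `phosvar` asks whether that
*temporal variability* is structured by the physical context of the
modified residue: residues in regular secondary structure (helices and
sheets), in ordered loops and turns, or in intrinsically disordered
regions.

## The variability statistic

For one site with ratio vector $r = (r_{G1}, r_{G1S}, r_{ES}, r_{LS},
r_{G2}, r_M)$ the variability is the sample standard deviation

$$ v = \sqrt{\tfrac{1}{k-1}\sum_{i=1}^{k} (r_i - \bar r)^2 } $$

over the $k$ non-missing phases. The $n-1$ denominator is the default of
the standard statistical tooling this analysis builds on; a population
denominator is available (`population = TRUE`) for sensitivity analysis,
as is an optional `log2` transform of the ratios (off by default — the
ratios are used as delivered). The primary analysis set keeps only sites
quantified in **all six** phases; robustness subsets relax this to at
least (default) or exactly `k` phases — both interpretations are
provided because subset definitions of this kind are ambiguous in the
literature this pipeline follows, and `filter_complete()` exposes the
choice as `mode`.

## Structural categories

Each site receives the secondary-structure state (`H`, `E`, `C`) and
disorder flag at **exactly its own residue** (no window vote), merged
into:

* **regular** — helix or sheet in an ordered region,
* **irregular** — coil in an ordered region,
* **disordered** — coil in a disordered region.

The two-level scheme collapses regular + irregular into **ordered**.
A residue predicted helix/sheet *and* disordered is a predictor
disagreement; we class it disordered (disorder dominates) and count a
warning, keeping the three categories exhaustive. The comparison stage
reports per-category counts and medians, a Kolmogorov–Smirnov test on
the two-level split and a one-way ANOVA across the three levels.
Coil-segment extraction (maximal `C` runs, split where the disorder flag
changes) supports the observation that ordered coils — turns and short
loops — are much shorter than disordered regions.

## Flanking-sequence statistics

Windows span ±6 residues around each site; positions beyond a terminus
are missing and excluded from every per-position test. The two-sample
logo compares low- versus high-variability sites (median split by
default — the split quantile is a package choice, exposed as `split_q`,
since no canonical threshold exists): for each position and amino acid
the 0/1 indicator vectors are compared with a Welch *t*-test, α = 0.05
uncorrected (a Bonferroni switch exists). When both indicator vectors
are constant the *t*-statistic is undefined and a pooled two-proportion
*z*-test is used instead — this preserves the intent (a difference of
frequency vectors) on degenerate columns. Composition profiling reports
the fractional difference $(P-Q)/Q$ of each amino acid between a query
and a background window set, with a percentile bootstrap CI obtained by
resampling windows of both sets; an amino acid absent from the
background is reported as undefined rather than dividing by zero.

## Multi-phosphorylation and disorder

A *neighbor* is another phospho-site of the same protein within
`w` residues (`w` = 1..5). For each cut-off a 2×2 table
(ordered/disordered × neighbor yes/no) is tested with Fisher's exact
test. The odds-ratio estimate is the conditional maximum-likelihood
estimate given the margins — the `fisher.test` convention — computed
here by solving the noncentral-hypergeometric score equation to high
precision (the simple cross-product `ad/bc` is reported alongside). The
neighbor pool defaults to the analysis set and can be switched to the
full input table (`neighbor_pool = "all-sites"`), because published
analyses of this design do not always state which pool they used.

## 2D annotation enrichment of kinase motifs

Kinase recognition motifs (user-supplied patterns over the ±6 window,
e.g. `R-R-X-pS/pT`; the bundled file carries common textbook motifs for
testing and is not an authoritative motif catalogue) are matched against
every site window. Each motif's member set is then located in the
two-dimensional space (variability, disorder): per dimension, with
midranks $R$ over all $n$ sites and $m$ members,

$$ s = \frac{2\,\big(\overline{R}_{\text{members}} - \tfrac{n+1}{2}\big)}{n-m} \in [-1, 1]. $$

The score depends on the data only through ranks, so it is invariant
under monotone transforms of either dimension. For joint significance we
use a Hotelling-type quadratic form on the centered mean-rank vector:
under the null the members are a simple random sample without
replacement from the $n$ ranks, so the exact covariance is the empirical
midrank covariance scaled by $(n-m)/(m(n-1))$; the statistic is referred
to a χ² with 2 df (or 1 df on the variability dimension alone if the two
rank vectors are collinear), and Benjamini–Hochberg correction is
applied across motifs with FDR < 0.01 flagged. The original 2D
enrichment software's exact joint test is not published in detail; the
score formula above is exact and fixed, while p-values are defined by
this package's documented approximation — its null uniformity is
verified by simulation in the test suite. The disorder coordinate uses
the per-residue disorder probability when the profiles carry one, else
the binary call (ties are absorbed by midranks).

## Conservation of phospho-sites

Controls are all S/T/Y residues of the phospho-proteins not observed
phosphorylated; each record carries its structural background
(ordered/disordered from the disorder call) and the per-residue
evolutionary rate consumed from rate4site output as-is (lower = more
conserved; no re-normalization). Three Mann–Whitney–Wilcoxon contrasts
are reported: phospho vs control within ordered, within disordered, and
phospho ordered vs phospho disordered.

## The synthetic-data generator

The generator exists so that every stage is testable without running
PsiPred, DISOPRED or rate4site. Its defaults *are* the study
conditions: 1,059 proteins; 5,748 sites of which 10% are incomplete,
leaving 5,173 in the analysis set; class proportions 145 : 353 : 4,675;
class-median variabilities 1.65 / 1.83 / 2.22; neighbor-clustering odds
ratio 1.9 at `w` = 4; conservation stratum means −0.38, −0.28, 0.14,
0.22.

Design choices where the conditions left the mechanism open:

* **Ratio noise.** Each site draws $\sigma$ from a log-normal whose
  median is the class target (log-scale SD 0.1 — small enough that the
  realized class median is controlled by the target rather than by
  sampling noise even in the 145-site regular class, while sites still
  differ in variability within a class). The six ratios are
  $1 + \sigma \tilde z$ with $\tilde z$ a noise 6-vector standardized to
  unit sample SD; if any ratio would be negative the whole vector is
  shifted up to zero. A constant shift preserves the sample SD exactly,
  so realized per-site variability equals the planted $\sigma$ and
  ratios remain valid nonnegative fold changes — a simple truncation at
  zero would instead bias the realized SDs away from the calibration
  targets at these effect sizes.
* **Neighbor clustering.** A planted fraction of sites comes in pairs at
  distance 1–4 (distance drawn before choosing a run, so its
  distribution is identical in ordered and disordered regions); all
  other sites are kept ≥ 11 residues apart, so planted pairs are the
  only neighbors. The disordered pair fraction is derived from the
  target odds ratio, corrected for the completeness filter (losing a
  partner to missingness removes a neighbor), so the analysis-set odds
  ratio at the target cut-off equals the planted value up to binomial
  noise.
* **Sequences.** I.i.d. uniform over the 20 amino acids, with a 2×
  proline excess in disordered stretches and the planted residues
  (S/T/Y at sites with realistic 84/14/2 proportions; proline at +1 of
  motif-planted sites, placed with probability increasing with disorder
  and variability so the planted proline-directed motif separates in
  the 2D space).
* **Conservation scores.** Gaussian per stratum with SD 0.6 — wide
  enough that the four strata overlap broadly, as real rate4site scores
  do, while the planted mean differences remain detectable at the
  stratum sizes used in the tests.
* **Structure.** Alternating ordered/disordered blocks (geometric
  lengths, means ≈ 40); ordered blocks mix helix/sheet runs with short
  coils, disordered blocks are all-coil, so ordered coils come out much
  shorter than disordered regions. Helix/sheet residues are never
  flagged disordered, matching the category counts being exhaustive.

What the generator does **not** emulate: realistic amino-acid
composition beyond the proline excess, phospho-occupancy kinetics,
correlated missingness, sequence evolution, or predictor error
(profiles are treated as truth). Passing tests therefore demonstrate
that the pipeline recovers planted statistical structure of the stated
form — not that the predictors themselves are accurate on real
proteins.

## Numerical and testing choices

* Quantile-based splits use the type-7 convention; ties at the threshold
  go to the low-variability set.
* Mann–Whitney uses midranks, tie-corrected variance and no continuity
  correction; KS p-values use the asymptotic Kolmogorov distribution
  (the compared samples here are large).
* Degenerate one-way ANOVA (zero within-group variance with distinct
  means) reports F = ∞, p = 0 with a `degenerate` flag rather than NaN.
* The test suite verifies the statistical primitives against independent
  brute-force oracles: exhaustive hypergeometric enumeration for
  Fisher's test (complete sweep of all tables with margins ≤ 14 plus
  1,500 random tables with margins ≤ 30 — exhaustive where enumeration
  is cheap, sampled at the full size), ECDF scans for KS on 1,000 random
  pairs, pair counting for Mann–Whitney, and the step-up formula for
  Benjamini–Hochberg.
* Null calibration is checked by simulation (2,000 replicates per test
  family; KS on 500 + 500 points, Fisher on ~800-observation tables, 2D
  enrichment at n = 500, m = 50), and power/coverage checks use 100–200
  replicates at the generator's default size; these sizes are the
  package's chosen compromise between Monte-Carlo resolution and a test
  suite that runs in minutes.

## Known limitations

* The replication pathway is exercised end-to-end on the calibrated
  generator; results on real predictor output will additionally reflect
  predictor error and composition biases the generator does not model.
* The 2D joint p-value is an approximation defined by this package (see
  above); scores are exact.
* The bundled motif file is illustrative, not a curated kinase-substrate
  resource.
* The two-sample logo reports statistics, not typography; plotting is
  left to the user.
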