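---
title: "Simulating spatial single-cell data and benchmarking spatial summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spatial single-cell data and benchmarking spatial summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CellPatternSim)
```

## The generative model

CellPatternSim simulates the per-cell tables produced by single-cell
spatial platforms (multiplex immunofluorescence, imaging-based spatial
transcriptomics) without reference data. A sample is assembled in fixed
stages, each stochastic and each conditioned only on the stages before it:

1. **Cell locations** are a homogeneous Poisson process: the number of
   cells is Poisson(λ·|W|) and locations are i.i.d. uniform in the
   rectangular window `W`. This is the complete spatial randomness (CSR)
   baseline; all spatial structure is added through labels, not through
   the locations themselves.
2. **Probability surfaces** encode structure. A kernel set is `k` centres
   drawn uniformly in `W` with isotropic bandwidths
   `sd ~ Uniform(sdmin, sdmax)`. The raw field is the pointwise *maximum*
   of unit-peak Gaussian bumps, then affinely rescaled from `[0, 1]` to
   `[prob_min, prob_max]`.
3. **Labels** — tissue compartment, hole flag, phenotype positivity per
   cell type — are independent Bernoulli draws with success probability
   equal to the relevant surface at the cell's location.
4. **Continuous markers** are Gaussian conditional on positivity:
   `N(meanPos, sdPos)` for positive cells, `N(meanNeg, sdNeg)` for
   negative ones.

Because positivity thins a Poisson process by a location-dependent
probability, the positive cells form an inhomogeneous Poisson process
whose intensity is proportional to the surface — clusters appear where
kernels sit, against a background floor of `prob_min`.

### Why max-combination and theoretical scaling

Only the bounds of the scaled surface are meaningful parameters, so the
package guarantees them exactly. Combining kernels by pointwise maximum
(rather than summation) means overlapping clusters can never push the
probability above `prob_max`, and the peak value 1 is attained at every
kernel centre, so `prob_max` is reached exactly there. Rescaling uses the
theoretical raw range `[0, 1]` rather than the empirical range over
sampled points, so a surface is a well-defined object independent of the
point pattern it is later applied to. These are the package's own
conventions; other simulators may combine kernels additively, and results
that depend on the overlap behaviour of clusters are not expected to be
numerically identical across such conventions.

### The shift policy for colocalization

For two or more cell types, type *t* reuses the kernel set of type *t−1*
with every centre displaced by a fixed magnitude in an independent uniform
direction, wrapping torus-style at the window edges. The magnitude is
`shift × width(W)/2`, so `shift = 0` shares the surface exactly (maximal
colocalization) and `shift = 1` moves every cluster half the domain away.
The linear-in-shift magnitude with torus wrap is a deliberate policy
choice: it makes the two endpoints interpretable and keeps every shifted
surface statistically equivalent to a fresh one (centres remain uniform).
Wrapping can split a cluster across opposite edges; edge-corrected
statistics tolerate this.

## Tunable parameters

All lengths are in window units (the default window is 2 × 2, centred at
the origin, area 4).

| parameter | default | meaning |
|---|---|---|
| `lambda` | — (required) | expected cells per unit area; 250 gives ≈ 1000 cells per default window |
| `k` | 5 | phenotype clusters per sample |
| `sdmin`, `sdmax` | 0.1, 0.3 | cluster bandwidth bounds; larger values give larger, more diffuse clusters |
| `probs` | (0.01, 0.75) | abundance bounds: background positivity floor and in-cluster peak |
| `shift` | 0 | displacement fraction between consecutive cell-type surfaces |
| tissue stage | k = 2, sd 0.4–0.6, probs (0.2, 0.8) | a few broad compartments, both labels common |
| hole stage | k = 1, sd 0.1–0.2, probs (0.1, 0.3) | one small non-cellular focus (necrosis, fold), modest hole rate |
| `nPerm` | 100 | label permutations per test |
| `radii` | 0.01–0.5 step 0.01 | 50 assessed radii; r = 0 is excluded (g is undefined there, K and G are degenerate) |
| `alpha` | 0.05 | one-sided significance level |

Marker distributions have **no defaults**: the separation between the
positive and negative component is the effect size a benchmarking study
manipulates, and silently defaulting it would invite misinterpretation.

The tissue and hole stages never influence positivity — the three surfaces
are sampled independently, and hole cells remain eligible for phenotype
labels (the flag is exported so downstream tools can decide). Coupling
(e.g. restricting a phenotype to one compartment) is out of scope.

## Spatial summary statistics

The estimators operate on the positive cells of one sample in the known
window; all are re-implemented here with one shared O(n²) pair pass in
compiled code and validated against naive double-loop oracles in the test
suite.

* **Ripley's K**, translation edge correction:
  `K(r) = |W|/(n(n−1)) · Σ_{i≠j} 1{d_ij ≤ r} · w_ij` with
  `w_ij = |W| / ((W_x − |Δx|)(W_y − |Δy|))`. CSR reference πr².
* **Nearest-neighbour G**, reduced-sample (border) correction: among the
  points farther than r from the boundary, the fraction whose nearest
  neighbour is within r. Reference `1 − exp(−λ̂πr²)`, `λ̂ = n/|W|`. If no
  point is interior at some radius the estimate is `NA` there.
* **Pair correlation g**, Epanechnikov kernel of half-width `b` with the
  same translation weights, normalised so CSR gives 1. The automatic
  bandwidth is Stoyan's rule `b = 0.15/√λ̂`. Reference 1; `r = 0` is `NA`.

Translation for K/g and border for G are the standard default corrections
of the spatial-statistics ecosystem for rectangular windows; the CSR
closed-form calibrations in the test suite pin the implementations to
those conventions.

### The permutation test

Observed statistics are compared to a conditional null: each permutation
reassigns the same number of positive labels uniformly at random over all
cell locations and recomputes the statistics (the same permutations serve
all three statistics, which also lets K and g share their pair pass). Per
radius the test reports the *degree of clustering* (observed − permutation
mean) and the add-one one-sided p-value
`p = (1 + #{perm ≥ obs})/(1 + n_valid)`, which is never exactly 0 and is
exactly `1/(nPerm+1)` when the observed value exceeds every permutation.
Significance is one-sided toward clustering. Numerical details: permuted
index sets are sorted before evaluation so that a degenerate all-positive
marker reproduces the observed value bit-for-bit (`p = 1`, degree exactly
0); permutation values that are `NA` (possible for G at large radii) are
dropped from both the count and the denominator; samples with fewer than
two positive cells are flagged non-evaluable and excluded from benchmark
denominators.

## Benchmarking scenarios

Four canonical scenarios cross cluster size with phenotype abundance at
λ = 250, k = 5:

| scenario | bandwidths | abundance |
|---|---|---|
| 1 | 0.1–0.3 | 0.01–0.75 |
| 2 | 0.2–0.4 | 0.01–0.75 |
| 3 | 0.1–0.3 | 0.01–0.2 |
| 4 | 0.2–0.4 | 0.01–0.2 |

`runScenario()` simulates the samples (holes and tissue with their stage
defaults, positivity with the scenario parameters), tests every sample,
and `summariseBenchmark()` counts, per statistic, the radii at which it
found significant clustering in *strictly* the most samples
("most significant" — ties credit no statistic, so the three counts need
not sum to 50) and the radii at which every evaluable sample was
significant ("all significant"). The strict-maximum rule is what makes
"most sensitive" well defined when two statistics saturate.

### Problem sizes

The package runs its benchmark at 100 samples × 100 permutations per
scenario (a few minutes on one CPU); this is the scale used by the test
suite and by `scripts/acceptance.R`. Larger designs — e.g. 1000 samples —
are a matter of raising `nSims` in `scenarioConfig()`; counts based on
"all samples significant" become strictly harder as samples are added, so
absolute counts should only be compared within a fixed `nSims`.

## Seed discipline

A simulation carries one master seed; every (sample, stage) pair derives
its own substream via a small integer mixer. Consequences: regenerating a
later stage (e.g. positivity with new parameters) never perturbs earlier
stages; samples are mutually independent; and raising `prob_max` with the
same seed can only add positive cells, never remove them (the underlying
uniform draws are identical), which the test suite exploits as a strict
monotonicity check. The permutation stage of `runScenario()` has its own
substream per sample; standalone `permutationTest()` calls use the
caller's RNG state.

## What the simulator does and does not emulate

The generator produces clustered or colocalized phenotypes over a CSR
cell background with binary tissue compartments and focal holes. It does
**not** emulate: inhomogeneous cell density (tissue-wide gradients in
cell packing), cell-size exclusion effects (points may be arbitrarily
close), multi-compartment tissue architectures, count-distributed
expression (negative binomial), or segmentation artefacts. Passing
benchmarks here therefore demonstrates sensitivity to surface-driven
clustering under stationary backgrounds — not robustness to every
real-tissue pathology. The hole stage exists precisely to let users probe
the first-order effect of non-stationarity, but holes are also Bernoulli
thinnings, not hard mask subtractions.

## Known limitations

* Windows are axis-aligned rectangles; polygonal cores and annuli are out
  of scope, and the edge corrections rely on the rectangle.
* Kernels are isotropic Gaussians; elongated or curved niches cannot be
  expressed.
* The statistics are univariate; cross-type (bivariate) K/G/g are not
  included, though the colocalization generator (`shift`) produces data on
  which such methods could be benchmarked externally, and
  `nnCoOccurrence()` offers a minimal bivariate read-out.
* Exact numeric parity with other simulators' surfaces is not claimed
  (kernel combination and scaling conventions differ; see above).
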