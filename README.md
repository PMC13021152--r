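# CellPatternSim

Simulation of spatial single-cell molecular data and benchmarking of
spatial summary statistics.

## The problem

Single-cell spatial platforms — multiplex immunofluorescence (mIF),
imaging-based spatial transcriptomics — produce maps of cells with
phenotype labels and marker intensities, and a growing collection of
statistical methods claims to quantify how strongly cell types cluster or
colocalize in such maps. There is no gold standard for these analyses, so
methods need to be compared on data whose ground truth is known.
CellPatternSim generates that ground truth without any reference dataset:
it simulates biologically motivated point patterns with controllable
clustering, tissue compartments, non-cellular holes, phenotype abundance
and expression shifts, and then measures how well standard spatial summary
functions recover the built-in structure.

## The model

Each simulated sample is built in steps:

1. **Point pattern.** Cell locations form a homogeneous Poisson process
   with intensity λ (cells per unit area) in a rectangular window *W*:
   *N* ~ Poisson(λ·|W|) points placed uniformly.
2. **Probability surfaces.** Structure comes from Gaussian kernel sets:
   *k* centres uniform in *W*, bandwidths σ ~ U(sd_min, sd_max). The raw
   field is the pointwise maximum of unit-peak bumps
   s(x, y) = max_k exp(−d_k²/2σ_k²) ∈ [0, 1], affinely rescaled to
   p(x, y) = p_min + (p_max − p_min)·s(x, y).
3. **Labels.** Tissue compartment ("Tissue 1"/"Tissue 2"), hole flags and
   per-type phenotype positivity are independent Bernoulli draws from
   per-stage surfaces; a second cell type's kernels can be shifted by a
   fraction of the window half-width to tune colocalization.
4. **Continuous markers.** Conditional on positivity, marker values are
   drawn from user-specified normals N(μ_pos, σ_pos) / N(μ_neg, σ_neg).

For benchmarking, the package re-implements three univariate spatial
summary functions with standard edge corrections — Ripley's K(r)
(translation correction; CSR reference πr²), the nearest-neighbour
distance distribution G(r) (reduced-sample/border correction; reference
1 − exp(−λπr²)) and the pair correlation g(r) (Epanechnikov-smoothed,
translation correction, Stoyan bandwidth; reference 1) — plus a
label-permutation test: the positive labels are reassigned uniformly over
all cell locations, and the *degree of clustering* (observed − permutation
mean) with a one-sided add-one p-value, p = (1 + #{perm ≥ obs})/(1 + n_perm),
is reported per radius.

## Worked example

```r
library(CellPatternSim)

sim <- spatialSimulation(nSims = 3, window = simWindow(c(-1, 1), c(-1, 1)),
                         seed = 42)
sim <- generatePointPattern(sim, lambda = 250)      # ~1000 cells per sample
sim <- generateHoles(sim)                           # stage defaults
sim <- generateTissue(sim)
sim <- generateCellPositivity(sim, k = 5, sdmin = 0.1, sdmax = 0.3,
                              probs = c(0.01, 0.75))
tabs <- cellTables(sim)
summariseCells(tabs)
#>   Sample Total Cells Cell 1 Assignment Positive Cell 1 Assignment % Positive
#> 1      1        1048                        163                        15.55
#> 2      2        1033                        211                        20.43
#> 3      3        1030                        216                        20.97
```

Each sample has ≈ 250·4 = 1000 cells; with five tight clusters and
abundance bounds (0.01, 0.75), 15–21% of cells are phenotype-positive.
Testing the first sample for significant clustering:

```r
set.seed(1)
pr <- permutationTest(tabs[[1]], marker = "Cell 1 Assignment", nPerm = 100)
pr
#> PermutationResult: K/G/g over 50 radii, 100 permutations
#>   K: significant clustering at 48/50 radii (alpha = 0.05)
#>   G: significant clustering at 10/50 radii (alpha = 0.05)
#>   g: significant clustering at 50/50 radii (alpha = 0.05)

subset(as.data.frame(pr), abs(r - 0.1) < 1e-9)
#>  stat   r observed null_mean degree_of_clustering p_value significant
#>     K 0.1    0.088    0.0327               0.0554  0.0099        TRUE
#>     G 0.1    0.896    0.7286               0.1669  0.0099        TRUE
#>     g 0.1    2.983    1.0274               1.9558  0.0099        TRUE
```

At r = 0.1 the observed K is ~2.7× its permutation mean and no permutation
reached the observed value (p = 1/101 ≈ 0.0099): the simulated clustering
is recovered. Ripley's K and g flag nearly every radius while G flags few —
the sensitivity difference the benchmark quantifies.

Scenario-level benchmarking (cluster size × phenotype abundance) runs the
whole pipeline over many samples:

```r
res <- runScenario(scenarioConfig(1, nSims = 100, nPerm = 100, seed = 1001))
summariseBenchmark(res)
```

which tabulates, per statistic, at how many of the 50 radii it found
significant clustering in the most samples ("most significant") and at how
many all samples were significant ("all significant").

Whole pipelines can also be driven from a YAML/JSON config via
`runPipeline()`, which writes per-cell CSV tables (simple or HALO-like
dialect), sample summaries, permutation results and a reproducibility
manifest.

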