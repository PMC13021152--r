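#' @import methods
NULL

#' Rectangular simulation window
#'
#' An axis-aligned rectangle representing the observed tissue region (a core,
#' a field of view) in arbitrary spatial units. All point coordinates, kernel
#' centres and radii live in these units.
#'
#' @slot xrange,yrange numeric(2), strictly increasing.
#'
#' @seealso [simWindow()]
#' @export
setClass("SimWindow",
  representation(xrange = "numeric", yrange = "numeric"),
  prototype(xrange = c(-1, 1), yrange = c(-1, 1))
)

setValidity("SimWindow", function(object) {
  msg <- character()
  if (length(object@xrange) != 2L || length(object@yrange) != 2L)
    msg <- c(msg, "xrange and yrange must each have length 2")
  if (!all(is.finite(c(object@xrange, object@yrange))))
    msg <- c(msg, "window ranges must be finite")
  else {
    if (diff(object@xrange) <= 0) msg <- c(msg, "xrange must be increasing (xmax > xmin)")
    if (diff(object@yrange) <= 0) msg <- c(msg, "yrange must be increasing (ymax > ymin)")
  }
  if (length(msg)) msg else TRUE
})

#' Set of isotropic Gaussian kernels defining a probability surface
#'
#' A probability surface is built from \eqn{k \ge 0} unit-peak isotropic
#' Gaussian bumps. The raw field is the pointwise maximum
#' \deqn{s(x, y) = \max_k \exp\{-((x - x_k)^2 + (y - y_k)^2) / (2\sigma_k^2)\}}
#' so that \eqn{s \in [0, 1]} with the peak exactly 1 at each centre, and the
#' returned probability is the affine rescaling
#' \eqn{p = p_{min} + (p_{max} - p_{min}) s}. With zero kernels the surface is
#' constant at \eqn{p_{min}}.
#'
#' @slot centers numeric matrix with k rows and columns x, y.
#' @slot sds numeric(k), kernel bandwidths (standard deviations), all > 0.
#' @slot probRange numeric(2) in [0, 1], ordered: (prob_min, prob_max).
#'
#' @seealso [sampleKernels()], [evaluateSurface()], [shiftKernels()],
#'   [densityGrid()]
#' @export
setClass("KernelSet",
  representation(centers = "matrix", sds = "numeric", probRange = "numeric"),
  prototype(centers = matrix(numeric(), ncol = 2L,
                             dimnames = list(NULL, c("x", "y"))),
            sds = numeric(), probRange = c(0, 1))
)

setValidity("KernelSet", function(object) {
  msg <- character()
  if (ncol(object@centers) != 2L)
    msg <- c(msg, "centers must be a two-column (x, y) matrix")
  if (nrow(object@centers) != length(object@sds))
    msg <- c(msg, "one bandwidth per kernel centre required")
  if (length(object@sds) && any(!is.finite(object@sds) | object@sds <= 0))
    msg <- c(msg, "all kernel bandwidths must be positive")
  pr <- object@probRange
  if (length(pr) != 2L || anyNA(pr) || pr[1] < 0 || pr[2] > 1 || pr[1] > pr[2])
    msg <- c(msg, "probRange must be ordered and within [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Accumulating state of a spatial single-cell simulation
#'
#' Central container for a stepwise simulation of one scenario: the window,
#' the number of independent samples, the homogeneous Poisson point patterns,
#' the kernel sets used for tissue / hole / phenotype probability surfaces,
#' and the per-cell assignments each stage produced. Stages are run in order
#' (point pattern, then tissue, holes, phenotype positivity, continuous
#' marker values); each stage draws from its own seed substream so rerunning
#' a later stage never perturbs an earlier one.
#'
#' @slot window a [SimWindow-class].
#' @slot nSims number of independent samples.
#' @slot nCellTypes number of phenotypes simulated per cell (1 for clustering
#'   studies, 2+ for colocalization).
#' @slot lambda point intensity per unit area; `NA` until patterns exist.
#' @slot seed master seed; all stages derive substreams from it.
#' @slot patterns list (length 0 or nSims) of two-column coordinate matrices.
#' @slot tissueKernels,holeKernels lists of [KernelSet-class], one per sample.
#' @slot cellKernels list per sample of lists of [KernelSet-class], one per
#'   cell type.
#' @slot tissue list of character vectors ("Tissue 1"/"Tissue 2") per sample.
#' @slot holes list of logical vectors per sample.
#' @slot holeDrop whether exported tables drop hole cells by default.
#' @slot positivity list of n-by-nCellTypes 0/1 matrices per sample.
#' @slot markerValues list of n-by-nCellTypes numeric matrices per sample.
#'
#' @seealso [spatialSimulation()], [generatePointPattern()],
#'   [generateTissue()], [generateHoles()], [generateCellPositivity()],
#'   [generateMarkerValues()], [cellTables()]
#' @export
setClass("SpatialSimulation",
  representation(
    window = "SimWindow",
    nSims = "integer",
    nCellTypes = "integer",
    lambda = "numeric",
    seed = "integer",
    patterns = "list",
    tissueKernels = "list",
    holeKernels = "list",
    cellKernels = "list",
    tissue = "list",
    holes = "list",
    holeDrop = "logical",
    positivity = "list",
    markerValues = "list"
  ),
  prototype(
    nSims = 1L, nCellTypes = 1L, lambda = NA_real_, seed = 1L,
    patterns = list(), tissueKernels = list(), holeKernels = list(),
    cellKernels = list(), tissue = list(), holes = list(),
    holeDrop = FALSE, positivity = list(), markerValues = list()
  )
)

setValidity("SpatialSimulation", function(object) {
  msg <- character()
  if (length(object@nSims) != 1L || is.na(object@nSims) || object@nSims < 1L)
    msg <- c(msg, "nSims must be a single integer >= 1")
  if (length(object@nCellTypes) != 1L || is.na(object@nCellTypes) ||
      object@nCellTypes < 1L)
    msg <- c(msg, "nCellTypes must be a single integer >= 1")
  if (length(object@lambda) == 1L && !is.na(object@lambda) && object@lambda < 0)
    msg <- c(msg, "lambda must be non-negative")
  ns <- object@nSims
  for (slotName in c("patterns", "tissueKernels", "holeKernels",
                     "cellKernels", "tissue", "holes", "positivity",
                     "markerValues")) {
    len <- length(slot(object, slotName))
    if (len != 0L && len != ns)
      msg <- c(msg, sprintf("%s must be absent or have one entry per sample",
                            slotName))
  }
  if (length(object@cellKernels) &&
      any(lengths(object@cellKernels) != object@nCellTypes))
    msg <- c(msg, "cellKernels must hold one KernelSet per cell type per sample")
  if (length(msg)) msg else TRUE
})

#' Gaussian distributions for a continuous marker
#'
#' Parameters of the marker-value model for one cell type: positive cells
#' draw from Normal(meanPos, sdPos), negative cells from
#' Normal(meanNeg, sdNeg). Units are arbitrary (fluorescence intensity,
#' expression). There are deliberately no defaults: the separation between
#' the two components is the effect size under study and must be stated.
#'
#' @slot meanPos,sdPos,meanNeg,sdNeg numeric(1); sds >= 0.
#'
#' @seealso [markerDistribution()], [generateMarkerValues()]
#' @export
setClass("MarkerDistribution",
  representation(meanPos = "numeric", sdPos = "numeric",
                 meanNeg = "numeric", sdNeg = "numeric")
)

setValidity("MarkerDistribution", function(object) {
  vals <- c(object@meanPos, object@sdPos, object@meanNeg, object@sdNeg)
  if (length(vals) != 4L || anyNA(vals))
    return("meanPos, sdPos, meanNeg, sdNeg must all be single finite numbers")
  if (object@sdPos < 0 || object@sdNeg < 0)
    return("standard deviations must be non-negative")
  TRUE
})

#' Result of the label-permutation clustering test for one sample
#'
#' For each statistic and radius: the observed value on the positive cells,
#' the mean and quantile envelope of the statistic over label permutations,
#' the degree of clustering (observed minus permutation mean), and a
#' one-sided add-one permutation p-value for clustering.
#'
#' @slot radii radii at which the statistics were evaluated.
#' @slot statNames character, subset of c("K", "G", "g").
#' @slot observed,nullMean,nullLo,nullHi,degree,pValue numeric matrices,
#'   radii by statistics.
#' @slot nPerm number of permutations.
#' @slot alpha significance level used by [isSignificant()].
#' @slot nPositive number of positive cells; the test needs at least 2.
#' @slot evaluable FALSE when the sample had fewer than 2 positive cells.
#'
#' @seealso [permutationTest()]
#' @export
setClass("PermutationResult",
  representation(
    radii = "numeric", statNames = "character",
    observed = "matrix", nullMean = "matrix",
    nullLo = "matrix", nullHi = "matrix",
    degree = "matrix", pValue = "matrix",
    nPerm = "integer", alpha = "numeric",
    nPositive = "integer", evaluable = "logical"
  )
)

setValidity("PermutationResult", function(object) {
  dims <- vapply(list(object@observed, object@nullMean,
                      object@degree, object@pValue),
                 function(m) all(dim(m) == c(length(object@radii),
                                             length(object@statNames))),
                 logical(1))
  if (!all(dims)) return("result matrices must be radii x statistics")
  TRUE
})

#' Parameters of one benchmarking scenario
#'
#' Bundles every input of a simulate-then-test benchmark run: point
#' intensity, phenotype kernel parameters, tissue/hole defaults, sample and
#' permutation counts, the radius grid and significance level.
#'
#' @slot name scenario label.
#' @slot lambda point intensity per unit area.
#' @slot k number of phenotype kernels (clusters).
#' @slot sdRange numeric(2): bounds of the cluster bandwidth draw.
#' @slot probRange numeric(2): phenotype abundance bounds (prob_min, prob_max).
#' @slot nSims,nPerm sample and permutation counts.
#' @slot window the simulation window.
#' @slot radii radius grid for the summary functions.
#' @slot alpha significance level.
#' @slot seed master seed of the run.
#' @slot tissueParams,holeParams named lists (k, sdmin, sdmax, probs) for the
#'   tissue and hole stages.
#'
#' @seealso [scenarioConfig()], [runScenario()]
#' @export
setClass("ScenarioConfig",
  representation(
    name = "character", lambda = "numeric", k = "integer",
    sdRange = "numeric", probRange = "numeric",
    nSims = "integer", nPerm = "integer",
    window = "SimWindow", radii = "numeric", alpha = "numeric",
    seed = "integer", tissueParams = "list", holeParams = "list"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be non-negative")
  if (object@k < 0L) msg <- c(msg, "k must be non-negative")
  if (object@sdRange[1] <= 0 || object@sdRange[1] > object@sdRange[2])
    msg <- c(msg, "sdRange must be positive and ordered")
  pr <- object@probRange
  if (pr[1] < 0 || pr[2] > 1 || pr[1] > pr[2])
    msg <- c(msg, "probRange must be ordered and within [0, 1]")
  if (object@nSims < 1L) msg <- c(msg, "nSims must be >= 1")
  if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
  if (any(diff(object@radii) <= 0) || any(object@radii < 0))
    msg <- c(msg, "radii must be non-negative and strictly increasing")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Per-sample significance calls of a benchmark run
#'
#' @slot config the [ScenarioConfig-class] that produced the run.
#' @slot significant logical array samples x radii x statistics: p < alpha.
#' @slot evaluable logical array of the same shape: the statistic could be
#'   computed and its p-value is defined at that radius.
#' @slot excluded integer ids of samples with fewer than 2 positive cells.
#' @slot statNames statistics evaluated (K, G, g).
#'
#' @seealso [runScenario()], [summariseBenchmark()]
#' @export
setClass("ScenarioResult",
  representation(
    config = "ScenarioConfig",
    significant = "array", evaluable = "array",
    excluded = "integer", statNames = "character"
  )
)
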