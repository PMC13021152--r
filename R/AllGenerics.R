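#' @rdname SimWindow-class
#' @param object,x a package object.
#' @export
setGeneric("xrange", function(x) standardGeneric("xrange"))

#' @rdname SimWindow-class
#' @export
setGeneric("yrange", function(x) standardGeneric("yrange"))

#' @rdname SimWindow-class
#' @export
setGeneric("windowArea", function(x) standardGeneric("windowArea"))

#' @rdname SpatialSimulation-class
#' @export
setGeneric("nSims", function(x) standardGeneric("nSims"))

#' @rdname SpatialSimulation-class
#' @export
setGeneric("nCellTypes", function(x) standardGeneric("nCellTypes"))

#' @rdname SpatialSimulation-class
#' @export
setGeneric("simulationWindow", function(x) standardGeneric("simulationWindow"))

#' @rdname SpatialSimulation-class
#' @export
setGeneric("pointIntensity", function(x) standardGeneric("pointIntensity"))

#' @rdname SpatialSimulation-class
#' @export
setGeneric("pointPatterns", function(x) standardGeneric("pointPatterns"))

#' @rdname KernelSet-class
#' @export
setGeneric("nKernels", function(x) standardGeneric("nKernels"))

#' @rdname KernelSet-class
#' @export
setGeneric("kernelCenters", function(x) standardGeneric("kernelCenters"))

#' @rdname KernelSet-class
#' @export
setGeneric("kernelSds", function(x) standardGeneric("kernelSds"))

#' @rdname KernelSet-class
#' @export
setGeneric("probRange", function(x) standardGeneric("probRange"))

#' Generate the homogeneous Poisson point patterns of a simulation
#'
#' @param x a [SpatialSimulation-class].
#' @param ... stage parameters; see the method documentation.
#' @export
setGeneric("generatePointPattern",
           function(x, ...) standardGeneric("generatePointPattern"))

#' Assign cells to tissue compartments from a probability surface
#' @inheritParams generatePointPattern
#' @export
setGeneric("generateTissue", function(x, ...) standardGeneric("generateTissue"))

#' Flag cells falling in non-cellular holes
#' @inheritParams generatePointPattern
#' @export
setGeneric("generateHoles", function(x, ...) standardGeneric("generateHoles"))

#' Assign phenotype positivity from per-type probability surfaces
#' @inheritParams generatePointPattern
#' @export
setGeneric("generateCellPositivity",
           function(x, ...) standardGeneric("generateCellPositivity"))

#' Draw continuous marker values conditional on positivity
#' @inheritParams generatePointPattern
#' @export
setGeneric("generateMarkerValues",
           function(x, ...) standardGeneric("generateMarkerValues"))

#' Materialise per-sample cell tables
#' @inheritParams generatePointPattern
#' @export
setGeneric("cellTables", function(x, ...) standardGeneric("cellTables"))

#' Run the simulate-then-test pipeline of a benchmarking scenario
#' @param x a [ScenarioConfig-class].
#' @param ... see the method documentation.
#' @export
setGeneric("runScenario", function(x, ...) standardGeneric("runScenario"))

#' Tabulate most-significant and all-significant radius counts
#' @param x a [ScenarioResult-class] or a list of them.
#' @param ... unused.
#' @export
setGeneric("summariseBenchmark",
           function(x, ...) standardGeneric("summariseBenchmark"))

#' Per-radius significance calls of a permutation test
#' @param x a [PermutationResult-class].
#' @param ... unused.
#' @export
setGeneric("isSignificant", function(x, ...) standardGeneric("isSignificant"))
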