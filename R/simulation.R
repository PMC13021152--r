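#' Create a spatial simulation object
#'
#' Initialises the accumulating state for `nSims` independent samples in a
#' rectangular window. Stages are then applied in order:
#' [generatePointPattern()], [generateTissue()], [generateHoles()],
#' [generateCellPositivity()], [generateMarkerValues()]; each fills its slot
#' for every sample. Use one cell type to study clustering, two or more to
#' study colocalization.
#'
#' @param nSims number of independent samples (>= 1).
#' @param window a [SimWindow-class] (default the 2 x 2 window centred at 0).
#' @param nCellTypes number of phenotypes per cell (>= 1).
#' @param seed master seed; every stage and sample derives a reproducible
#'   substream from it.
#'
#' @return a [SpatialSimulation-class] with empty stage slots.
#' @examples
#' sim <- spatialSimulation(nSims = 3, seed = 11)
#' sim <- generatePointPattern(sim, lambda = 100)
#' nSims(sim)
#' @export
spatialSimulation <- function(nSims, window = simWindow(), nCellTypes = 1L,
                              seed = 1L) {
  nSims <- .checkCount(nSims, "nSims")
  nCellTypes <- .checkCount(nCellTypes, "nCellTypes")
  stopifnot(is(window, "SimWindow"))
  validObject(window)
  new("SpatialSimulation", window = window, nSims = nSims,
      nCellTypes = nCellTypes, seed = as.integer(seed))
}

.checkCount <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x))
    stop(what, " must be a single integer >= 1", call. = FALSE)
  as.integer(x)
}

#' @describeIn generatePointPattern draws, for each sample, a point count
#'   `N ~ Poisson(lambda * area)` and places the N points uniformly and
#'   independently in the window (a homogeneous Poisson process, the CSR
#'   null model). Reproducible given the object's seed.
#' @param lambda point (cell) intensity per unit area, >= 0.
#' @param overwrite set TRUE to regenerate over existing patterns.
#' @return the updated [SpatialSimulation-class].
#' @export
setMethod("generatePointPattern", "SpatialSimulation",
  function(x, lambda, overwrite = FALSE) {
    if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
      stop("lambda must be a single non-negative number", call. = FALSE)
    if (length(x@patterns) && !overwrite)
      stop("point patterns already exist; use overwrite = TRUE to regenerate",
           call. = FALSE)
    w <- x@window
    mu <- lambda * windowArea(w)
    x@patterns <- lapply(seq_len(x@nSims), function(i) {
      .withSeed(.substreamSeed(x@seed, i, .STAGE[["pattern"]]), {
        n <- stats::rpois(1L, mu)
        cbind(x = stats::runif(n, w@xrange[1], w@xrange[2]),
              y = stats::runif(n, w@yrange[1], w@yrange[2]))
      })
    })
    x@lambda <- as.numeric(lambda)
    validObject(x)
    x
  })

.requirePatterns <- function(x) {
  if (!length(x@patterns))
    stop("no point patterns yet; call generatePointPattern() first",
         call. = FALSE)
}

#' @rdname SpatialSimulation-class
#' @export
setMethod("nSims", "SpatialSimulation", function(x) x@nSims)

#' @rdname SpatialSimulation-class
#' @export
setMethod("nCellTypes", "SpatialSimulation", function(x) x@nCellTypes)

#' @rdname SpatialSimulation-class
#' @export
setMethod("simulationWindow", "SpatialSimulation", function(x) x@window)

#' @rdname SpatialSimulation-class
#' @export
setMethod("pointIntensity", "SpatialSimulation", function(x) x@lambda)

#' @rdname SpatialSimulation-class
#' @export
setMethod("pointPatterns", "SpatialSimulation", function(x) x@patterns)

setMethod("show", "SpatialSimulation", function(object) {
  cat("SpatialSimulation:", object@nSims, "sample(s),",
      object@nCellTypes, "cell type(s)\n")
  show(object@window)
  stageLine <- function(label, done, extra = "") {
    cat(sprintf("  %-22s %s%s\n", label,
                if (done) "done" else "pending", extra))
  }
  stageLine("point patterns", length(object@patterns) > 0L,
            if (!is.na(object@lambda))
              sprintf(" (lambda = %g)", object@lambda) else "")
  stageLine("tissue compartments", length(object@tissue) > 0L)
  stageLine("holes", length(object@holes) > 0L)
  stageLine("cell positivity", length(object@positivity) > 0L)
  stageLine("marker values", length(object@markerValues) > 0L)
})
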