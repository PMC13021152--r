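# Label stages: each samples per-sample kernel surfaces and draws per-cell
# Bernoulli labels from them. All stages are stochastic thinnings of the
# surface (no hard thresholds), mirroring how phenotype positivity works, so
# "low probability" regions are only *likely* to get the complementary label.

.replaceGuard <- function(present, what, overwrite) {
  if (present && !overwrite)
    stop(what, " already assigned; use overwrite = TRUE to regenerate",
         call. = FALSE)
}

#' @describeIn generateTissue samples, per sample, a fresh kernel set and
#'   labels each cell "Tissue 1" with the surface probability at its
#'   location, "Tissue 2" otherwise (independent Bernoulli draws). High
#'   probability regions therefore form the first compartment. Kernel sets
#'   are stored for later density export.
#' @param k,sdmin,sdmax,probs kernel-set parameters; see [sampleKernels()].
#'   Defaults give two broad compartment kernels.
#' @param overwrite set TRUE to regenerate existing labels.
#' @return the updated [SpatialSimulation-class].
#' @export
setMethod("generateTissue", "SpatialSimulation",
  function(x, k = 2L, sdmin = 0.4, sdmax = 0.6, probs = c(0.2, 0.8),
           overwrite = FALSE) {
    .requirePatterns(x)
    .replaceGuard(length(x@tissue) > 0L, "tissue", overwrite)
    res <- .surfaceBernoulli(x, .STAGE[["tissue"]], k, sdmin, sdmax, probs)
    x@tissueKernels <- res$kernels
    x@tissue <- lapply(res$flags,
                       function(f) ifelse(f, "Tissue 1", "Tissue 2"))
    validObject(x)
    x
  })

#' @describeIn generateHoles draws, per sample, a hole probability surface
#'   and flags each cell as lying in a non-cellular hole (necrosis, tissue
#'   fold) by an independent Bernoulli draw. Holes let downstream analyses
#'   probe violations of stationarity. Cells are flagged, not removed;
#'   `drop` only sets the default of [cellTables()].
#' @param k,sdmin,sdmax,probs kernel-set parameters; defaults give one small
#'   focal hole kernel.
#' @param drop default for dropping hole cells at export time.
#' @param overwrite set TRUE to regenerate existing flags.
#' @return the updated [SpatialSimulation-class].
#' @export
setMethod("generateHoles", "SpatialSimulation",
  function(x, k = 1L, sdmin = 0.1, sdmax = 0.2, probs = c(0.1, 0.3),
           drop = FALSE, overwrite = FALSE) {
    .requirePatterns(x)
    .replaceGuard(length(x@holes) > 0L, "holes", overwrite)
    res <- .surfaceBernoulli(x, .STAGE[["holes"]], k, sdmin, sdmax, probs)
    x@holeKernels <- res$kernels
    x@holes <- res$flags
    x@holeDrop <- isTRUE(drop)
    validObject(x)
    x
  })

# Shared tissue/hole machinery: per sample, substream -> kernel set ->
# surface evaluation -> independent uniform draws.
.surfaceBernoulli <- function(x, stage, k, sdmin, sdmax, probs) {
  kernels <- vector("list", x@nSims)
  flags <- vector("list", x@nSims)
  for (i in seq_len(x@nSims)) {
    pts <- x@patterns[[i]]
    .withSeed(.substreamSeed(x@seed, i, stage), {
      kset <- sampleKernels(k, x@window, sdmin, sdmax, probs)
      p <- evaluateSurface(kset, pts[, 1L], pts[, 2L])
      u <- stats::runif(nrow(pts))
      kernels[[i]] <- kset
      flags[[i]] <- u < p
    })
  }
  list(kernels = kernels, flags = flags)
}

#' @describeIn generateCellPositivity assigns, per sample, phenotype
#'   positivity for each cell type. Cell type 1 receives a fresh kernel set;
#'   each further type t receives the type t-1 set displaced by
#'   [shiftKernels()] with the given `shift`, so `shift = 0` makes all types
#'   share one surface (maximal colocalization) and `shift = 1` separates
#'   them by half the domain. Each cell's positivity per type is an
#'   independent Bernoulli draw from that type's surface at the cell
#'   location.
#' @param k,sdmin,sdmax,probs kernel-set parameters; see [sampleKernels()].
#' @param shift displacement fraction in [0, 1] between consecutive cell
#'   types; ignored (with a warning) when there is a single cell type.
#' @param overwrite set TRUE to regenerate existing positivity.
#' @return the updated [SpatialSimulation-class].
#' @export
setMethod("generateCellPositivity", "SpatialSimulation",
  function(x, k = 5L, sdmin = 0.1, sdmax = 0.3, probs = c(0.01, 0.75),
           shift = 0, overwrite = FALSE) {
    .requirePatterns(x)
    .replaceGuard(length(x@positivity) > 0L, "cell positivity", overwrite)
    if (shift != 0 && x@nCellTypes == 1L) {
      warning("shift is ignored with a single cell type", call. = FALSE)
      shift <- 0
    }
    if (shift < 0 || shift > 1)
      stop("shift must be in [0, 1]", call. = FALSE)
    nT <- x@nCellTypes
    x@cellKernels <- vector("list", x@nSims)
    x@positivity <- vector("list", x@nSims)
    for (i in seq_len(x@nSims)) {
      pts <- x@patterns[[i]]
      n <- nrow(pts)
      .withSeed(.substreamSeed(x@seed, i, .STAGE[["cells"]]), {
        ksets <- vector("list", nT)
        ksets[[1L]] <- sampleKernels(k, x@window, sdmin, sdmax, probs)
        for (t in seq_len(nT)[-1L])
          ksets[[t]] <- shiftKernels(ksets[[t - 1L]], shift, x@window)
        pos <- matrix(0L, nrow = n, ncol = nT,
                      dimnames = list(NULL, paste("Cell", seq_len(nT))))
        for (t in seq_len(nT)) {
          p <- evaluateSurface(ksets[[t]], pts[, 1L], pts[, 2L])
          pos[, t] <- as.integer(stats::runif(n) < p)
        }
        x@cellKernels[[i]] <- ksets
        x@positivity[[i]] <- pos
      })
    }
    validObject(x)
    x
  })

#' Construct a continuous-marker distribution specification
#'
#' @param meanPos,sdPos mean and sd of the marker in positive cells.
#' @param meanNeg,sdNeg mean and sd in negative cells. `sd* >= 0`; zero sd
#'   gives a point mass.
#' @return a [MarkerDistribution-class].
#' @examples
#' markerDistribution(meanPos = 10, sdPos = 1, meanNeg = 5, sdNeg = 1)
#' @export
markerDistribution <- function(meanPos, sdPos, meanNeg, sdNeg) {
  new("MarkerDistribution", meanPos = as.numeric(meanPos),
      sdPos = as.numeric(sdPos), meanNeg = as.numeric(meanNeg),
      sdNeg = as.numeric(sdNeg))
}

setMethod("show", "MarkerDistribution", function(object) {
  cat(sprintf("MarkerDistribution: pos ~ N(%g, %g), neg ~ N(%g, %g)\n",
              object@meanPos, object@sdPos, object@meanNeg, object@sdNeg))
})

#' @describeIn generateMarkerValues draws, for every cell and cell type, a
#'   continuous marker value (protein abundance, expression): positive cells
#'   from `Normal(meanPos, sdPos)`, negative cells from
#'   `Normal(meanNeg, sdNeg)`, independently across cells and types.
#'   Requires positivity to have been assigned.
#' @param distributions one [MarkerDistribution-class] (recycled across cell
#'   types) or a list with one per cell type. No defaults: the positive /
#'   negative separation is the effect size under study.
#' @param overwrite set TRUE to regenerate existing values.
#' @return the updated [SpatialSimulation-class].
#' @export
setMethod("generateMarkerValues", "SpatialSimulation",
  function(x, distributions, overwrite = FALSE) {
    if (!length(x@positivity))
      stop("cell positivity must be assigned before marker values",
           call. = FALSE)
    .replaceGuard(length(x@markerValues) > 0L, "marker values", overwrite)
    if (is(distributions, "MarkerDistribution"))
      distributions <- rep(list(distributions), x@nCellTypes)
    if (!is.list(distributions) || length(distributions) != x@nCellTypes ||
        !all(vapply(distributions, is, logical(1), "MarkerDistribution")))
      stop("distributions must be one MarkerDistribution per cell type",
           call. = FALSE)
    lapply(distributions, validObject)
    nT <- x@nCellTypes
    x@markerValues <- vector("list", x@nSims)
    for (i in seq_len(x@nSims)) {
      pos <- x@positivity[[i]]
      n <- nrow(pos)
      .withSeed(.substreamSeed(x@seed, i, .STAGE[["markers"]]), {
        vals <- matrix(NA_real_, nrow = n, ncol = nT)
        for (t in seq_len(nT)) {
          d <- distributions[[t]]
          vals[, t] <- ifelse(pos[, t] == 1L,
                              stats::rnorm(n, d@meanPos, d@sdPos),
                              stats::rnorm(n, d@meanNeg, d@sdNeg))
        }
        x@markerValues[[i]] <- vals
      })
    }
    validObject(x)
    x
  })
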