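#' Sample a Gaussian kernel set
#'
#' Draws `k` isotropic Gaussian kernels with centres uniform over the window
#' and bandwidths `sd ~ Uniform(sdmin, sdmax)`, independently per kernel.
#' The kernels define a probability surface rescaled into
#' `[probs[1], probs[2]]`; see [KernelSet-class] for the exact field.
#' Draws come from the current RNG stream.
#'
#' @param k number of kernels (>= 0).
#' @param window a [SimWindow-class].
#' @param sdmin,sdmax bandwidth bounds, `0 < sdmin <= sdmax`, in window units.
#' @param probs numeric(2) in [0, 1], ordered: probability bounds of the
#'   scaled surface.
#'
#' @return a [KernelSet-class].
#' @examples
#' set.seed(1)
#' ks <- sampleKernels(5, simWindow(), 0.1, 0.3, c(0.01, 0.75))
#' kernelSds(ks)
#' @export
sampleKernels <- function(k, window, sdmin, sdmax, probs) {
  if (length(k) != 1L || is.na(k) || k < 0 || k != as.integer(k))
    stop("k must be a single integer >= 0", call. = FALSE)
  k <- as.integer(k)
  if (!is.finite(sdmin) || !is.finite(sdmax) || sdmin <= 0 || sdmin > sdmax)
    stop("need 0 < sdmin <= sdmax", call. = FALSE)
  .checkProbs(probs)
  centers <- cbind(x = stats::runif(k, window@xrange[1], window@xrange[2]),
                   y = stats::runif(k, window@yrange[1], window@yrange[2]))
  sds <- stats::runif(k, sdmin, sdmax)
  new("KernelSet", centers = centers, sds = sds,
      probRange = as.numeric(probs))
}

.checkProbs <- function(probs) {
  if (length(probs) != 2L || anyNA(probs) || probs[1] < 0 || probs[2] > 1 ||
      probs[1] > probs[2])
    stop("probs must be an ordered pair within [0, 1]", call. = FALSE)
  invisible(probs)
}

#' Evaluate a probability surface at points
#'
#' The raw field is the pointwise maximum of unit-peak Gaussian bumps,
#' \eqn{s(x,y) = \max_k \exp(-d_k^2 / (2\sigma_k^2))} with \eqn{d_k} the
#' distance to centre k, so \eqn{s \in [0,1]} and the peak is exactly 1 at
#' every centre. The returned probability is the affine map
#' \eqn{p = p_{min} + (p_{max} - p_{min}) s}; with zero kernels,
#' \eqn{p \equiv p_{min}}. The max combination (rather than a sum) keeps
#' overlapping clusters from exceeding \eqn{p_{max}}, making the bounds exact.
#'
#' @param kset a [KernelSet-class].
#' @param x,y coordinate vectors of equal length.
#'
#' @return numeric vector of probabilities in `[probRange(kset)]`.
#' @export
evaluateSurface <- function(kset, x, y) {
  stopifnot(is(kset, "KernelSet"), length(x) == length(y))
  validObject(kset)
  s <- numeric(length(x))
  for (i in seq_along(kset@sds)) {
    d2 <- (x - kset@centers[i, 1L])^2 + (y - kset@centers[i, 2L])^2
    s <- pmax(s, exp(-d2 / (2 * kset@sds[i]^2)))
  }
  pr <- kset@probRange
  pr[1] + (pr[2] - pr[1]) * s
}

#' Shift a kernel set to decouple two phenotype surfaces
#'
#' Translates every kernel centre by a displacement of magnitude
#' `shift * width(window) / 2` in an independently drawn uniform random
#' direction, wrapping centres torus-style back into the window. Bandwidths
#' and the probability range are untouched. `shift = 0` returns the input
#' unchanged (perfect surface sharing, maximal colocalization); `shift = 1`
#' moves every cluster half the domain away. Draws come from the current RNG
#' stream.
#'
#' @param kset a [KernelSet-class].
#' @param shift displacement fraction in [0, 1].
#' @param window a [SimWindow-class].
#'
#' @return a [KernelSet-class] with displaced centres.
#' @export
shiftKernels <- function(kset, shift, window) {
  stopifnot(is(kset, "KernelSet"))
  if (length(shift) != 1L || is.na(shift) || shift < 0 || shift > 1)
    stop("shift must be a single number in [0, 1]", call. = FALSE)
  if (shift == 0) return(kset)
  k <- length(kset@sds)
  mag <- shift * diff(window@xrange) / 2
  theta <- stats::runif(k, 0, 2 * pi)
  newx <- kset@centers[, 1L] + mag * cos(theta)
  newy <- kset@centers[, 2L] + mag * sin(theta)
  wx <- diff(window@xrange); wy <- diff(window@yrange)
  kset@centers[, 1L] <- window@xrange[1] + ((newx - window@xrange[1]) %% wx)
  kset@centers[, 2L] <- window@yrange[1] + ((newy - window@yrange[1]) %% wy)
  kset
}

#' Probability surface on a regular grid
#'
#' Evaluates the scaled surface at the centres of a `resolution` by
#' `resolution` grid of cells tiling the window, for visualisation or export;
#' values are obtained through [evaluateSurface()], so grid nodes agree
#' exactly with point evaluations.
#'
#' @param kset a [KernelSet-class].
#' @param window a [SimWindow-class].
#' @param resolution number of grid cells per axis (>= 1).
#'
#' @return data.frame with columns `x`, `y`, `probability`
#'   (`resolution^2` rows, y varying fastest).
#' @seealso [writeDensityGrid()]
#' @export
densityGrid <- function(kset, window, resolution = 100L) {
  resolution <- .checkCount(resolution, "resolution")
  cx <- window@xrange[1] +
    (seq_len(resolution) - 0.5) * diff(window@xrange) / resolution
  cy <- window@yrange[1] +
    (seq_len(resolution) - 0.5) * diff(window@yrange) / resolution
  grid <- expand.grid(y = cy, x = cx)[, c("x", "y")]
  grid$probability <- evaluateSurface(kset, grid$x, grid$y)
  rownames(grid) <- NULL
  grid
}

#' Write a density grid as CSV
#'
#' @param grid output of [densityGrid()].
#' @param file path of the CSV to write (columns x, y, probability).
#' @return the file path, invisibly.
#' @export
writeDensityGrid <- function(grid, file) {
  utils::write.csv(grid, file, row.names = FALSE)
  invisible(file)
}

#' @rdname KernelSet-class
#' @export
setMethod("nKernels", "KernelSet", function(x) length(x@sds))

#' @rdname KernelSet-class
#' @export
setMethod("kernelCenters", "KernelSet", function(x) x@centers)

#' @rdname KernelSet-class
#' @export
setMethod("kernelSds", "KernelSet", function(x) x@sds)

#' @rdname KernelSet-class
#' @export
setMethod("probRange", "KernelSet", function(x) x@probRange)

setMethod("show", "KernelSet", function(object) {
  cat(sprintf("KernelSet: %d kernel(s), prob range [%g, %g]\n",
              length(object@sds), object@probRange[1], object@probRange[2]))
  if (length(object@sds))
    cat(sprintf("  bandwidths in [%g, %g]\n",
                min(object@sds), max(object@sds)))
})
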