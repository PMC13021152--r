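# Spatial summary functions. The O(n^2) pair computations live in compiled
# code (src/spatial_stats.cpp); these wrappers validate inputs and attach
# the CSR reference curves.

.checkRadii <- function(radii, window) {
  if (!length(radii) || anyNA(radii) || any(radii < 0))
    stop("radii must be non-negative numbers", call. = FALSE)
  if (is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing", call. = FALSE)
  maxr <- min(diff(window@xrange), diff(window@yrange)) / 2
  if (max(radii) > maxr)
    stop(sprintf("radii must not exceed half the shorter window side (%g)",
                 maxr), call. = FALSE)
  as.numeric(radii)
}

.checkPoints <- function(x, y) {
  if (length(x) != length(y) || anyNA(x) || anyNA(y))
    stop("x and y must be equal-length coordinate vectors without NAs",
         call. = FALSE)
}

.statCurve <- function(radii, est, theo) {
  data.frame(r = radii, theo = theo, est = est)
}

.tooFew <- function(radii, theo, what) {
  warning("fewer than 2 points; ", what, " is undefined for this pattern",
          call. = FALSE)
  .statCurve(radii, rep(NA_real_, length(radii)), theo)
}

#' Ripley's K function with translation edge correction
#'
#' Estimates \deqn{\hat K(r) = \frac{|W|}{n(n-1)} \sum_{i \ne j}
#' 1\{d_{ij} \le r\}\, w_{ij}, \qquad
#' w_{ij} = \frac{|W|}{(W_x - |\Delta x_{ij}|)(W_y - |\Delta y_{ij}|)}}
#' for points in a rectangular window of sides \eqn{W_x, W_y} and area
#' \eqn{|W|}. Under complete spatial randomness (CSR) the expectation is
#' \eqn{\pi r^2}, returned in the `theo` column.
#'
#' @param x,y point coordinates (typically the positive cells of one sample).
#' @param radii strictly increasing radii, at most half the shorter window
#'   side.
#' @param window a [SimWindow-class].
#'
#' @return data.frame with columns `r`, `theo` (CSR reference), `est`.
#'   With fewer than 2 points the estimate is all `NA`, with a warning.
#' @examples
#' set.seed(7)
#' w <- simWindow()
#' x <- runif(200, -1, 1); y <- runif(200, -1, 1)
#' head(ripleysK(x, y, seq(0.05, 0.25, 0.05), w))
#' @export
ripleysK <- function(x, y, radii, window = simWindow()) {
  .checkPoints(x, y)
  radii <- .checkRadii(radii, window)
  theo <- pi * radii^2
  if (length(x) < 2L) return(.tooFew(radii, theo, "Ripley's K"))
  res <- cpp_spatial_stats(x, y, radii,
                           window@xrange[1], window@xrange[2],
                           window@yrange[1], window@yrange[2],
                           0, TRUE, FALSE, FALSE)
  .statCurve(radii, res$K, theo)
}

#' Nearest-neighbour distance distribution G with border correction
#'
#' Reduced-sample (border-corrected) empirical CDF of nearest-neighbour
#' distances: at radius r, among the points lying farther than r from the
#' window boundary, the fraction whose nearest neighbour is within r. The
#' CSR reference is \eqn{1 - \exp(-\hat\lambda \pi r^2)} with
#' \eqn{\hat\lambda = n / |W|}. Radii for which no point is interior give
#' `NA`.
#'
#' @inheritParams ripleysK
#' @return data.frame with columns `r`, `theo`, `est`.
#' @export
nearestNeighbourG <- function(x, y, radii, window = simWindow()) {
  .checkPoints(x, y)
  radii <- .checkRadii(radii, window)
  lambdaHat <- length(x) / windowArea(window)
  theo <- 1 - exp(-lambdaHat * pi * radii^2)
  if (length(x) < 2L) return(.tooFew(radii, theo, "nearest-neighbour G"))
  res <- cpp_spatial_stats(x, y, radii,
                           window@xrange[1], window@xrange[2],
                           window@yrange[1], window@yrange[2],
                           0, FALSE, TRUE, FALSE)
  .statCurve(radii, res$G, theo)
}

#' Pair correlation function g with translation edge correction
#'
#' Kernel-smoothed density of pair distances, normalised so the CSR
#' expectation is 1: \deqn{\hat g(r) = \frac{|W|}{2\pi r\, n(n-1)}
#' \sum_{i \ne j} \kappa_b(r - d_{ij})\, w_{ij}} with the Epanechnikov
#' kernel \eqn{\kappa_b(u) = \frac{3}{4b}(1 - u^2/b^2)_+} and the same
#' translation weights as [ripleysK()]. `bandwidth = "auto"` applies
#' Stoyan's rule \eqn{b = 0.15 / \sqrt{\hat\lambda}}. `r = 0` is undefined
#' and reported `NA`.
#'
#' @inheritParams ripleysK
#' @param bandwidth positive half-width of the smoothing kernel, or
#'   `"auto"`.
#' @return data.frame with columns `r`, `theo` (constant 1), `est`.
#' @export
pairCorrelation <- function(x, y, radii, window = simWindow(),
                            bandwidth = "auto") {
  .checkPoints(x, y)
  radii <- .checkRadii(radii, window)
  theo <- rep(1, length(radii))
  if (length(x) < 2L) return(.tooFew(radii, theo, "pair correlation"))
  bw <- .pcfBandwidth(bandwidth, length(x), windowArea(window))
  res <- cpp_spatial_stats(x, y, radii,
                           window@xrange[1], window@xrange[2],
                           window@yrange[1], window@yrange[2],
                           bw, FALSE, FALSE, TRUE)
  .statCurve(radii, res$g, theo)
}

.pcfBandwidth <- function(bandwidth, n, area) {
  if (identical(bandwidth, "auto")) return(0.15 / sqrt(n / area))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("bandwidth must be a single positive number or \"auto\"",
         call. = FALSE)
  bandwidth
}

#' Label-permutation test for the degree of clustering
#'
#' Tests whether the positive cells of one sample are more clustered than
#' expected when the same number of positive labels is scattered uniformly
#' over all cell locations. The observed statistic is computed on the
#' positive cells; each of `nPerm` permutations reassigns the positive
#' labels uniformly at random over all cells (keeping the positive count
#' fixed) and recomputes it. Per radius and statistic the test reports the
#' degree of clustering (observed minus permutation mean) and the one-sided
#' add-one p-value \eqn{p = (1 + \#\{perm \ge obs\}) / (1 + n_{valid})},
#' which is never exactly 0; larger statistics mean more clustering, so
#' small p indicates significant clustering. The same permutations are
#' shared by all requested statistics. Uses the current RNG stream.
#'
#' @param table a per-sample cell table from [cellTables()], or any
#'   data.frame with `x`, `y` and a 0/1 marker column.
#' @param marker name of the binary marker column.
#' @param stats which statistics to evaluate: subset of `"K"`
#'   ([ripleysK()]), `"G"` ([nearestNeighbourG()]), `"g"`
#'   ([pairCorrelation()]).
#' @param radii strictly increasing radii; a radius of 0 is allowed but the
#'   pair correlation is `NA` there.
#' @param nPerm number of label permutations.
#' @param alpha significance level for [isSignificant()].
#' @param window a [SimWindow-class].
#' @param bandwidth pair-correlation bandwidth; see [pairCorrelation()].
#' @param nullQuantiles two probabilities for the reported null envelope.
#'
#' @return a [PermutationResult-class]. With fewer than 2 positive cells the
#'   result is flagged non-evaluable (all matrices `NA`) with a warning.
#' @examples
#' sim <- spatialSimulation(1, seed = 5)
#' sim <- generatePointPattern(sim, lambda = 150)
#' sim <- generateCellPositivity(sim, k = 3)
#' tab <- cellTables(sim)[[1]]
#' set.seed(99)
#' pr <- permutationTest(tab, nPerm = 39, radii = seq(0.05, 0.25, 0.05))
#' as.data.frame(pr)[1:5, ]
#' @export
permutationTest <- function(table, marker = "Cell 1 Assignment",
                            stats = c("K", "G", "g"),
                            radii = seq(0.01, 0.5, by = 0.01),
                            nPerm = 100L, alpha = 0.05,
                            window = simWindow(), bandwidth = "auto",
                            nullQuantiles = c(0.025, 0.975)) {
  stats <- match.arg(stats, c("K", "G", "g"), several.ok = TRUE)
  if (!all(c("x", "y", marker) %in% names(table)))
    stop("table must contain columns x, y and '", marker, "'", call. = FALSE)
  nPerm <- .checkCount(nPerm, "nPerm")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (anyNA(radii) || any(radii < 0) || is.unsorted(radii, strictly = TRUE))
    stop("radii must be non-negative and strictly increasing", call. = FALSE)
  radii <- as.numeric(radii)
  labels <- table[[marker]]
  if (!all(labels %in% c(0L, 1L)))
    stop("marker column must be 0/1", call. = FALSE)
  n <- nrow(table)
  m <- sum(labels == 1L)
  nr <- length(radii)
  ns <- length(stats)
  blank <- matrix(NA_real_, nr, ns, dimnames = list(NULL, stats))
  if (m < 2L) {
    warning("fewer than 2 positive cells; sample is not evaluable",
            call. = FALSE)
    return(new("PermutationResult", radii = radii, statNames = stats,
               observed = blank, nullMean = blank, nullLo = blank,
               nullHi = blank, degree = blank, pValue = blank,
               nPerm = nPerm, alpha = alpha, nPositive = m,
               evaluable = FALSE))
  }
  px <- table$x
  py <- table$y
  bw <- if ("g" %in% stats) .pcfBandwidth(bandwidth, m, windowArea(window))
        else 0
  evalStats <- function(idx) {
    res <- cpp_spatial_stats(px[idx], py[idx], radii,
                             window@xrange[1], window@xrange[2],
                             window@yrange[1], window@yrange[2],
                             bw, "K" %in% stats, "G" %in% stats,
                             "g" %in% stats)
    matrix(vapply(stats, function(s) res[[s]], numeric(nr)),
           nrow = nr, ncol = ns, dimnames = list(NULL, stats))
  }
  observed <- evalStats(which(labels == 1L))
  nulls <- array(NA_real_, c(nPerm, nr, ns))
  for (p in seq_len(nPerm)) {
    # sorted so an all-positive marker reproduces the observed value exactly
    idx <- sort(sample.int(n, m))
    nulls[p, , ] <- evalStats(idx)
  }
  nullMean <- blank; nullLo <- blank; nullHi <- blank; pValue <- blank
  for (s in seq_len(ns)) {
    for (t in seq_len(nr)) {
      perm <- nulls[, t, s]
      valid <- !is.na(perm)
      obs <- observed[t, s]
      nullMean[t, s] <- mean(perm[valid])
      if (any(valid)) {
        q <- stats::quantile(perm[valid], nullQuantiles, names = FALSE)
        nullLo[t, s] <- q[1]
        nullHi[t, s] <- q[2]
      }
      if (!is.na(obs) && any(valid))
        pValue[t, s] <- (1 + sum(perm[valid] >= obs)) / (1 + sum(valid))
    }
  }
  new("PermutationResult", radii = radii, statNames = stats,
      observed = observed, nullMean = nullMean, nullLo = nullLo,
      nullHi = nullHi, degree = observed - nullMean, pValue = pValue,
      nPerm = nPerm, alpha = alpha, nPositive = as.integer(m),
      evaluable = TRUE)
}

#' @describeIn isSignificant logical matrix (radii x statistics): one-sided
#'   p-value below `alpha`; `NA` where the statistic was not evaluable.
#' @param alpha optional override of the level stored in the result.
#' @export
setMethod("isSignificant", "PermutationResult",
  function(x, alpha = x@alpha) {
    x@pValue < alpha
  })

#' @describeIn PermutationResult-class long-format view: one row per
#'   statistic and radius with observed, null mean/envelope, degree of
#'   clustering, p-value and significance call.
#' @param x a [PermutationResult-class].
#' @param row.names,optional,... ignored (base signature).
#' @export
setMethod("as.data.frame", "PermutationResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    nr <- length(x@radii)
    out <- do.call(rbind, lapply(seq_along(x@statNames), function(s) {
      data.frame(stat = x@statNames[s], r = x@radii,
                 observed = x@observed[, s], null_mean = x@nullMean[, s],
                 null_lo = x@nullLo[, s], null_hi = x@nullHi[, s],
                 degree_of_clustering = x@degree[, s],
                 p_value = x@pValue[, s],
                 significant = x@pValue[, s] < x@alpha)
    }))
    rownames(out) <- NULL
    out
  })

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %s over %d radii, %d permutations\n",
              paste(object@statNames, collapse = "/"),
              length(object@radii), object@nPerm))
  if (!object@evaluable) {
    cat("  not evaluable (fewer than 2 positive cells)\n")
  } else {
    sig <- isSignificant(object)
    for (s in seq_along(object@statNames))
      cat(sprintf("  %s: significant clustering at %d/%d radii (alpha = %g)\n",
                  object@statNames[s], sum(sig[, s], na.rm = TRUE),
                  sum(!is.na(sig[, s])), object@alpha))
  }
})

#' Bivariate nearest-neighbour co-occurrence of two phenotypes
#'
#' Fraction of cells positive for `markerA` that have at least one
#' `markerB`-positive cell within distance `r` (a cell positive for both
#' counts at distance 0). A simple colocalization read-out: it decreases as
#' the surfaces of the two phenotypes are shifted apart.
#'
#' @param table a cell table with `x`, `y` and the two 0/1 marker columns.
#' @param markerA,markerB the two marker column names.
#' @param r co-occurrence radius.
#' @return a single fraction, or `NA` if either phenotype has no cells.
#' @export
nnCoOccurrence <- function(table, markerA = "Cell 1 Assignment",
                           markerB = "Cell 2 Assignment", r = 0.1) {
  stopifnot(all(c("x", "y", markerA, markerB) %in% names(table)))
  a <- which(table[[markerA]] == 1L)
  b <- which(table[[markerB]] == 1L)
  if (!length(a) || !length(b)) return(NA_real_)
  d2 <- outer(table$x[a], table$x[b], "-")^2 +
    outer(table$y[a], table$y[b], "-")^2
  mean(apply(d2 <= r^2, 1L, any))
}
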