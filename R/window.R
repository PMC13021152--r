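#' Construct a rectangular simulation window
#'
#' @param xrange,yrange numeric(2), strictly increasing coordinate bounds.
#'   The default is the 2 x 2 unit window centred at the origin.
#'
#' @return a [SimWindow-class].
#' @examples
#' w <- simWindow(c(-1, 1), c(-1, 1))
#' windowArea(w)
#' @export
simWindow <- function(xrange = c(-1, 1), yrange = c(-1, 1)) {
  new("SimWindow", xrange = as.numeric(xrange), yrange = as.numeric(yrange))
}

#' @rdname SimWindow-class
#' @export
setMethod("xrange", "SimWindow", function(x) x@xrange)

#' @rdname SimWindow-class
#' @export
setMethod("yrange", "SimWindow", function(x) x@yrange)

#' @rdname SimWindow-class
#' @export
setMethod("windowArea", "SimWindow",
          function(x) diff(x@xrange) * diff(x@yrange))

setMethod("show", "SimWindow", function(object) {
  cat(sprintf("SimWindow [%g, %g] x [%g, %g] (area %g)\n",
              object@xrange[1], object@xrange[2],
              object@yrange[1], object@yrange[2], windowArea(object)))
})

# TRUE for points inside the window, bounds inclusive
.inWindow <- function(window, x, y) {
  x >= window@xrange[1] & x <= window@xrange[2] &
    y >= window@yrange[1] & y <= window@yrange[2]
}
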