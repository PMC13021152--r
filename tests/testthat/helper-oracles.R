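# Independent brute-force implementations of the spatial summary functions,
# written as literal double loops over ordered pairs. They share no code
# with the package's estimators and serve as oracles on small fixtures.

naiveRipleysK <- function(x, y, radii, win) {
  n <- length(x)
  xr <- xrange(win); yr <- yrange(win)
  Wx <- diff(xr); Wy <- diff(yr); A <- Wx * Wy
  vapply(radii, function(r) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(x[i] - x[j]); dy <- abs(y[i] - y[j])
      if (sqrt(dx^2 + dy^2) <= r) s <- s + A / ((Wx - dx) * (Wy - dy))
    }
    A / (n * (n - 1)) * s
  }, numeric(1))
}

naiveNearestNeighbourG <- function(x, y, radii, win) {
  n <- length(x)
  xr <- xrange(win); yr <- yrange(win)
  nnd <- vapply(seq_len(n), function(i)
    min(sqrt((x[i] - x[-i])^2 + (y[i] - y[-i])^2)), numeric(1))
  bdist <- pmin(x - xr[1], xr[2] - x, y - yr[1], yr[2] - y)
  vapply(radii, function(r) {
    keep <- bdist > r
    if (!any(keep)) NA_real_ else mean(nnd[keep] <= r)
  }, numeric(1))
}

naivePairCorrelation <- function(x, y, radii, win, bw) {
  n <- length(x)
  xr <- xrange(win); yr <- yrange(win)
  Wx <- diff(xr); Wy <- diff(yr); A <- Wx * Wy
  vapply(radii, function(r) {
    if (r <= 0) return(NA_real_)
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(x[i] - x[j]); dy <- abs(y[i] - y[j])
      u <- r - sqrt(dx^2 + dy^2)
      if (abs(u) < bw)
        s <- s + A / ((Wx - dx) * (Wy - dy)) * 0.75 / bw * (1 - (u / bw)^2)
    }
    A / (n * (n - 1)) * s / (2 * pi * r)
  }, numeric(1))
}

# a reproducible CSR pattern in a window, independent of the package's RNG
# machinery
csrPattern <- function(n, win, seed) {
  set.seed(seed)
  xr <- xrange(win); yr <- yrange(win)
  list(x = runif(n, xr[1], xr[2]), y = runif(n, yr[1], yr[2]))
}

# one simulated sample with positivity, as a quick fixture
quickTable <- function(seed = 11, lambda = 150, nSims = 1, k = 3, ...) {
  sim <- spatialSimulation(nSims, seed = seed)
  sim <- generatePointPattern(sim, lambda)
  sim <- generateCellPositivity(sim, k = k, ...)
  cellTables(sim)
}
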