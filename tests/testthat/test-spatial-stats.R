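w11 <- simWindow(c(-1, 1), c(-1, 1))
wu <- simWindow(c(0, 1), c(0, 1))

test_that("estimators match the brute-force oracles on 20-point patterns", {
  for (seed in c(101, 202)) {
    pat <- csrPattern(20, w11, seed)
    radii <- seq(0.05, 0.5, by = 0.05)
    bw <- 0.15 / sqrt(20 / 4)
    expect_equal(ripleysK(pat$x, pat$y, radii, w11)$est,
                 naiveRipleysK(pat$x, pat$y, radii, w11), tolerance = 1e-12)
    expect_equal(nearestNeighbourG(pat$x, pat$y, radii, w11)$est,
                 naiveNearestNeighbourG(pat$x, pat$y, radii, w11),
                 tolerance = 1e-12)
    expect_equal(pairCorrelation(pat$x, pat$y, radii, w11, bandwidth = bw)$est,
                 naivePairCorrelation(pat$x, pat$y, radii, w11, bw),
                 tolerance = 1e-12)
  }
})

test_that("Ripley's K handles edge cases and the 3-point fixture", {
  # hand-placed three points in the unit window against the oracle
  x <- c(0.1, 0.2, 0.9); y <- c(0.5, 0.5, 0.5)
  expect_equal(ripleysK(x, y, 0.15, wu)$est,
               naiveRipleysK(x, y, 0.15, wu), tolerance = 1e-12)
  # only the (0.1, 0.2) pair is within 0.15: check the explicit formula
  manual <- 1 / (3 * 2) * 2 * (1 / ((1 - 0.1) * 1))
  expect_equal(ripleysK(x, y, 0.15, wu)$est, manual, tolerance = 1e-12)

  expect_identical(ripleysK(x, y, c(0, 0.05), wu)$est[1], 0)
  expect_warning(k1 <- ripleysK(0.5, 0.5, 0.1, wu), "fewer than 2")
  expect_true(all(is.na(k1$est)))
  expect_error(ripleysK(x, y, c(0.1, 0.6), wu), "half the shorter")
  expect_error(ripleysK(x, y, c(0.2, 0.1), wu), "increasing")
})

test_that("nearest-neighbour G is a border-corrected CDF", {
  # two points 0.1 apart, far from every boundary
  g <- nearestNeighbourG(c(0.5, 0.5), c(0.45, 0.55), c(0.05, 0.2), wu)
  expect_identical(g$est, c(0, 1))
  expect_identical(nearestNeighbourG(c(0.5, 0.6), c(0.5, 0.5), 0, wu)$est, 0)
  # radii beyond every interior point give NA
  gna <- nearestNeighbourG(c(0.5, 0.6), c(0.45, 0.45), c(0.1, 0.45), wu)
  expect_true(is.na(gna$est[2]))
  # CSR reference uses the empirical intensity
  expect_equal(g$theo, 1 - exp(-(2 / 1) * pi * c(0.05, 0.2)^2),
               tolerance = 1e-12)
})

test_that("pair correlation is near 1 under CSR and large in a tight cluster", {
  set.seed(5150)
  est <- replicate(50, {
    p <- list(x = runif(400, -1, 1), y = runif(400, -1, 1))
    pairCorrelation(p$x, p$y, c(0.1, 0.2), w11)$est
  })
  m <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_lt(abs(m[1] - 1), 3 * se[1])
  expect_lt(abs(m[2] - 1), 3 * se[2])

  # all points in one blob of sd 0.05: strong excess at r = 0.05
  set.seed(61)
  bx <- rnorm(150, 0, 0.05); by <- rnorm(150, 0, 0.05)
  keep <- abs(bx) < 1 & abs(by) < 1
  expect_gt(pairCorrelation(bx[keep], by[keep], 0.05, w11)$est, 1)

  # r = 0 is undefined
  expect_true(is.na(pairCorrelation(bx[keep], by[keep], c(0, 0.1), w11)$est[1]))
})

test_that("numerical derivative of K agrees with g on CSR averages", {
  set.seed(99)
  radii <- seq(0.05, 0.3, by = 0.01)
  nrep <- 60
  kms <- matrix(0, length(radii), nrep)
  gms <- matrix(0, length(radii), nrep)
  for (i in seq_len(nrep)) {
    p <- list(x = runif(500, -1, 1), y = runif(500, -1, 1))
    kms[, i] <- ripleysK(p$x, p$y, radii, w11)$est
    gms[, i] <- pairCorrelation(p$x, p$y, radii, w11)$est
  }
  kbar <- rowMeans(kms); gbar <- rowMeans(gms)
  mid <- 2:(length(radii) - 1)
  dK <- (kbar[mid + 1] - kbar[mid - 1]) / (2 * 0.01)
  gFromK <- dK / (2 * pi * radii[mid])
  relerr <- abs(gFromK - gbar[mid]) / gbar[mid]
  expect_lt(max(relerr), 0.15)
})

test_that("translation weights are >= 1 and estimators translate invariantly", {
  pat <- csrPattern(30, wu, 7)
  radii <- seq(0.05, 0.25, by = 0.05)
  shifted <- simWindow(c(10, 11), c(-5, -4))
  for (f in list(ripleysK, nearestNeighbourG, pairCorrelation)) {
    a <- f(pat$x, pat$y, radii, wu)$est
    b <- f(pat$x + 10, pat$y - 5, radii, shifted)$est
    expect_equal(a, b, tolerance = 1e-12)
  }
  # a two-point pattern isolates one translation weight w = |W|/overlap > 1:
  # K(r) = |W|/(n(n-1)) * 2w = w here
  x <- c(0.3, 0.7); y <- c(0.3, 0.3)
  w <- 1 / ((1 - 0.4) * 1)
  expect_equal(ripleysK(x, y, 0.45, wu)$est[1], w, tolerance = 1e-12)
  expect_gt(w, 1)
})

test_that("permutation test follows the add-one p-value formula", {
  # strongly clustered positives: observed K exceeds every permutation
  set.seed(314)
  n <- 200
  x <- runif(n, -1, 1); y <- runif(n, -1, 1)
  x[1:10] <- rnorm(10, 0, 0.01); y[1:10] <- rnorm(10, 0, 0.01)
  tab <- data.frame(Sample = 1, x = x, y = y,
                    `Cell 1 Assignment` = rep(c(1L, 0L), c(10, n - 10)),
                    check.names = FALSE)
  pr <- permutationTest(tab, stats = "K", radii = c(0.05, 0.1), nPerm = 100)
  expect_equal(unname(pr@pValue[1, "K"]), 1 / 101, tolerance = 1e-12)
  expect_true(all(isSignificant(pr)[, "K"]))
  expect_identical(pr@nPositive, 10L)

  # constant marker: every permutation reproduces the observed set exactly
  tab$`Cell 1 Assignment` <- 1L
  prc <- permutationTest(tab, stats = c("K", "g"), radii = c(0.1, 0.2),
                         nPerm = 25)
  expect_true(all(prc@degree == 0))
  expect_true(all(prc@pValue == 1))
})

test_that("permutations conserve the positive count and fail below 2", {
  tabs <- quickTable(seed = 12, lambda = 150)
  tab <- tabs[[1]]
  set.seed(4)
  pr <- permutationTest(tab, radii = seq(0.01, 0.5, by = 0.01), nPerm = 10)
  expect_identical(dim(pr@pValue), c(50L, 3L))
  expect_true(all(pr@pValue > 0 & pr@pValue <= 1, na.rm = TRUE))
  expect_equal(pr@degree, pr@observed - pr@nullMean)

  few <- tab[, ]
  few$`Cell 1 Assignment` <- 0L
  few$`Cell 1 Assignment`[1] <- 1L
  expect_warning(bad <- permutationTest(few, nPerm = 5), "not evaluable")
  expect_false(bad@evaluable)
  expect_true(all(is.na(bad@pValue)))
})

test_that("significance is calibrated under constant-probability labels", {
  # under a flat surface the labels are CSR-thinned: the one-sided test at
  # alpha = 0.05 with 100 permutations rejects with probability 5/101
  sim <- spatialSimulation(100, seed = 808)
  sim <- generatePointPattern(sim, 250)
  sim <- generateCellPositivity(sim, k = 0, probs = c(0.2, 0.2))
  tabs <- cellTables(sim)
  set.seed(909)
  hits <- vapply(tabs, function(tb) {
    pr <- permutationTest(tb, stats = "K", radii = 0.1, nPerm = 100)
    isSignificant(pr)[1, 1]
  }, logical(1))
  expect_gte(sum(hits), qbinom(0.005, 100, 5 / 101))
  expect_lte(sum(hits), qbinom(0.995, 100, 5 / 101))
})
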