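w11 <- simWindow(c(-1, 1), c(-1, 1))

test_that("sampled kernels respect bandwidth bounds and the window", {
  set.seed(31)
  ks <- sampleKernels(5, w11, 0.1, 0.3, c(0.01, 0.75))
  expect_identical(nKernels(ks), 5L)
  expect_true(all(kernelSds(ks) >= 0.1 & kernelSds(ks) <= 0.3))
  ctr <- kernelCenters(ks)
  expect_true(all(ctr[, 1] >= -1 & ctr[, 1] <= 1))
  expect_true(all(ctr[, 2] >= -1 & ctr[, 2] <= 1))

  # degenerate uniform: sd exactly the common bound
  ks1 <- sampleKernels(1, w11, 0.2, 0.2, c(0, 1))
  expect_identical(kernelSds(ks1), 0.2)

  expect_error(sampleKernels(2, w11, 0.3, 0.1, c(0, 1)), "sdmin")
  expect_error(sampleKernels(2, w11, 0.1, 0.3, c(0.5, 0.2)), "probs")
  expect_error(sampleKernels(2, w11, 0.1, 0.3, c(0.2, 1.5)), "probs")
})

test_that("surface evaluation follows the max-then-rescale formula", {
  ks <- new("KernelSet", centers = cbind(x = 0, y = 0), sds = 0.2,
            probRange = c(0.01, 0.75))
  # peak attains prob_max exactly at the centre
  expect_identical(evaluateSurface(ks, 0, 0), 0.75)
  # one bandwidth away: hand evaluation of the formula
  expect_equal(evaluateSurface(ks, 0.2, 0), 0.01 + 0.74 * exp(-0.5),
               tolerance = 1e-12)
  # ten bandwidths away the surface is at prob_min
  ks01 <- new("KernelSet", centers = cbind(x = 0, y = 0), sds = 0.1,
              probRange = c(0.01, 0.75))
  expect_equal(evaluateSurface(ks01, 1, 0), 0.01, tolerance = 1e-6)
  # no kernels: constant at prob_min
  ks0 <- new("KernelSet", probRange = c(0.3, 0.8))
  expect_identical(evaluateSurface(ks0, c(-1, 0, 1), c(0, 0, 0)),
                   c(0.3, 0.3, 0.3))
})

test_that("duplicating a kernel leaves the max-combined surface unchanged", {
  set.seed(8)
  ks <- sampleKernels(3, w11, 0.1, 0.3, c(0.05, 0.9))
  dup <- new("KernelSet", centers = kernelCenters(ks)[c(1:3, 2), ],
             sds = kernelSds(ks)[c(1:3, 2)], probRange = probRange(ks))
  px <- runif(200, -1, 1); py <- runif(200, -1, 1)
  expect_identical(evaluateSurface(ks, px, py), evaluateSurface(dup, px, py))
})

test_that("probability scaling is affine and order preserving", {
  set.seed(9)
  ks <- sampleKernels(4, w11, 0.1, 0.4, c(0.1, 0.6))
  raw <- new("KernelSet", centers = kernelCenters(ks), sds = kernelSds(ks),
             probRange = c(0, 1))
  px <- runif(300, -1, 1); py <- runif(300, -1, 1)
  s <- evaluateSurface(raw, px, py)
  p <- evaluateSurface(ks, px, py)
  expect_identical(order(s), order(p))
  expect_true(all(p >= 0.1 & p <= 0.6))
  expect_equal(p, 0.1 + 0.5 * s, tolerance = 1e-12)
})

test_that("kernel shifting displaces by shift * half-width then wraps", {
  ks <- new("KernelSet", centers = cbind(x = c(0, 0.2), y = c(0, -0.1)),
            sds = c(0.15, 0.25), probRange = c(0.01, 0.75))
  expect_identical(shiftKernels(ks, 0, w11), ks)

  set.seed(77)
  shifted <- shiftKernels(ks, 0.5, w11)
  # displacement magnitude is 0.5 * (2/2) = 0.5 (no wrap for these centres)
  d <- sqrt(rowSums((kernelCenters(shifted) - kernelCenters(ks))^2))
  expect_equal(d, c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(kernelSds(shifted), kernelSds(ks))
  expect_identical(probRange(shifted), probRange(ks))

  # wrapped centres stay inside the window
  set.seed(78)
  edge <- new("KernelSet", centers = cbind(x = 0.99, y = 0.99), sds = 0.1,
              probRange = c(0, 1))
  for (i in 1:20) {
    ctr <- kernelCenters(shiftKernels(edge, 1, w11))
    expect_true(all(ctr >= -1 & ctr <= 1))
  }

  expect_error(shiftKernels(ks, 1.5, w11), "shift")
  expect_error(shiftKernels(ks, -0.1, w11), "shift")
})

test_that("density grid matches point evaluation and its range contract", {
  # zero kernels: constant surface at prob_min
  ks0 <- new("KernelSet", probRange = c(0.3, 0.8))
  g0 <- densityGrid(ks0, w11, 7)
  expect_identical(nrow(g0), 49L)
  expect_true(all(g0$probability == 0.3))

  set.seed(12)
  ks <- sampleKernels(3, w11, 0.1, 0.3, c(0.01, 0.75))
  g <- densityGrid(ks, w11, 100)
  expect_identical(nrow(g), 10000L)
  expect_true(all(g$probability >= 0.01 & g$probability <= 0.75))
  expect_identical(g$probability, evaluateSurface(ks, g$x, g$y))

  # a kernel centred exactly on a grid node attains prob_max there
  wu <- simWindow(c(0, 1), c(0, 1))
  ksn <- new("KernelSet", centers = cbind(x = 0.55, y = 0.35), sds = 0.1,
             probRange = c(0.01, 0.75))
  gn <- densityGrid(ksn, wu, 10)
  expect_identical(max(gn$probability), 0.75)
  expect_identical(gn$probability[gn$x == 0.55 & gn$y == 0.35], 0.75)
})

test_that("density grids round-trip through CSV", {
  set.seed(4)
  ks <- sampleKernels(2, w11, 0.1, 0.2, c(0.1, 0.9))
  g <- densityGrid(ks, w11, 12)
  f <- tempfile(fileext = ".csv")
  writeDensityGrid(g, f)
  back <- read.csv(f)
  expect_equal(back$probability, g$probability, tolerance = 1e-9)
  unlink(f)
})
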