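baseSim <- function(nSims = 2, lambda = 150, seed = 21, nCellTypes = 1) {
  generatePointPattern(
    spatialSimulation(nSims, seed = seed, nCellTypes = nCellTypes), lambda)
}

test_that("tissue assignment follows the surface probabilities", {
  sim <- baseSim()
  expect_error(generateTissue(spatialSimulation(2)), "patterns")

  all1 <- generateTissue(sim, probs = c(1, 1))
  expect_true(all(unlist(all1@tissue) == "Tissue 1"))
  all2 <- generateTissue(sim, probs = c(0, 0))
  expect_true(all(unlist(all2@tissue) == "Tissue 2"))

  mid <- generateTissue(sim, probs = c(0.2, 0.8))
  frac <- mean(unlist(mid@tissue) == "Tissue 1")
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.9)
  expect_true(all(lengths(mid@tissue) ==
                    vapply(pointPatterns(sim), nrow, integer(1))))
})

test_that("hole flags are Bernoulli draws and drop is only an export flag", {
  sim <- baseSim()
  none <- generateHoles(sim, probs = c(0, 0))
  expect_false(any(unlist(none@holes)))
  all <- generateHoles(sim, probs = c(1, 1), drop = TRUE)
  expect_true(base::all(unlist(all@holes)))
  expect_true(base::all(vapply(cellTables(all), nrow, integer(1)) == 0L))
  # flagged cells are retained in the object either way
  expect_identical(unname(lengths(all@holes)),
                   vapply(pointPatterns(sim), nrow, integer(1)))
  # conservation: exported rows = total - flagged when dropping
  some <- generateHoles(sim, probs = c(0.2, 0.4), drop = TRUE)
  kept <- unname(vapply(cellTables(some), nrow, integer(1)))
  total <- vapply(pointPatterns(sim), nrow, integer(1))
  flagged <- vapply(some@holes, sum, integer(1))
  expect_identical(kept, total - flagged)
})

test_that("constant-surface positivity recovers the Bernoulli rate", {
  sim <- baseSim(nSims = 10, lambda = 250, seed = 33)
  p <- 0.3
  sim <- generateCellPositivity(sim, k = 0, probs = c(p, p))
  pos <- unlist(lapply(sim@positivity, function(m) m[, 1]))
  n <- length(pos)
  expect_gt(n, 5000)
  expect_lt(abs(mean(pos) - p), 3 * sqrt(p * (1 - p) / n))
  # every cell has exactly one indicator per type
  expect_true(all(pos %in% c(0L, 1L)))
})

test_that("per-sample positive fraction stays inside the prob bounds", {
  sim <- baseSim(nSims = 5, lambda = 250, seed = 14)
  sim <- generateCellPositivity(sim, k = 5, sdmin = 0.1, sdmax = 0.3,
                                probs = c(0.01, 0.75))
  fracs <- vapply(sim@positivity, function(m) mean(m[, 1]), numeric(1))
  expect_true(all(fracs > 0.01 & fracs < 0.75))
})

test_that("shared surfaces (shift = 0) induce positively correlated types", {
  sim <- baseSim(nSims = 10, lambda = 250, seed = 55, nCellTypes = 2)
  sim <- generateCellPositivity(sim, k = 5, sdmin = 0.1, sdmax = 0.3,
                                probs = c(0.01, 0.75), shift = 0)
  pos <- do.call(rbind, sim@positivity)
  expect_gt(cor(pos[, 1], pos[, 2]), 0)
  # both types literally share one kernel set
  expect_identical(sim@cellKernels[[1]][[1]], sim@cellKernels[[1]][[2]])
})

test_that("shift with a single cell type warns and is ignored", {
  sim <- baseSim(nSims = 1)
  expect_warning(generateCellPositivity(sim, shift = 0.5), "single cell type")
})

test_that("raising prob_max never removes a positive cell (same seed)", {
  lo <- generateCellPositivity(baseSim(seed = 60), k = 4, probs = c(0.01, 0.3))
  hi <- generateCellPositivity(baseSim(seed = 60), k = 4, probs = c(0.01, 0.75))
  for (i in 1:2)
    expect_true(all(hi@positivity[[i]][lo@positivity[[i]] == 1L] == 1L))
})

test_that("stage draws are independent given constant surfaces", {
  sim <- baseSim(nSims = 10, lambda = 250, seed = 71)
  sim <- generateTissue(sim, probs = c(0.5, 0.5))
  sim <- generateHoles(sim, probs = c(0.5, 0.5))
  sim <- generateCellPositivity(sim, k = 0, probs = c(0.5, 0.5))
  tiss <- as.integer(unlist(sim@tissue) == "Tissue 1")
  hole <- as.integer(unlist(sim@holes))
  pos <- unlist(lapply(sim@positivity, function(m) m[, 1]))
  n <- length(tiss)
  expect_lt(abs(cor(tiss, hole)), 5 / sqrt(n))
  expect_lt(abs(cor(tiss, pos)), 5 / sqrt(n))
  expect_lt(abs(cor(hole, pos)), 5 / sqrt(n))
})

test_that("continuous marker values follow the positivity-conditional model", {
  sim <- baseSim(nSims = 4, lambda = 250, seed = 81)
  expect_error(generateMarkerValues(sim, markerDistribution(10, 1, 5, 1)),
               "positivity")
  sim <- generateCellPositivity(sim, k = 3)
  expect_error(markerDistribution(10, -1, 5, 1), "non-negative")

  # zero-sd point masses
  pm <- generateMarkerValues(sim, markerDistribution(10, 0, 5, 0))
  for (i in seq_len(4)) {
    v <- pm@markerValues[[i]][, 1]
    pos <- pm@positivity[[i]][, 1] == 1L
    expect_true(all(v[pos] == 10))
    expect_true(all(v[!pos] == 5))
  }

  # group means separate by the specified effect
  mv <- generateMarkerValues(sim, markerDistribution(10, 1, 5, 1),
                             overwrite = TRUE)
  v <- unlist(lapply(mv@markerValues, function(m) m[, 1]))
  pos <- unlist(lapply(mv@positivity, function(m) m[, 1])) == 1L
  expect_lt(abs(mean(v[pos]) - 10), 3 / sqrt(sum(pos)))
  expect_lt(abs(mean(v[!pos]) - 5), 3 / sqrt(sum(!pos)))
  expect_lt(abs((mean(v[pos]) - mean(v[!pos])) - 5), 0.2)
})

test_that("all-positive samples give marker mean near the positive mean", {
  sim <- baseSim(nSims = 1, lambda = 2500, seed = 91)
  sim <- generateCellPositivity(sim, k = 0, probs = c(1, 1))
  sim <- generateMarkerValues(sim, markerDistribution(10, 1, 0, 1))
  v <- sim@markerValues[[1]][, 1]
  expect_gt(length(v), 5000)
  expect_lt(abs(mean(v) - 10), 3 / sqrt(length(v)))
})
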