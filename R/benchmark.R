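# Benchmarking scenarios: four canonical parameterisations crossing cluster
# size (kernel bandwidth range) with phenotype abundance (probability
# range), all at intensity 250 and 5 clusters in the 2 x 2 window:
#   1: tight clusters (sd 0.1-0.3), high abundance (0.01-0.75)
#   2: dispersed clusters (sd 0.2-0.4), high abundance (0.01-0.75)
#   3: tight clusters (sd 0.1-0.3), low abundance (0.01-0.2)
#   4: dispersed clusters (sd 0.2-0.4), low abundance (0.01-0.2)

.SCENARIOS <- list(
  `1` = list(sdRange = c(0.1, 0.3), probRange = c(0.01, 0.75)),
  `2` = list(sdRange = c(0.2, 0.4), probRange = c(0.01, 0.75)),
  `3` = list(sdRange = c(0.1, 0.3), probRange = c(0.01, 0.2)),
  `4` = list(sdRange = c(0.2, 0.4), probRange = c(0.01, 0.2))
)

#' Configure a benchmarking scenario
#'
#' Builds the full parameter set of one simulate-then-test run. `scenario`
#' 1--4 selects a canonical combination of cluster size and phenotype
#' abundance (see the table in the package vignette); any field can be
#' overridden. The tissue and hole stages run with their module defaults
#' (tissue: 2 kernels, sd 0.4--0.6, probs 0.2--0.8; holes: 1 kernel,
#' sd 0.1--0.2, probs 0.1--0.3), overridable through `tissueParams` /
#' `holeParams`.
#'
#' @param scenario integer 1--4 selecting the canonical parameterisation.
#' @param nSims number of simulated samples.
#' @param nPerm label permutations per sample.
#' @param seed master seed of the run.
#' @param lambda point intensity per unit area.
#' @param k number of phenotype kernels.
#' @param sdRange,probRange overrides of the scenario's bandwidth and
#'   abundance bounds.
#' @param window simulation window.
#' @param radii radius grid of the summary functions.
#' @param alpha significance level.
#' @param tissueParams,holeParams named lists of overrides for the tissue
#'   and hole stages (`k`, `sdmin`, `sdmax`, `probs`).
#'
#' @return a [ScenarioConfig-class].
#' @examples
#' scenarioConfig(1, nSims = 2, nPerm = 5, seed = 1)
#' @export
scenarioConfig <- function(scenario = 1L, nSims = 100L, nPerm = 100L,
                           seed = 1L, lambda = 250, k = 5L,
                           sdRange = NULL, probRange = NULL,
                           window = simWindow(),
                           radii = seq(0.01, 0.5, by = 0.01),
                           alpha = 0.05,
                           tissueParams = list(), holeParams = list()) {
  key <- as.character(scenario)
  if (!key %in% names(.SCENARIOS))
    stop("scenario must be 1, 2, 3 or 4", call. = FALSE)
  base <- .SCENARIOS[[key]]
  new("ScenarioConfig",
      name = paste("Scenario", key),
      lambda = as.numeric(lambda), k = as.integer(k),
      sdRange = as.numeric(if (is.null(sdRange)) base$sdRange else sdRange),
      probRange = as.numeric(if (is.null(probRange)) base$probRange
                             else probRange),
      nSims = .checkCount(nSims, "nSims"), nPerm = .checkCount(nPerm, "nPerm"),
      window = window, radii = as.numeric(radii), alpha = as.numeric(alpha),
      seed = as.integer(seed),
      tissueParams = utils::modifyList(
        list(k = 2L, sdmin = 0.4, sdmax = 0.6, probs = c(0.2, 0.8)),
        tissueParams),
      holeParams = utils::modifyList(
        list(k = 1L, sdmin = 0.1, sdmax = 0.2, probs = c(0.1, 0.3)),
        holeParams))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(paste0("%s: lambda = %g, k = %d, sd [%g, %g], ",
                     "probs [%g, %g]\n  %d samples x %d permutations, ",
                     "%d radii, alpha = %g, seed = %d\n"),
              object@name, object@lambda, object@k,
              object@sdRange[1], object@sdRange[2],
              object@probRange[1], object@probRange[2],
              object@nSims, object@nPerm, length(object@radii),
              object@alpha, object@seed))
})

#' @describeIn runScenario simulates `nSims` samples (point pattern, holes
#'   and tissue with their defaults, phenotype positivity with the scenario
#'   parameters), then runs the label-permutation test for Ripley's K,
#'   nearest-neighbour G and pair correlation g on every sample. Samples
#'   with fewer than 2 positive cells are excluded and recorded. Fully
#'   deterministic given the config seed.
#' @param verbose print per-sample progress.
#' @return a [ScenarioResult-class].
#' @export
setMethod("runScenario", "ScenarioConfig",
  function(x, verbose = FALSE) {
    validObject(x)
    sim <- spatialSimulation(nSims = x@nSims, window = x@window,
                             nCellTypes = 1L, seed = x@seed)
    sim <- generatePointPattern(sim, lambda = x@lambda)
    hp <- x@holeParams
    sim <- generateHoles(sim, k = hp$k, sdmin = hp$sdmin, sdmax = hp$sdmax,
                         probs = hp$probs)
    tp <- x@tissueParams
    sim <- generateTissue(sim, k = tp$k, sdmin = tp$sdmin, sdmax = tp$sdmax,
                          probs = tp$probs)
    sim <- generateCellPositivity(sim, k = x@k, sdmin = x@sdRange[1],
                                  sdmax = x@sdRange[2], probs = x@probRange)
    tables <- cellTables(sim)
    statNames <- c("K", "G", "g")
    nr <- length(x@radii)
    sig <- array(FALSE, c(x@nSims, nr, 3L),
                 dimnames = list(NULL, NULL, statNames))
    evalable <- array(FALSE, c(x@nSims, nr, 3L),
                      dimnames = list(NULL, NULL, statNames))
    excluded <- integer()
    for (i in seq_len(x@nSims)) {
      tb <- tables[[i]]
      if (sum(tb[["Cell 1 Assignment"]] == 1L) < 2L) {
        excluded <- c(excluded, i)
        next
      }
      pr <- .withSeed(.substreamSeed(x@seed, i, .STAGE[["permutation"]]),
        permutationTest(tb, marker = "Cell 1 Assignment", stats = statNames,
                        radii = x@radii, nPerm = x@nPerm, alpha = x@alpha,
                        window = x@window))
      ok <- !is.na(pr@pValue)
      evalable[i, , ] <- ok
      sig[i, , ][ok] <- pr@pValue[ok] < x@alpha
      if (verbose && i %% 10L == 0L)
        message(x@name, ": sample ", i, "/", x@nSims)
    }
    if (length(excluded))
      message(x@name, ": ", length(excluded),
              " sample(s) excluded (fewer than 2 positive cells)")
    new("ScenarioResult", config = x, significant = sig,
        evaluable = evalable, excluded = excluded, statNames = statNames)
  })

setMethod("show", "ScenarioResult", function(object) {
  cat("ScenarioResult for", object@config@name, "\n")
  print(summariseBenchmark(object))
})

#' @describeIn summariseBenchmark per scenario and statistic, counts over
#'   the radius grid: `most_significant` = radii where that statistic found
#'   significant clustering in strictly the most samples (ties credit no
#'   statistic); `all_significant` = radii where every evaluable sample was
#'   significant (requiring at least one evaluable sample).
#' @return data.frame with columns `scenario`, `statistic`,
#'   `most_significant`, `all_significant`.
#' @export
setMethod("summariseBenchmark", "ScenarioResult",
  function(x, ...) {
    nr <- dim(x@significant)[2L]
    nstat <- length(x@statNames)
    counts <- matrix(0L, nr, nstat, dimnames = list(NULL, x@statNames))
    evalN <- counts
    slab <- function(a, s)  # samples x radii slice, dims kept
      matrix(a[, , s], nrow = dim(a)[1L], ncol = dim(a)[2L])
    for (s in seq_len(nstat)) {
      counts[, s] <- colSums(slab(x@significant, s) & slab(x@evaluable, s))
      evalN[, s] <- colSums(slab(x@evaluable, s))
    }
    most <- integer(nstat)
    for (t in seq_len(nr)) {
      mx <- max(counts[t, ])
      winner <- which(counts[t, ] == mx)
      if (length(winner) == 1L && mx > 0L)
        most[winner] <- most[winner] + 1L
    }
    allSig <- vapply(seq_len(nstat), function(s)
      sum(evalN[, s] > 0L & counts[, s] == evalN[, s]), integer(1))
    data.frame(scenario = x@config@name, statistic = x@statNames,
               most_significant = most, all_significant = allSig,
               row.names = NULL)
  })

#' @describeIn summariseBenchmark row-binds the summaries of several runs.
#' @export
setMethod("summariseBenchmark", "list",
  function(x, ...) {
    if (!length(x)) stop("no results to summarise", call. = FALSE)
    do.call(rbind, lapply(x, summariseBenchmark))
  })
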