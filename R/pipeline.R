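#' Run a whole simulation pipeline from a configuration
#'
#' Executes the stages of a simulation in their fixed order -- point
#' pattern, tissue, holes, cell positivity, marker distributions, export,
#' permutation statistics -- from a single declarative configuration (a
#' YAML or JSON file, or an equivalent named list). Only the stages whose
#' sections are present are run; a `stats` section with an `input` directory
#' runs the statistics on previously exported tables without re-simulating.
#' Every numeric field is validated before any computation starts and all
#' problems are reported together. A `manifest.json` recording the package
#' version, seed and parameters is written next to the outputs; it contains
#' no timestamps, so identical configurations yield byte-identical output
#' trees.
#'
#' Configuration sections (all optional unless noted):
#' \describe{
#'   \item{seed}{master seed (required with `core`).}
#'   \item{output}{output directory (required).}
#'   \item{core}{`n_sims`, `n_cell_types`, `lambda`, `window`
#'     (`xmin`/`xmax`/`ymin`/`ymax`).}
#'   \item{tissue, holes, cells}{`k`, `sdmin`, `sdmax`, `prob_min`,
#'     `prob_max`; `holes` also takes `drop`, `cells` also takes `shift`.}
#'   \item{distributions}{list of `mean_pos`/`sd_pos`/`mean_neg`/`sd_neg`
#'     entries, one per cell type.}
#'   \item{export}{`dialect` ("simple"/"halo-like"), `drop_holes`.}
#'   \item{stats}{`marker`, `stats` (subset of K/G/g), `radii`
#'     (`from`/`to`/`by`), `n_perm`, `alpha`; or `input` directory for a
#'     stats-only run.}
#' }
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @param quiet suppress progress messages.
#'
#' @return invisibly, a list with the simulation object (if any), the paths
#'   written, and the summary/statistics data.frames produced.
#' @examples
#' cfg <- list(seed = 7, output = tempfile("run"),
#'             core = list(n_sims = 2, lambda = 60),
#'             cells = list(k = 3, sdmin = 0.1, sdmax = 0.3,
#'                          prob_min = 0.01, prob_max = 0.75),
#'             export = list(dialect = "simple"))
#' res <- runPipeline(cfg, quiet = TRUE)
#' list.files(res$output)
#' @export
runPipeline <- function(config, quiet = FALSE) {
  cfg <- .loadConfig(config)
  .validatePipelineConfig(cfg)
  out <- cfg$output
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("cannot create output directory: ", out, call. = FALSE)
  say <- function(...) if (!quiet) message(...)
  result <- list(output = out, files = character())
  tables <- NULL
  sim <- NULL

  if (!is.null(cfg$core)) {
    core <- cfg$core
    w <- if (is.null(core$window)) simWindow() else
      simWindow(c(core$window$xmin, core$window$xmax),
                c(core$window$ymin, core$window$ymax))
    say("simulating ", core$n_sims, " sample(s)")
    sim <- spatialSimulation(nSims = core$n_sims, window = w,
                             nCellTypes = core$n_cell_types %||% 1L,
                             seed = cfg$seed)
    sim <- generatePointPattern(sim, lambda = core$lambda)
    if (!is.null(cfg$tissue))
      sim <- do.call(generateTissue,
                     c(list(sim), .kernelArgs(cfg$tissue)))
    if (!is.null(cfg$holes))
      sim <- do.call(generateHoles,
                     c(list(sim), .kernelArgs(cfg$holes),
                       list(drop = isTRUE(cfg$holes$drop))))
    if (!is.null(cfg$cells))
      sim <- do.call(generateCellPositivity,
                     c(list(sim), .kernelArgs(cfg$cells),
                       list(shift = cfg$cells$shift %||% 0)))
    if (!is.null(cfg$distributions)) {
      specs <- lapply(cfg$distributions, function(d)
        markerDistribution(d$mean_pos, d$sd_pos, d$mean_neg, d$sd_neg))
      sim <- generateMarkerValues(sim, specs)
    }
    tables <- cellTables(sim)
    result$sim <- sim
    if (!is.null(cfg$export)) {
      say("exporting cell tables")
      paths <- writeCellTables(
        tables, file.path(out, "tables"),
        dialect = cfg$export$dialect %||% "simple")
      result$files <- c(result$files, paths)
      if (!is.null(cfg$cells)) {
        summ <- summariseCells(tables)
        sfile <- file.path(out, "sample_summary.csv")
        utils::write.csv(summ, sfile, row.names = FALSE)
        result$summary <- summ
        result$files <- c(result$files, sfile)
      }
    }
  }

  if (!is.null(cfg$stats)) {
    st <- cfg$stats
    if (is.null(tables)) {
      say("reading tables from ", st$input)
      tables <- readCellTables(st$input)
    }
    radii <- if (is.null(st$radii)) seq(0.01, 0.5, by = 0.01) else
      seq(st$radii$from, st$radii$to, by = st$radii$by)
    w <- if (!is.null(sim)) simulationWindow(sim) else
      if (is.null(cfg$core$window)) simWindow() else
        simWindow(c(cfg$core$window$xmin, cfg$core$window$xmax),
                  c(cfg$core$window$ymin, cfg$core$window$ymax))
    marker <- st$marker %||% "Cell 1 Assignment"
    whichStats <- unlist(st$stats) %||% c("K", "G", "g")
    say("permutation statistics (", length(tables), " sample(s))")
    statRows <- lapply(seq_along(tables), function(i) {
      tb <- tables[[i]]
      if (sum(tb[[marker]] == 1L) < 2L) return(NULL)
      pr <- .withSeed(.substreamSeed(cfg$seed, i, .STAGE[["permutation"]]),
        permutationTest(tb, marker = marker, stats = whichStats,
                        radii = radii, nPerm = st$n_perm %||% 100L,
                        alpha = st$alpha %||% 0.05, window = w))
      cbind(sample = if (nrow(tb)) tb$Sample[1L] else i, as.data.frame(pr))
    })
    statDf <- do.call(rbind, statRows)
    sfile <- file.path(out, "permutation_results.csv")
    utils::write.csv(statDf, sfile, row.names = FALSE)
    result$stats <- statDf
    result$files <- c(result$files, sfile)
  }

  manifest <- list(package = "CellPatternSim",
                   version = as.character(utils::packageVersion("CellPatternSim")),
                   seed = cfg$seed, config = .manifestConfig(cfg))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result$files <- c(result$files, file.path(out, "manifest.json"))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.kernelArgs <- function(section) {
  args <- list()
  for (nm in c("k", "sdmin", "sdmax"))
    if (!is.null(section[[nm]])) args[[nm]] <- section[[nm]]
  if (!is.null(section$prob_min) || !is.null(section$prob_max))
    args$probs <- c(section$prob_min, section$prob_max)
  args
}

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    if (grepl("\\.json$", config, ignore.case = TRUE))
      return(jsonlite::read_json(config, simplifyVector = FALSE))
    return(yaml::read_yaml(config))
  }
  if (!is.list(config)) stop("config must be a file path or a named list",
                             call. = FALSE)
  config
}

# All validation up front, every problem reported at once.
.validatePipelineConfig <- function(cfg) {
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(!is.null(cfg$output), "an 'output' directory is required")
  hasCore <- !is.null(cfg$core)
  statsOnly <- !hasCore && !is.null(cfg$stats$input)
  need(hasCore || statsOnly,
       "either a 'core' section or a stats 'input' directory is required")
  if (hasCore || !is.null(cfg$stats))
    need(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
         "a single numeric 'seed' is required")
  if (hasCore) {
    need(is.numeric(cfg$core$n_sims) && cfg$core$n_sims >= 1,
         "core$n_sims must be >= 1")
    need(is.numeric(cfg$core$lambda) && cfg$core$lambda >= 0,
         "core$lambda must be >= 0")
    if (!is.null(cfg$core$window)) {
      wdw <- cfg$core$window
      need(all(c("xmin", "xmax", "ymin", "ymax") %in% names(wdw)),
           "core$window needs xmin, xmax, ymin, ymax")
      if (all(c("xmin", "xmax", "ymin", "ymax") %in% names(wdw)))
        need(wdw$xmax > wdw$xmin && wdw$ymax > wdw$ymin,
             "core$window must have positive extent")
    }
  } else {
    for (sec in c("tissue", "holes", "cells", "distributions", "export"))
      need(is.null(cfg[[sec]]),
           sprintf("'%s' requires a 'core' section (stage order is fixed)",
                   sec))
  }
  for (sec in c("tissue", "holes", "cells")) {
    s <- cfg[[sec]]
    if (is.null(s)) next
    if (!is.null(s$sdmin) || !is.null(s$sdmax))
      need(is.numeric(s$sdmin) && is.numeric(s$sdmax) &&
             s$sdmin > 0 && s$sdmin <= s$sdmax,
           sprintf("%s: need 0 < sdmin <= sdmax", sec))
    if (!is.null(s$prob_min) || !is.null(s$prob_max))
      need(is.numeric(s$prob_min) && is.numeric(s$prob_max) &&
             s$prob_min >= 0 && s$prob_max <= 1 && s$prob_min <= s$prob_max,
           sprintf("%s: probabilities must satisfy 0 <= min <= max <= 1", sec))
  }
  if (!is.null(cfg$cells$shift))
    need(cfg$cells$shift >= 0 && cfg$cells$shift <= 1,
         "cells$shift must be in [0, 1]")
  if (!is.null(cfg$distributions)) {
    need(!is.null(cfg$cells),
         "'distributions' requires a 'cells' section (stage order is fixed)")
    for (d in cfg$distributions)
      need(all(c("mean_pos", "sd_pos", "mean_neg", "sd_neg") %in% names(d)) &&
             d$sd_pos >= 0 && d$sd_neg >= 0,
           "each distribution needs mean_pos, sd_pos, mean_neg, sd_neg (sds >= 0)")
  }
  if (!is.null(cfg$stats$radii)) {
    r <- cfg$stats$radii
    need(all(c("from", "to", "by") %in% names(r)) && r$by > 0 && r$to > r$from,
         "stats$radii needs from < to and by > 0")
  }
  if (!is.null(cfg$stats$alpha))
    need(cfg$stats$alpha > 0 && cfg$stats$alpha < 1,
         "stats$alpha must be in (0, 1)")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

# drop non-scalar clutter so the manifest stays readable
.manifestConfig <- function(cfg) {
  cfg$output <- NULL
  cfg
}
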