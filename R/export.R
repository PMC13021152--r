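#' @describeIn cellTables materialises one data.frame per sample with fixed
#'   column names: `Sample`, `x`, `y`, then `Tissue Assignment`,
#'   `Hole Assignment`, `Cell i Assignment` (0/1) and `Cell i Value` for the
#'   stages that have been run (absent stages yield absent columns). Row
#'   order is generation order.
#' @param dropHoles omit rows flagged as holes (defaults to the `drop` flag
#'   given to [generateHoles()]).
#' @return a list of `nSims` data.frames.
#' @export
setMethod("cellTables", "SpatialSimulation",
  function(x, dropHoles = x@holeDrop) {
    .requirePatterns(x)
    hasTissue <- length(x@tissue) > 0L
    hasHoles <- length(x@holes) > 0L
    hasPos <- length(x@positivity) > 0L
    hasVals <- length(x@markerValues) > 0L
    out <- lapply(seq_len(x@nSims), function(i) {
      pts <- x@patterns[[i]]
      n <- nrow(pts)
      df <- data.frame(Sample = rep.int(i, n), x = pts[, 1L], y = pts[, 2L],
                       check.names = FALSE)
      if (hasTissue) df[["Tissue Assignment"]] <- x@tissue[[i]]
      if (hasHoles) df[["Hole Assignment"]] <- as.integer(x@holes[[i]])
      if (hasPos) {
        for (t in seq_len(x@nCellTypes))
          df[[sprintf("Cell %d Assignment", t)]] <- x@positivity[[i]][, t]
      }
      if (hasVals) {
        for (t in seq_len(x@nCellTypes))
          df[[sprintf("Cell %d Value", t)]] <- x@markerValues[[i]][, t]
      }
      if (dropHoles && hasHoles) {
        df <- df[df[["Hole Assignment"]] == 0L, , drop = FALSE]
        rownames(df) <- NULL
      }
      df
    })
    names(out) <- sprintf("Sample %d", seq_len(x@nSims))
    out
  })

#' Sample-level abundance summary
#'
#' One row per sample: total cell count and, for each requested 0/1 marker
#' column, the positive count and the percent positive
#' (`100 * positives / total`; reported as `NA` for empty samples rather
#' than 0, so empty samples cannot bias scenario averages).
#'
#' @param tables list of per-sample tables from [cellTables()].
#' @param markers character vector of 0/1 columns to summarise, e.g.
#'   `"Cell 1 Assignment"`.
#'
#' @return data.frame with columns `Sample`, `Total Cells`, and per marker
#'   `<marker> Positive` / `<marker> % Positive`.
#' @examples
#' sim <- spatialSimulation(2, seed = 3)
#' sim <- generatePointPattern(sim, lambda = 50)
#' sim <- generateCellPositivity(sim, k = 2)
#' summariseCells(cellTables(sim))
#' @export
summariseCells <- function(tables, markers = "Cell 1 Assignment") {
  stopifnot(is.list(tables), length(tables) >= 1L)
  for (m in markers) {
    ok <- vapply(tables, function(tb) m %in% names(tb), logical(1))
    if (!all(ok))
      stop(sprintf("marker column '%s' is missing from %d table(s)",
                   m, sum(!ok)), call. = FALSE)
  }
  rows <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    id <- if (nrow(tb)) tb[["Sample"]][1L] else i
    row <- data.frame(Sample = id, `Total Cells` = nrow(tb),
                      check.names = FALSE)
    for (m in markers) {
      npos <- sum(tb[[m]] == 1L)
      row[[paste(m, "Positive")]] <- npos
      row[[paste(m, "% Positive")]] <-
        if (nrow(tb) > 0L) 100 * npos / nrow(tb) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-sample cell tables as CSV
#'
#' One CSV per sample (RFC-4180 quoting, UTF-8), named
#' `<prefix>_<sample>.csv`. The `"simple"` dialect writes the table columns
#' verbatim; `"halo-like"` additionally emits `XMin`/`XMax`/`YMin`/`YMax`
#' columns, each equal to the point coordinate (a degenerate bounding box),
#' so tools expecting cell-segmentation bounding boxes in the HALO style can
#' ingest the files. Exact compatibility with any proprietary schema is not
#' attempted.
#'
#' @param tables list of per-sample tables from [cellTables()].
#' @param dir output directory (created if needed).
#' @param dialect `"simple"` or `"halo-like"`.
#' @param prefix file-name prefix.
#'
#' @return character vector of the paths written, invisibly.
#' @seealso [readCellTables()]
#' @export
writeCellTables <- function(tables, dir, dialect = c("simple", "halo-like"),
                            prefix = "sample") {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- character(length(tables))
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    id <- if (nrow(tb)) tb[["Sample"]][1L] else i
    if (dialect == "halo-like") {
      lead <- tb[seq_len(3L)]
      lead[["XMin"]] <- tb$x
      lead[["XMax"]] <- tb$x
      lead[["YMin"]] <- tb$y
      lead[["YMax"]] <- tb$y
      tb <- cbind(lead, tb[-seq_len(3L)])
    }
    paths[i] <- file.path(dir, sprintf("%s_%04d.csv", prefix, id))
    utils::write.csv(tb, paths[i], row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' Read back cell tables written by [writeCellTables()]
#'
#' @param dir directory containing the CSVs.
#' @param prefix file-name prefix used at write time.
#' @return list of data.frames, ordered by file name.
#' @export
readCellTables <- function(dir, prefix = "sample") {
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_\\d+\\.csv$"),
                           full.names = TRUE))
  if (!length(files))
    stop("no cell tables found under ", dir, call. = FALSE)
  lapply(files, function(f)
    utils::read.csv(f, check.names = FALSE, fileEncoding = "UTF-8"))
}
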