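#' Run the full simulate-render-track-analyze pipeline
#'
#' Executes the four stages in order, writing every artifact under
#' \code{outDir} and recording each in a JSON manifest with its stage,
#' path, md5 checksum and the master seed. Re-running with the same
#' configuration reproduces identical checksums for the deterministic
#' stages. An invalid configuration aborts before any stage runs; a stage
#' failure aborts with the failing stage named, retaining earlier outputs.
#'
#' Recognised configuration keys (flat, as in \code{\link{readConfig}}):
#' \code{regime} (preset name), \code{founders}, \code{duration} (min),
#' \code{seed}, \code{interval} (count sampling, min), \code{render}
#' (logical; render + retrack stages), \code{field_size} (px),
#' \code{noise_sd}, \code{size_time} (min at which size distributions are
#' read), plus any \code{regime.<field>} override of
#' \code{\link{regimeParams}} (e.g. \code{regime.cycleCV = 0}).
#'
#' @param config named list or path to a key=value config file.
#' @param outDir writable output directory (created if missing).
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @examples
#' out <- file.path(tempdir(), "pipe-example")
#' m <- runPipeline(list(regime = "low_metal", founders = 1,
#'                       duration = 420, seed = 1, render = FALSE), out)
#' vapply(m$stages, function(s) s$stage, character(1))
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- readConfig(config)
  stopifnot(is.list(config))
  getOr <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  regimeName <- getOr("regime", "low_metal")
  presets <- eval(formals(regimePreset)$name)
  if (!regimeName %in% presets)
    stop("unknown regime '", regimeName, "'; available: ",
         paste(presets, collapse = ", "))
  over <- config[grepl("^regime\\.", names(config))]
  names(over) <- sub("^regime\\.", "", names(over))
  reg <- do.call(regimePreset, c(list(name = regimeName), over))
  founders <- .assertCount(getOr("founders", 1), "founders")
  duration <- getOr("duration", 600)
  seed <- getOr("seed", 1)
  interval <- getOr("interval", 6)
  doRender <- isTRUE(getOr("render", TRUE))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  manifest <- list(config = config, stages = list())
  addArtifact <- function(stage, paths) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      stage = stage, seed = seed,
      artifacts = lapply(paths, function(p) list(
        path = basename(p), md5 = unname(tools::md5sum(p)))))
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # simulate
  tree <- runStage("simulate",
                   simulatePopulation(reg, founders, duration, seed))
  cs <- countSeries(tree, interval = interval)
  treePath <- file.path(outDir, "tree.json")
  countsPath <- file.path(outDir, "counts.csv")
  newickPath <- file.path(outDir, "tree.nwk")
  writeTreeJSON(tree, treePath)
  writeCountsCSV(cs, countsPath)
  treeNewick(tree, newickPath)
  addArtifact("simulate", c(treePath, countsPath, newickPath))

  recTree <- NULL
  if (doRender) {
    rp <- renderParams(
      frameInterval = interval,
      noiseSd = getOr("noise_sd", 0),
      fieldSize = rep(as.integer(getOr("field_size", 384)), 2L),
      seed = seed)
    movie <- runStage("render", renderMovie(tree, rp))
    moviePrefix <- file.path(outDir, "movie")
    writeMovieTIFF(movie, moviePrefix)
    addArtifact("render", c(paste0(moviePrefix, "_",
                                   c("labels", "cyto", "nuclear",
                                     "budneck"), ".tif"),
                            paste0(moviePrefix, ".json")))
    rec <- runStage("track", reconstructLineage(movie))
    tracksPath <- file.path(outDir, "tracks.csv")
    eventsPath <- file.path(outDir, "events.csv")
    recTreePath <- file.path(outDir, "tree_reconstructed.json")
    writeTracksCSV(rec$tracks, tracksPath)
    writeEventsCSV(rec$events, eventsPath)
    writeTreeJSON(rec$tree, recTreePath)
    addArtifact("track", c(tracksPath, eventsPath, recTreePath))
    recTree <- rec$tree
  }

  analysis <- runStage("analyze", {
    res <- list(n_cells = nCells(tree),
                n_divisions = nrow(divisions(tree)),
                growth_mode = tryCatch(
                  classifyGrowthMode(cs, shiftTime = reg@shiftTime),
                  error = function(e) NA_character_))
    res$fit_exponential <- tryCatch({
      f <- fitExponential(cs)
      list(tau_min = f@tau, r2 = f@r2)
    }, error = function(e) NULL)
    res$fit_linear <- tryCatch({
      f <- fitLinear(cs, autoWindow = TRUE, shiftTime = reg@shiftTime)
      list(rate_cells_per_min = f@rate, r2 = f@r2,
           window = f@window)
    }, error = function(e) NULL)
    res$interdivision <- tryCatch(
      interdivisionStats(tree)[, c("division_index", "mean_min", "n")],
      error = function(e) NULL)
    res$size_gap <- tryCatch(
      sizeDistributions(tree, getOr("size_time", duration * 0.7))$gap,
      error = function(e) NA_real_)
    res$vacuole_bins <- tryCatch(vacuoleFraction(tree)$bins,
                                 error = function(e) NULL)
    if (!is.null(recTree))
      res$reconstructed_cells <- nCells(recTree)
    res
  })
  analysisPath <- file.path(outDir, "analysis.json")
  jsonlite::write_json(analysis, analysisPath, auto_unbox = TRUE,
                       digits = NA, na = "null")
  addArtifact("analyze", analysisPath)

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(manifest)
}
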