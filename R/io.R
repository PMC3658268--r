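# Readers and writers for the package's artifact formats: tree JSON,
# Newick, counts/tracks/events CSV, multi-frame TIFF movies with a JSON
# sidecar, and flat key=value configuration. Writers are byte-deterministic:
# fixed column order and floats at 6 significant digits.

.fmtNum <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15 & is.finite(x),
                sprintf("%d", as.integer(x)), sprintf("%.6g", x)))
}

.writeTable <- function(d, path) {
  cols <- names(d)
  body <- vapply(seq_len(nrow(d)), function(i) {
    paste(vapply(cols, function(cn) {
      v <- d[[cn]][i]
      if (is.numeric(v)) .fmtNum(v) else as.character(v)
    }, character(1)), collapse = ",")
  }, character(1))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

.regimeToList <- function(reg) {
  if (is.null(reg)) return(NULL)
  rp <- reg@resourceParams
  list(name = reg@name, meanCycleTime = reg@meanCycleTime,
       preCycleTime = reg@preCycleTime, cycleCV = reg@cycleCV,
       f = reg@f, preF = reg@preF, regen = reg@regen,
       preRegen = reg@preRegen, storageCap = reg@storageCap,
       criticalSize = reg@criticalSize,
       sizeGrowthRate = reg@sizeGrowthRate,
       daughterSizeFraction = reg@daughterSizeFraction,
       preDaughterSizeFraction = reg@preDaughterSizeFraction,
       shiftTime = reg@shiftTime, slowdownRef = reg@slowdownRef,
       slowdownGamma = reg@slowdownGamma,
       z0 = rp@z0, zc = rp@zc, dz = rp@dz)
}

.regimeFromList <- function(l) {
  if (is.null(l)) return(NULL)
  regimeParams(name = l$name, meanCycleTime = l$meanCycleTime,
               preCycleTime = l$preCycleTime, cycleCV = l$cycleCV,
               f = l$f, preF = l$preF, regen = l$regen,
               preRegen = l$preRegen, storageCap = l$storageCap,
               criticalSize = l$criticalSize,
               sizeGrowthRate = l$sizeGrowthRate,
               daughterSizeFraction = l$daughterSizeFraction,
               preDaughterSizeFraction = l$preDaughterSizeFraction,
               shiftTime = l$shiftTime, slowdownRef = l$slowdownRef,
               slowdownGamma = l$slowdownGamma,
               resourceParams = resourceParams(l$z0, l$zc, l$dz))
}

#' Write and read lineage trees as JSON
#'
#' Full per-cell and per-division records plus the generating regime and
#' seed; a write/read round trip reproduces the tree exactly.
#'
#' @param tree a \code{\link{LineageTree}}.
#' @param path output/input file path.
#' @return \code{readTreeJSON} returns a \code{LineageTree};
#'   \code{writeTreeJSON} the path, invisibly.
#' @export
writeTreeJSON <- function(tree, path) {
  stopifnot(is(tree, "LineageTree"))
  obj <- list(cells = cells(tree), divisions = divisions(tree),
              regime = .regimeToList(tree@regime), seed = tree@seed,
              duration = tree@duration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname writeTreeJSON
#' @export
readTreeJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- as.data.frame(obj$cells)
  dv <- as.data.frame(obj$divisions)
  for (cn in c("id", "parent_id", "generation", "n_divisions"))
    cl[[cn]] <- as.integer(cl[[cn]])
  for (cn in c("birth_time", "size_birth", "size_final", "resource_birth",
               "resource_final", "growth_start", "implosion_time",
               "recovery_time"))
    cl[[cn]] <- as.numeric(cl[[cn]])
  cl$born_pre_shift <- as.logical(cl$born_pre_shift)
  cl$status <- as.character(cl$status)
  cl$exposed_class <- as.character(cl$exposed_class)
  if (!nrow(dv)) {
    dv <- data.frame(
      mother_id = integer(), daughter_id = integer(), time = numeric(),
      mother_resource_before = numeric(), mother_resource_after = numeric(),
      daughter_resource = numeric(), mother_size = numeric(),
      daughter_size = numeric(), f_used = numeric(), post_shift = logical(),
      clipped = logical())
  }
  if (nrow(dv)) {
    for (cn in c("mother_id", "daughter_id")) dv[[cn]] <- as.integer(dv[[cn]])
    for (cn in c("time", "mother_resource_before", "mother_resource_after",
                 "daughter_resource", "mother_size", "daughter_size",
                 "f_used"))
      dv[[cn]] <- as.numeric(dv[[cn]])
    dv$post_shift <- as.logical(dv$post_shift)
    dv$clipped <- as.logical(dv$clipped)
  }
  new("LineageTree", cells = cl, divisions = dv,
      regime = .regimeFromList(obj$regime),
      seed = if (is.null(obj$seed)) NA_real_ else as.numeric(obj$seed),
      duration = as.numeric(obj$duration))
}

#' Newick export of a lineage tree
#'
#' Budding genealogies are written as binary trees: each division is an
#' internal node whose two children are the mother's continuation and the
#' newborn daughter. Branch lengths are in minutes; leaves are named
#' \code{c<id>}. One Newick line per founder.
#'
#' @param tree a \code{\link{LineageTree}}.
#' @param path optional file to write to.
#' @return character vector of Newick strings (one per founder),
#'   invisibly when written to a file.
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 1, 700, seed = 1)
#' treeNewick(tr)
#' @export
treeNewick <- function(tree, path = NULL) {
  stopifnot(is(tree, "LineageTree"))
  cl <- cells(tree)
  dv <- divisions(tree)
  span <- tree@duration
  sub <- function(id, from) {
    ev <- dv[dv$mother_id == id & dv$time > from, , drop = FALSE]
    if (!nrow(ev))
      return(sprintf("c%d:%s", id, .fmtNum(span - from)))
    ev <- ev[order(ev$time), ]
    e <- ev[1, ]
    sprintf("(%s,%s):%s", sub(id, e$time), sub(e$daughter_id, e$time),
            .fmtNum(e$time - from))
  }
  founders <- cl$id[is.na(cl$parent_id)]
  out <- vapply(founders, function(f) {
    body <- sub(f, cl$birth_time[match(f, cl$id)])
    # top-level subtree already carries the root edge length
    paste0(if (grepl("^\\(", body)) body else paste0("(", body, ")"), ";")
  }, character(1))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Write and read count series as CSV
#'
#' Columns \code{time_min,total,mothers,daughters,imploded}; reading
#' validates the schema (monotone times, non-negative integer counts) and
#' reports the offending column.
#'
#' @param series a \code{\link{CountSeries}}.
#' @param path file path.
#' @return \code{readCountsCSV} returns a \code{CountSeries}.
#' @export
writeCountsCSV <- function(series, path) {
  stopifnot(is(series, "CountSeries"))
  .writeTable(counts(series), path)
}

#' @rdname writeCountsCSV
#' @export
readCountsCSV <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_min", "total", "mothers", "daughters", "imploded")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("counts file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(diff(d$time_min) <= 0))
    stop("counts file ", path, ": time_min must be strictly increasing")
  for (cn in need[-1]) {
    if (any(is.na(d[[cn]]) | d[[cn]] < 0 | d[[cn]] != floor(d[[cn]])))
      stop("counts file ", path, ": column ", cn,
           " must hold non-negative integers")
    d[[cn]] <- as.integer(d[[cn]])
  }
  iv <- if (nrow(d) > 1) d$time_min[2] - d$time_min[1] else 6
  new("CountSeries", data = d, interval = iv)
}

#' Write tracks and events tables as CSV
#'
#' @param tracks tracks data.frame from \code{\link{trackBackwards}}.
#' @param events events data.frame from \code{\link{callEvents}}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeTracksCSV <- function(tracks, path) {
  cols <- c("cell_label", "frame", "time_min", "x", "y", "area_px",
            "nuclear_mean")
  .writeTable(tracks[, cols], path)
}

#' @rdname writeTracksCSV
#' @export
writeEventsCSV <- function(events, path) {
  .writeTable(events, path)
}

#' Write and read movies as multi-frame TIFF
#'
#' One 16-bit multi-frame TIFF per channel (\code{_labels},
#' \code{_cyto}, \code{_nuclear}, \code{_budneck}) plus a JSON sidecar
#' (\code{<prefix>.json}) holding the frame interval, times and rendering
#' parameters. Intensities are stored as rounded 16-bit counts.
#'
#' @param movie a \code{\link{Movie}}.
#' @param prefix output path prefix.
#' @return \code{readMovieTIFF} returns a \code{Movie}.
#' @export
writeMovieTIFF <- function(movie, prefix) {
  stopifnot(is(movie, "Movie"))
  wr <- function(frames, suffix) {
    imgs <- lapply(frames, function(m) {
      m[m < 0] <- 0; m[m > 65535] <- 65535
      round(m) / 65535
    })
    tiff::writeTIFF(imgs, paste0(prefix, "_", suffix, ".tif"),
                    bits.per.sample = 16L, compression = "none")
  }
  wr(movie@labels, "labels")
  wr(movie@cyto, "cyto")
  wr(movie@nuclear, "nuclear")
  wr(movie@budneck, "budneck")
  p <- movie@params
  side <- list(frame_interval = p@frameInterval, times = movie@times,
               field_size = p@fieldSize, area_scale = p@areaScale,
               noise_sd = p@noiseSd, budneck_contrast = p@budneckContrast,
               anaphase_offset = p@anaphaseOffset,
               nuclear_onset_jitter = p@nuclearOnsetJitter,
               bud_period = p@budPeriod, bg_level = p@bgLevel,
               cyto_level = p@cytoLevel, nuclear_level = p@nuclearLevel,
               budneck_level = p@budneckLevel, nuc_radius = p@nucRadius,
               neck_radius = p@neckRadius, seed = p@seed,
               provenance = movie@provenance)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname writeMovieTIFF
#' @export
readMovieTIFF <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  rd <- function(suffix, int = FALSE) {
    imgs <- tiff::readTIFF(paste0(prefix, "_", suffix, ".tif"), all = TRUE)
    lapply(imgs, function(m) {
      v <- round(m * 65535)
      if (int) matrix(as.integer(v), nrow(m), ncol(m)) else v
    })
  }
  params <- renderParams(
    frameInterval = side$frame_interval, noiseSd = side$noise_sd,
    budneckContrast = side$budneck_contrast,
    anaphaseOffset = side$anaphase_offset,
    nuclearOnsetJitter = side$nuclear_onset_jitter,
    budPeriod = side$bud_period, fieldSize = as.integer(side$field_size),
    areaScale = side$area_scale, bgLevel = side$bg_level,
    cytoLevel = side$cyto_level, nuclearLevel = side$nuclear_level,
    budneckLevel = side$budneck_level, nucRadius = side$nuc_radius,
    neckRadius = side$neck_radius, seed = side$seed)
  new("Movie", labels = rd("labels", int = TRUE), cyto = rd("cyto"),
      nuclear = rd("nuclear"), budneck = rd("budneck"),
      times = as.numeric(side$times), params = params,
      provenance = as.list(side$provenance))
}

#' Flat key=value configuration files
#'
#' \code{readConfig} parses \code{key = value} lines (\code{#} comments
#' allowed) with automatic typing of numbers and logicals;
#' \code{writeConfig} writes them back; the representation round-trips
#' losslessly.
#'
#' @param path file path.
#' @param config named list of scalar values.
#' @return \code{readConfig} returns a named list.
#' @export
readConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config line without '=': ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  out
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    s <- if (is.numeric(v)) .fmtNum(v) else as.character(v)
    paste0(k, " = ", s)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
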