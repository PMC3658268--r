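#' Accessors for asymdiv classes
#'
#' @param x an object.
#' @name accessors
NULL

#' @describeIn accessors per-cell table of a \code{LineageTree}.
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @describeIn accessors division-event table of a \code{LineageTree}.
#' @export
setGeneric("divisions", function(x) standardGeneric("divisions"))

#' @describeIn accessors number of cells.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @describeIn accessors count table of a \code{CountSeries}.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @describeIn accessors number of frames of a \code{Movie}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname cellSizeAt
#' @export
setGeneric("cellSizeAt", function(x, t, ids = NULL)
  standardGeneric("cellSizeAt"))

setMethod("cells", "LineageTree", function(x) x@cells)
setMethod("divisions", "LineageTree", function(x) x@divisions)
setMethod("nCells", "LineageTree", function(x) nrow(x@cells))
setMethod("counts", "CountSeries", function(x) x@data)
setMethod("nFrames", "Movie", function(x) length(x@labels))

#' @describeIn accessors regime used to generate a simulated tree (NULL
#'   for reconstructed trees).
#' @export
regime <- function(x) {
  stopifnot(is(x, "LineageTree"))
  x@regime
}

#' @describeIn accessors per-frame track table of a reconstructed tree.
#' @export
tracks <- function(x) {
  stopifnot(is(x, "LineageTree"))
  x@tracks
}

#' Mother/daughter classification
#'
#' A cell is classified as a mother once it has completed at least one
#' division; cells that never divided are daughters.
#'
#' @param x a \code{LineageTree}.
#' @param t classification horizon in minutes; divisions after \code{t}
#'   are ignored. Default: the full observed span.
#' @return logical vector along \code{cells(x)}, \code{TRUE} for mothers.
#' @examples
#' reg <- regimePreset("rich")
#' tr <- simulatePopulation(reg, nFounders = 1, duration = 300, seed = 1)
#' table(isMother(tr))
#' @export
isMother <- function(x, t = Inf) {
  stopifnot(is(x, "LineageTree"))
  dv <- divisions(x)
  ids <- cells(x)$id
  if (!nrow(dv)) return(setNames(rep(FALSE, length(ids)), ids))
  m <- dv$mother_id[dv$time <= t]
  setNames(ids %in% m, ids)
}

setMethod("show", "ResourceParams", function(object) {
  cat(sprintf("ResourceParams: Z0 = %g, Zc = %g, deltaZ = %g\n",
              object@z0, object@zc, object@dz))
})

setMethod("show", "CapacityResult", function(object) {
  cat("CapacityResult\n")
  if (!is.na(object@ns))
    cat(sprintf("  symmetric:  Ns = %g (%g cycles, %g discrete cells)\n",
                object@ns, object@cyclesSymmetric,
                object@cellsSymmetricDiscrete))
  if (object@unbounded) {
    cat("  asymmetric: unbounded (division can proceed indefinitely)\n")
  } else if (!is.na(object@nas)) {
    cat(sprintf("  asymmetric: Nas = %g progeny\n", object@nas))
  }
})

setMethod("show", "RegimeParams", function(object) {
  rp <- object@resourceParams
  cat(sprintf("RegimeParams '%s'\n", object@name))
  cat(sprintf("  cycle time %g min (pre-shift %g), CV %g\n",
              object@meanCycleTime, object@preCycleTime, object@cycleCV))
  cat(sprintf("  partition f %g (pre-shift %g), shift at %g min\n",
              object@f, object@preF, object@shiftTime))
  cat(sprintf("  regeneration %g/min (pre-shift %g), cap %g\n",
              object@regen, object@preRegen, object@storageCap))
  cat(sprintf("  resource Z0 = %g, Zc = %g, deltaZ = %g\n",
              rp@z0, rp@zc, rp@dz))
})

setMethod("show", "LineageTree", function(object) {
  cl <- cells(object)
  cat(sprintf("LineageTree: %d cells, %d divisions, span %g min\n",
              nrow(cl), nrow(divisions(object)), object@duration))
  if (nrow(cl)) {
    mo <- sum(cl$n_divisions > 0)
    cat(sprintf("  %d mothers, %d daughters; status: %s\n",
                mo, nrow(cl) - mo,
                paste(sprintf("%s=%d", names(table(cl$status)),
                              as.integer(table(cl$status))),
                      collapse = ", ")))
  }
  if (!is.null(object@regime))
    cat(sprintf("  regime '%s', seed %g\n", object@regime@name, object@seed))
})

setMethod("show", "CountSeries", function(object) {
  d <- object@data
  cat(sprintf("CountSeries: %d samples every %g min, final total %d\n",
              nrow(d), object@interval,
              if (nrow(d)) d$total[nrow(d)] else 0L))
})

setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit (%s): ", object@model))
  if (object@model == "exponential") {
    cat(sprintf("tau = %.4g min, r2 = %.4f", object@tau, object@r2))
  } else {
    cat(sprintf("slope = %.4g cells/min, r2 = %.4f", object@rate, object@r2))
  }
  cat(sprintf(", window [%g, %g] min\n", object@window[1], object@window[2]))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "Movie", function(object) {
  cat(sprintf("Movie: %d frames of %dx%d px every %g min\n",
              nFrames(object), object@params@fieldSize[1],
              object@params@fieldSize[2], object@params@frameInterval))
})
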