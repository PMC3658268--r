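#' @import methods
NULL

#' Parameters of the limiting-resource model
#'
#' Holds the three quantities governing division capacity under a
#' non-replenishable limiting resource: the initial vacuolar pool of a
#' progenitor cell (\code{z0}), the critical level below which division is
#' impossible (\code{zc}), and the amount lost at each division (\code{dz}).
#' All three are in the same arbitrary resource units.
#'
#' @slot z0 numeric(1), initial resource amount per progenitor, \code{> 0}.
#' @slot zc numeric(1), critical resource level, \code{0 < zc <= z0}.
#' @slot dz numeric(1), resource lost per division, \code{>= 0}.
#' @name ResourceParams-class
#' @rdname ResourceParams
#' @exportClass ResourceParams
setClass("ResourceParams",
  representation(z0 = "numeric", zc = "numeric", dz = "numeric"),
  prototype(z0 = 9, zc = 1, dz = 1))

setValidity("ResourceParams", function(object) {
  msg <- character()
  if (length(object@z0) != 1L || !is.finite(object@z0))
    msg <- c(msg, "z0 must be a single finite number")
  if (length(object@zc) != 1L || !is.finite(object@zc))
    msg <- c(msg, "zc must be a single finite number")
  if (length(object@dz) != 1L || !is.finite(object@dz))
    msg <- c(msg, "dz must be a single finite number")
  if (length(msg) == 0L) {
    if (object@zc <= 0) msg <- c(msg, "zc must be > 0")
    if (object@z0 < object@zc) msg <- c(msg, "z0 must be >= zc")
    if (object@dz < 0) msg <- c(msg, "dz must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param z0,zc,dz see slots.
#' @return \code{resourceParams} returns a validated \code{ResourceParams}.
#' @examples
#' rp <- resourceParams(z0 = 16, zc = 1, dz = 1)
#' @rdname ResourceParams
#' @export
resourceParams <- function(z0, zc, dz = 0) {
  new("ResourceParams", z0 = as.numeric(z0), zc = as.numeric(zc),
      dz = as.numeric(dz))
}

#' Division-capacity predictions
#'
#' Result container for the closed-form capacity model. \code{ns} is the
#' continuous population-growth factor under symmetric partitioning
#' (\code{z0/zc}); \code{nas} the number of progeny an asymmetrically
#' dividing progenitor can generate (\code{(z0 - zc)/dz}, \code{Inf} when
#' \code{dz = 0}); \code{cyclesSymmetric} the integer number of feasible
#' symmetric halvings and \code{cellsSymmetricDiscrete} the corresponding
#' discrete cell count \code{2^cycles}. Slots not computed by an operation
#' are \code{NA}.
#'
#' @slot ns,nas numeric(1).
#' @slot cyclesSymmetric,cellsSymmetricDiscrete numeric(1), integral values.
#' @slot unbounded logical(1), \code{TRUE} when division can proceed
#'   indefinitely (full retention, no per-division loss).
#' @name CapacityResult-class
#' @rdname CapacityResult
#' @exportClass CapacityResult
setClass("CapacityResult",
  representation(ns = "numeric", nas = "numeric",
                 cyclesSymmetric = "numeric",
                 cellsSymmetricDiscrete = "numeric",
                 unbounded = "logical"),
  prototype(ns = NA_real_, nas = NA_real_, cyclesSymmetric = NA_real_,
            cellsSymmetricDiscrete = NA_real_, unbounded = FALSE))

#' Simulation regime parameters
#'
#' One object fully specifies a growth/medium regime for
#' \code{\link{simulatePopulation}}. A regime has a pre-shift phase
#' (rich medium) and a post-shift phase; the shift at \code{shiftTime}
#' minutes switches the partition fraction, regeneration rate, daughter
#' size fraction and mean cycle time from their \code{pre*} values to the
#' main values. Regimes without a medium shift use \code{shiftTime = 0}
#' so the main values apply throughout.
#'
#' @slot name character(1), preset label.
#' @slot meanCycleTime numeric(1), post-shift mean inter-division time (min).
#' @slot preCycleTime numeric(1), pre-shift mean cycle time (min).
#' @slot cycleCV numeric(1), coefficient of variation of cycle times.
#' @slot f numeric(1), post-shift fraction of the vacuolar resource the
#'   mother retains at division (0.5 symmetric .. 1 full retention).
#' @slot preF numeric(1), pre-shift partition fraction.
#' @slot regen numeric(1), post-shift resource regeneration (units/min).
#' @slot preRegen numeric(1), pre-shift regeneration rate.
#' @slot storageCap numeric(1), maximal vacuolar pool per cell.
#' @slot criticalSize numeric(1), Start size threshold (arbitrary units).
#' @slot sizeGrowthRate numeric(1), cell growth rate (size units/min),
#'   active only while the cell's resource is at or above \code{zc}.
#' @slot daughterSizeFraction numeric(1), post-shift bud size as a fraction
#'   of the mother's size.
#' @slot preDaughterSizeFraction numeric(1), pre-shift value.
#' @slot shiftTime numeric(1), minutes at which the medium changes.
#' @slot slowdownRef numeric(1), resource level below which cycle times
#'   lengthen as \code{(slowdownRef/resource)^slowdownGamma}.
#' @slot slowdownGamma numeric(1), exponent of the coupling.
#' @slot resourceParams \code{ResourceParams} for the regime.
#' @name RegimeParams-class
#' @rdname RegimeParams
#' @exportClass RegimeParams
setClass("RegimeParams",
  representation(name = "character",
                 meanCycleTime = "numeric", preCycleTime = "numeric",
                 cycleCV = "numeric",
                 f = "numeric", preF = "numeric",
                 regen = "numeric", preRegen = "numeric",
                 storageCap = "numeric",
                 criticalSize = "numeric", sizeGrowthRate = "numeric",
                 daughterSizeFraction = "numeric",
                 preDaughterSizeFraction = "numeric",
                 shiftTime = "numeric",
                 slowdownRef = "numeric", slowdownGamma = "numeric",
                 resourceParams = "ResourceParams"))

setValidity("RegimeParams", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)
  for (s in c("meanCycleTime", "preCycleTime", "cycleCV", "f", "preF",
              "regen", "preRegen", "storageCap", "criticalSize",
              "sizeGrowthRate", "daughterSizeFraction",
              "preDaughterSizeFraction", "shiftTime", "slowdownRef",
              "slowdownGamma"))
    if (!num1(slot(object, s))) msg <- c(msg, paste(s, "must be numeric(1)"))
  if (length(msg)) return(msg)
  if (object@meanCycleTime <= 0 || object@preCycleTime <= 0)
    msg <- c(msg, "mean cycle times must be > 0")
  if (object@f < 0.5 || object@f > 1)
    msg <- c(msg, "partition fraction f must be in [0.5, 1]")
  if (object@preF < 0.5 || object@preF > 1)
    msg <- c(msg, "pre-shift partition fraction must be in [0.5, 1]")
  if (object@daughterSizeFraction <= 0 || object@daughterSizeFraction >= 1)
    msg <- c(msg, "daughterSizeFraction must be in (0, 1)")
  if (object@preDaughterSizeFraction <= 0 ||
      object@preDaughterSizeFraction >= 1)
    msg <- c(msg, "preDaughterSizeFraction must be in (0, 1)")
  if (object@regen < 0 || object@preRegen < 0)
    msg <- c(msg, "regeneration rates must be >= 0")
  if (object@shiftTime < 0) msg <- c(msg, "shiftTime must be >= 0")
  if (object@criticalSize <= 0) msg <- c(msg, "criticalSize must be > 0")
  if (object@sizeGrowthRate <= 0) msg <- c(msg, "sizeGrowthRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Stress-event parameters
#'
#' @slot kind character(1), one of \code{"zinc_shock"}, \code{"osmotic"},
#'   \code{"rapamycin"}.
#' @slot start,duration numeric(1), minutes.
#' @slot pImplodeMother,pImplodeDaughter numeric(1), per-cell implosion
#'   probabilities in \code{[0, 1]}.
#' @slot recoveryDelayMother,recoveryDelayDaughter numeric(1), minutes after
#'   the stress window before survivors of a recoverable stress resume
#'   cycling.
#' @name StressParams-class
#' @rdname StressParams
#' @exportClass StressParams
setClass("StressParams",
  representation(kind = "character", start = "numeric", duration = "numeric",
                 pImplodeMother = "numeric", pImplodeDaughter = "numeric",
                 recoveryDelayMother = "numeric",
                 recoveryDelayDaughter = "numeric"))

setValidity("StressParams", function(object) {
  msg <- character()
  if (!object@kind %in% c("zinc_shock", "osmotic", "rapamycin"))
    msg <- c(msg, "kind must be one of zinc_shock, osmotic, rapamycin")
  for (p in c("pImplodeMother", "pImplodeDaughter")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste(p, "must be a probability in [0, 1]"))
  }
  if (object@duration < 0) msg <- c(msg, "duration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param kind,start,duration,pImplodeMother,pImplodeDaughter see slots.
#' @param recoveryDelayMother,recoveryDelayDaughter see slots.
#' @rdname StressParams
#' @export
stressParams <- function(kind, start, duration = 120,
                         pImplodeMother = 0.08, pImplodeDaughter = 0.30,
                         recoveryDelayMother = 0,
                         recoveryDelayDaughter = 240) {
  new("StressParams", kind = kind, start = as.numeric(start),
      duration = as.numeric(duration),
      pImplodeMother = as.numeric(pImplodeMother),
      pImplodeDaughter = as.numeric(pImplodeDaughter),
      recoveryDelayMother = as.numeric(recoveryDelayMother),
      recoveryDelayDaughter = as.numeric(recoveryDelayDaughter))
}

#' Stress presets matching the survival experiments
#'
#' \code{"osmotic"}: salt stress with implosion of about 30\% of daughters
#' and 8\% of mothers. \code{"zinc_shock"}: resupply with toxic zinc after
#' starvation; mothers resume growth promptly, daughters only after a 4 h
#' delay. \code{"rapamycin"}: TOR inhibition hitting dividing cells, with
#' most mothers imploding and most daughters recovering.
#'
#' @param kind preset name.
#' @param start stress onset, minutes.
#' @param duration stress window length, minutes.
#' @return a \code{StressParams}.
#' @examples
#' stressPreset("osmotic", start = 510)
#' @export
stressPreset <- function(kind = c("osmotic", "zinc_shock", "rapamycin"),
                         start, duration = 120) {
  kind <- match.arg(kind)
  switch(kind,
    osmotic = stressParams("osmotic", start, duration,
                           pImplodeMother = 0.08, pImplodeDaughter = 0.30,
                           recoveryDelayMother = 0,
                           recoveryDelayDaughter = 0),
    zinc_shock = stressParams("zinc_shock", start, duration,
                              pImplodeMother = 0.05, pImplodeDaughter = 0.10,
                              recoveryDelayMother = 0,
                              recoveryDelayDaughter = 240),
    rapamycin = stressParams("rapamycin", start, duration,
                             pImplodeMother = 0.75, pImplodeDaughter = 0.15,
                             recoveryDelayMother = 120,
                             recoveryDelayDaughter = 60))
}

#' Lineage tree of a budding cell population
#'
#' Container for per-cell records and the mother-to-daughter division
#' events, produced either by \code{\link{simulatePopulation}} or by
#' \code{\link{reconstructLineage}}. Use \code{\link{cells}} and
#' \code{\link{divisions}} to access the tables; do not read slots
#' directly.
#'
#' \code{cells(x)} columns: \code{id}, \code{parent_id} (\code{NA} for
#' founders), \code{birth_time}, \code{generation}, \code{born_pre_shift},
#' \code{size_birth}, \code{resource_birth}, \code{resource_final},
#' \code{n_divisions}, \code{grew}, \code{status} (\code{alive},
#' \code{arrested} or \code{imploded}), \code{exposed_class},
#' \code{implosion_time}, \code{recovery_time}.
#'
#' \code{divisions(x)} columns: \code{mother_id}, \code{daughter_id},
#' \code{time}, \code{mother_resource_after}, \code{daughter_resource},
#' \code{mother_size}, \code{daughter_size}, \code{f_used},
#' \code{post_shift}, \code{clipped}.
#'
#' @slot cells data.frame of per-cell records.
#' @slot divisions data.frame of division events ordered by time.
#' @slot regime the generating \code{RegimeParams}, or \code{NULL} for
#'   trees reconstructed from images.
#' @slot seed numeric(1) master seed (NA when not applicable).
#' @slot duration numeric(1), simulated or observed horizon in minutes.
#' @slot tracks data.frame of per-frame track measurements (reconstructed
#'   trees only; empty otherwise).
#' @slot stress the applied \code{StressParams}, or \code{NULL}.
#' @name LineageTree-class
#' @rdname LineageTree
#' @exportClass LineageTree
setClass("LineageTree",
  representation(cells = "data.frame", divisions = "data.frame",
                 regime = "ANY", seed = "numeric", duration = "numeric",
                 tracks = "data.frame", stress = "ANY"),
  prototype(tracks = data.frame(), stress = NULL, regime = NULL,
            seed = NA_real_))

setValidity("LineageTree", function(object) {
  msg <- character()
  cl <- object@cells
  dv <- object@divisions
  if (nrow(cl)) {
    if (anyDuplicated(cl$id)) msg <- c(msg, "cell ids must be unique")
    nonroot <- !is.na(cl$parent_id)
    if (any(!cl$parent_id[nonroot] %in% cl$id))
      msg <- c(msg, "every parent_id must reference a cell")
  }
  if (nrow(dv)) {
    if (any(!dv$mother_id %in% cl$id) || any(!dv$daughter_id %in% cl$id))
      msg <- c(msg, "division events must reference known cells")
    bt <- cl$birth_time[match(dv$mother_id, cl$id)]
    if (any(dv$time < bt - 1e-9))
      msg <- c(msg, "divisions cannot precede the mother's birth")
  }
  if (length(msg)) msg else TRUE
})

#' @param cells data.frame with at least \code{id}, \code{parent_id} and
#'   \code{birth_time}; missing optional columns are filled with defaults.
#' @param divisions data.frame with at least \code{mother_id},
#'   \code{daughter_id} and \code{time}; missing columns filled with NA.
#' @param regime optional \code{RegimeParams}.
#' @param seed optional master seed.
#' @param duration observed span in minutes (default: last event time).
#' @return \code{lineageTree} returns a validated \code{LineageTree}.
#' @rdname LineageTree
#' @export
lineageTree <- function(cells, divisions = NULL, regime = NULL,
                        seed = NA_real_, duration = NULL) {
  stopifnot(all(c("id", "parent_id", "birth_time") %in% names(cells)))
  n <- nrow(cells)
  defaults <- list(
    generation = 0L, born_pre_shift = NA, size_birth = NA_real_,
    size_final = NA_real_, resource_birth = NA_real_,
    resource_final = NA_real_, n_divisions = 0L, growth_start = NA_real_,
    status = "alive", exposed_class = NA_character_,
    implosion_time = NA_real_, recovery_time = NA_real_)
  for (cn in names(defaults))
    if (is.null(cells[[cn]])) cells[[cn]] <- rep(defaults[[cn]], n)
  if (is.null(divisions))
    divisions <- data.frame(mother_id = integer(), daughter_id = integer(),
                            time = numeric())
  nd <- nrow(divisions)
  dvDefaults <- list(
    mother_resource_before = NA_real_, mother_resource_after = NA_real_,
    daughter_resource = NA_real_, mother_size = NA_real_,
    daughter_size = NA_real_, f_used = NA_real_, post_shift = NA,
    clipped = NA)
  for (cn in names(dvDefaults))
    if (is.null(divisions[[cn]])) divisions[[cn]] <- rep(dvDefaults[[cn]], nd)
  if (nd) {
    tab <- table(divisions$mother_id)
    cells$n_divisions <- as.integer(tab[as.character(cells$id)])
    cells$n_divisions[is.na(cells$n_divisions)] <- 0L
  }
  if (is.null(duration))
    duration <- max(c(cells$birth_time, divisions$time, 0))
  new("LineageTree", cells = cells, divisions = divisions, regime = regime,
      seed = as.numeric(seed), duration = as.numeric(duration))
}

#' Cell-count time series
#'
#' Per-class population counts sampled at a fixed interval. The underlying
#' table (\code{counts(x)}) has columns \code{time_min}, \code{total},
#' \code{mothers}, \code{daughters}, \code{imploded}; a cell is counted at
#' time t when it was born at or before t and had not imploded, and is a
#' mother when it had completed at least one division by t.
#'
#' @slot data data.frame as described above.
#' @slot interval numeric(1), sampling interval in minutes.
#' @name CountSeries-class
#' @rdname CountSeries
#' @exportClass CountSeries
setClass("CountSeries",
  representation(data = "data.frame", interval = "numeric"))

setValidity("CountSeries", function(object) {
  d <- object@data
  need <- c("time_min", "total", "mothers", "daughters", "imploded")
  if (!all(need %in% names(d)))
    return(paste("count table must have columns",
                 paste(need, collapse = ", ")))
  if (nrow(d) > 1 && any(diff(d$time_min) <= 0))
    return("time_min must be strictly increasing")
  if (any(d$total < 0 | d$mothers < 0 | d$daughters < 0))
    return("counts must be non-negative")
  TRUE
})

#' Growth-curve fit
#'
#' Result of \code{\link{fitExponential}} or \code{\link{fitLinear}}.
#' For an exponential fit, \code{tau} is the population doubling time
#' (1/slope of the least-squares line on log2 counts) and \code{rate} the
#' slope in doublings/min; for a linear fit, \code{rate} is the slope in
#' cells/min and \code{tau} is \code{NA} (the per-mother inter-division
#' time is a property of the lineage tree, see
#' \code{\link{interdivisionStats}}).
#'
#' @slot model character(1), \code{"exponential"} or \code{"linear"}.
#' @slot tau numeric(1), doubling time in minutes or NA.
#' @slot rate numeric(1), fitted slope.
#' @slot intercept numeric(1), fitted intercept (log2 cells or cells).
#' @slot r2 numeric(1), coefficient of determination on the fitted scale.
#' @slot window numeric(2), fitted time window (minutes).
#' @slot flags character, diagnostics such as \code{"zero-counts-dropped"}
#'   or \code{"nonpositive-slope"}.
#' @name GrowthFit-class
#' @rdname GrowthFit
#' @exportClass GrowthFit
setClass("GrowthFit",
  representation(model = "character", tau = "numeric", rate = "numeric",
                 intercept = "numeric", r2 = "numeric", window = "numeric",
                 flags = "character"),
  prototype(flags = character()))

#' Rendering parameters for synthetic time-lapse movies
#'
#' @slot frameInterval numeric(1), minutes between frames.
#' @slot noiseSd numeric(1), sd of Gaussian intensity noise per pixel.
#' @slot budneckContrast numeric(1), ratio of bud-neck ring intensity
#'   before versus after cell birth (> 1).
#' @slot anaphaseOffset numeric(1), minutes by which the daughter's
#'   nuclear-marker onset precedes bud-neck loss.
#' @slot nuclearOnsetJitter numeric(1), maximal onset jitter in frames.
#' @slot budPeriod numeric(1), minutes the bud is visible before birth.
#' @slot fieldSize integer(2), image height and width in pixels.
#' @slot areaScale numeric(1), pixels of cell area per size unit.
#' @slot bgLevel,cytoLevel,nuclearLevel,budneckLevel numeric(1) intensities.
#' @slot nucRadius,neckRadius numeric(1), marker radii in pixels.
#' @slot seed numeric(1), noise seed.
#' @name RenderParams-class
#' @rdname RenderParams
#' @exportClass RenderParams
setClass("RenderParams",
  representation(frameInterval = "numeric", noiseSd = "numeric",
                 budneckContrast = "numeric", anaphaseOffset = "numeric",
                 nuclearOnsetJitter = "numeric",
                 budPeriod = "numeric", fieldSize = "integer",
                 areaScale = "numeric", bgLevel = "numeric",
                 cytoLevel = "numeric", nuclearLevel = "numeric",
                 budneckLevel = "numeric", nucRadius = "numeric",
                 neckRadius = "numeric", seed = "numeric"))

setValidity("RenderParams", function(object) {
  msg <- character()
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@budneckContrast <= 1) msg <- c(msg, "budneckContrast must be > 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@fieldSize) != 2L || any(object@fieldSize < 32))
    msg <- c(msg, "fieldSize must be two pixel dimensions >= 32")
  if (length(msg)) msg else TRUE
})

#' @param frameInterval,noiseSd,budneckContrast,anaphaseOffset see slots.
#' @param nuclearOnsetJitter,budPeriod see slots.
#' @param fieldSize,areaScale,bgLevel,cytoLevel,nuclearLevel,budneckLevel see slots.
#' @param nucRadius,neckRadius,seed see slots.
#' @rdname RenderParams
#' @export
renderParams <- function(frameInterval = 6, noiseSd = 0,
                         budneckContrast = 5, anaphaseOffset = 12,
                         nuclearOnsetJitter = 0,
                         budPeriod = 60, fieldSize = c(384L, 384L),
                         areaScale = 200, bgLevel = 100, cytoLevel = 500,
                         nuclearLevel = 2000, budneckLevel = 1000,
                         nucRadius = 3, neckRadius = 3, seed = 1) {
  new("RenderParams", frameInterval = as.numeric(frameInterval),
      noiseSd = as.numeric(noiseSd),
      budneckContrast = as.numeric(budneckContrast),
      anaphaseOffset = as.numeric(anaphaseOffset),
      nuclearOnsetJitter = as.numeric(nuclearOnsetJitter),
      budPeriod = as.numeric(budPeriod),
      fieldSize = as.integer(fieldSize), areaScale = as.numeric(areaScale),
      bgLevel = as.numeric(bgLevel), cytoLevel = as.numeric(cytoLevel),
      nuclearLevel = as.numeric(nuclearLevel),
      budneckLevel = as.numeric(budneckLevel),
      nucRadius = as.numeric(nucRadius), neckRadius = as.numeric(neckRadius),
      seed = as.numeric(seed))
}

#' Synthetic time-lapse movie
#'
#' Frames at a fixed interval, each holding a 16-bit-style label mask
#' (0 background, stable cell ids), a cytoplasm (bright-field proxy)
#' channel, a nuclear-marker channel and a bud-neck-marker channel.
#'
#' @slot labels,cyto,nuclear,budneck lists of matrices, one per frame.
#' @slot times numeric, frame times in minutes (frame 1 at t = 0).
#' @slot params the \code{RenderParams} used.
#' @slot provenance list with the generating tree's seed and cell count.
#' @name Movie-class
#' @rdname Movie
#' @exportClass Movie
setClass("Movie",
  representation(labels = "list", cyto = "list", nuclear = "list",
                 budneck = "list", times = "numeric",
                 params = "RenderParams", provenance = "list"))
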