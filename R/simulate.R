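# Agent-based simulator of budding populations. Each cell is simulated
# independently: eligibility to divide requires reaching the Start size
# threshold and a vacuolar resource at or above the critical level Zc;
# cycle durations are lognormal around the regime mean, stretched when the
# pool falls below the regime's slowdown reference. At division the mother
# keeps fraction f of the pool minus the per-division loss deltaZ and the
# bud receives the remainder.

# Resource level after regenerating from t0 to t1 under the regime's
# piecewise (pre/post shift) regeneration rate, capped at storageCap.
.advanceResource <- function(regime, R, t0, t1) {
  if (t1 <= t0) return(R)
  sh <- regime@shiftTime
  cap <- regime@storageCap
  if (t0 < sh) {
    R <- min(cap, R + regime@preRegen * (min(t1, sh) - t0))
    t0 <- min(t1, sh)
  }
  if (t1 > t0) R <- min(cap, R + regime@regen * (t1 - t0))
  R
}

# Earliest time >= t0 at which the pool reaches `target`, or Inf.
.timeToReach <- function(regime, R, t0, target) {
  if (R >= target) return(t0)
  sh <- regime@shiftTime
  if (target > regime@storageCap) return(Inf)
  if (t0 < sh && regime@preRegen > 0) {
    tHit <- t0 + (target - R) / regime@preRegen
    if (tHit <= sh) return(tHit)
  }
  if (t0 < sh) {
    R <- .advanceResource(regime, R, t0, sh)
    t0 <- sh
    if (R >= target) return(t0)
  }
  if (regime@regen > 0) t0 + (target - R) / regime@regen else Inf
}

# Simulate one cell's whole life. Returns its division records, the times
# of daughter births (to be queued), and terminal state. Founders carry a
# uniform cell-cycle phase (their first division completes after a uniform
# fraction of a cycle), emulating the desynchronised age structure of a
# culture at the start of observation.
.simulateCellLife <- function(regime, id, birth, s0, r0, duration, seed,
                              phase = FALSE) {
  rp <- regime@resourceParams
  zc <- rp@zc; dz <- rp@dz
  # dividing must leave the mother viable: the pool has to cover the
  # critical level plus the per-division loss before a cycle can start
  divGate <- zc + dz
  t <- birth; R <- r0; S <- s0
  growthStart <- NA_real_
  divs <- list()
  status <- "alive"
  k <- 0L
  repeat {
    # growth is gated at Zc (a starved cell cannot grow)...
    tG <- .timeToReach(regime, R, t, zc)
    if (is.finite(tG) && tG < duration && is.na(growthStart) &&
        S < regime@criticalSize)
      growthStart <- tG
    # ...division at Zc + deltaZ
    tR <- .timeToReach(regime, R, t, divGate)
    if (!is.finite(tR)) {
      status <- "arrested"
      R <- .advanceResource(regime, R, t, duration)
      if (!is.na(growthStart))
        S <- min(regime@criticalSize,
                 S + regime@sizeGrowthRate * (duration - growthStart))
      break
    }
    if (tR >= duration) {
      R <- .advanceResource(regime, R, t, duration)
      if (!is.na(growthStart))
        S <- min(regime@criticalSize,
                 S + regime@sizeGrowthRate * (duration - growthStart))
      break
    }
    R <- .advanceResource(regime, R, t, tR)
    t <- tR
    # the drawn cycle time covers G1, so Start only delays division when
    # growth is the slower of the two (it gates completion, it does not
    # add to the cycle)
    sizeReady <- t
    if (S < regime@criticalSize)
      sizeReady <- growthStart +
        (regime@criticalSize - S) / regime@sizeGrowthRate
    k <- k + 1L
    base <- if (t < regime@shiftTime) regime@preCycleTime else
      regime@meanCycleTime
    slow <- max(1, regime@slowdownRef / R)^regime@slowdownGamma
    Tcyc <- .withDrawSeed(seed, id, k,
                          .rlnormMeanCV(1, base * slow, regime@cycleCV))
    if (phase && k == 1L)
      Tcyc <- Tcyc * .withDrawSeed(seed, id, 0L, stats::runif(1))
    tDiv <- max(t + Tcyc, sizeReady)
    if (tDiv > duration) {
      if (S < regime@criticalSize)
        S <- min(regime@criticalSize,
                 S + regime@sizeGrowthRate * (duration - growthStart))
      R <- .advanceResource(regime, R, t, duration)
      break
    }
    if (S < regime@criticalSize) S <- regime@criticalSize
    Rdiv <- .advanceResource(regime, R, t, tDiv)
    post <- tDiv >= regime@shiftTime
    fUsed <- if (post) regime@f else regime@preF
    dsf <- if (post) regime@daughterSizeFraction else
      regime@preDaughterSizeFraction
    dRes <- (1 - fUsed) * Rdiv
    mKeep <- fUsed * Rdiv - dz
    clipped <- mKeep < 0
    mKeep <- max(0, mKeep)
    divs[[length(divs) + 1L]] <- list(
      time = tDiv, mother_resource_before = Rdiv,
      mother_resource_after = mKeep, daughter_resource = dRes,
      mother_size = S, daughter_size = dsf * S,
      f_used = fUsed, post_shift = post, clipped = clipped)
    R <- mKeep
    t <- tDiv
  }
  list(divisions = divs, resource_final = R, status = status,
       growth_start = growthStart, size_final = S)
}

#' Simulate a budding cell population
#'
#' Event-driven, per-cell stochastic simulation under a growth regime.
#' Founders start at the Start size threshold with a full vacuolar pool.
#' A cell becomes eligible to divide once its size reaches the regime's
#' critical size and its pool is at or above the critical resource level;
#' cell growth itself requires the pool to be at or above that level, which
#' is what arrests resource-starved daughters. Identical seed and regime
#' give bit-identical trees, and random draws are keyed per cell so that
#' extending the duration never changes the history of existing cells.
#'
#' @param regime a \code{\link{RegimeParams}}, typically from
#'   \code{\link{regimePreset}}.
#' @param nFounders number of founder cells (>= 0).
#' @param duration simulated span in minutes (>= 0).
#' @param seed master seed (integer).
#' @param maxCells safety cap on the population size.
#' @return a \code{\link{LineageTree}}.
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), nFounders = 2,
#'                          duration = 900, seed = 1)
#' tr
#' @export
simulatePopulation <- function(regime, nFounders, duration, seed = 1,
                               maxCells = 2e5) {
  stopifnot(is(regime, "RegimeParams"))
  validObject(regime)
  nFounders <- .assertCount(nFounders, "nFounders")
  if (length(duration) != 1L || is.na(duration) || duration < 0)
    stop("duration must be a single non-negative number of minutes")
  rp <- regime@resourceParams

  emptyCells <- data.frame(
    id = integer(), parent_id = integer(), birth_time = numeric(),
    generation = integer(), born_pre_shift = logical(),
    size_birth = numeric(), size_final = numeric(),
    resource_birth = numeric(), resource_final = numeric(),
    n_divisions = integer(), growth_start = numeric(),
    status = character(), exposed_class = character(),
    implosion_time = numeric(), recovery_time = numeric())
  emptyDivs <- data.frame(
    mother_id = integer(), daughter_id = integer(), time = numeric(),
    mother_resource_before = numeric(), mother_resource_after = numeric(),
    daughter_resource = numeric(), mother_size = numeric(),
    daughter_size = numeric(), f_used = numeric(), post_shift = logical(),
    clipped = logical())
  if (nFounders == 0L)
    return(new("LineageTree", cells = emptyCells, divisions = emptyDivs,
               regime = regime, seed = as.numeric(seed),
               duration = as.numeric(duration)))

  # pending cells awaiting simulation, processed in birth order so that
  # ids are assigned chronologically and deterministically
  pending <- vector("list", nFounders)
  for (i in seq_len(nFounders))
    pending[[i]] <- list(parent = NA_integer_, birth = 0,
                         size = regime@criticalSize, resource = rp@z0,
                         gen = 0L)
  cellRows <- list()
  divRows <- list()
  nextId <- 1L
  while (length(pending)) {
    births <- vapply(pending, function(p) p$birth, numeric(1))
    j <- which.min(births)  # ties: first created wins
    p <- pending[[j]]
    pending[[j]] <- NULL
    id <- nextId; nextId <- nextId + 1L
    if (id > maxCells)
      stop("population exceeded maxCells = ", maxCells)
    life <- .simulateCellLife(regime, id, p$birth, p$size, p$resource,
                              duration, seed,
                              phase = is.na(p$parent))
    nd <- length(life$divisions)
    cellRows[[id]] <- data.frame(
      id = id, parent_id = p$parent, birth_time = p$birth,
      generation = p$gen,
      born_pre_shift = p$birth < regime@shiftTime || p$birth == 0,
      size_birth = p$size, size_final = life$size_final,
      resource_birth = p$resource, resource_final = life$resource_final,
      n_divisions = nd, growth_start = life$growth_start,
      status = life$status, exposed_class = NA_character_,
      implosion_time = NA_real_, recovery_time = NA_real_)
    for (dv in life$divisions) {
      pending[[length(pending) + 1L]] <- list(
        parent = id, birth = dv$time, size = dv$daughter_size,
        resource = dv$daughter_resource, gen = p$gen + 1L)
      divRows[[length(divRows) + 1L]] <- data.frame(
        mother_id = id, daughter_id = NA_integer_, time = dv$time,
        mother_resource_before = dv$mother_resource_before,
        mother_resource_after = dv$mother_resource_after,
        daughter_resource = dv$daughter_resource,
        mother_size = dv$mother_size, daughter_size = dv$daughter_size,
        f_used = dv$f_used, post_shift = dv$post_shift,
        clipped = dv$clipped)
    }
  }
  cellsDf <- do.call(rbind, cellRows)
  divsDf <- if (length(divRows)) do.call(rbind, divRows) else emptyDivs
  if (nrow(divsDf)) {
    # link daughters: a daughter is the cell whose (parent, birth) matches
    key <- paste(divsDf$mother_id, signif(divsDf$time, 12))
    ckey <- paste(cellsDf$parent_id, signif(cellsDf$birth_time, 12))
    divsDf$daughter_id <- cellsDf$id[match(key, ckey)]
    divsDf <- divsDf[order(divsDf$time, divsDf$mother_id), ]
    rownames(divsDf) <- NULL
  }
  new("LineageTree", cells = cellsDf, divisions = divsDf, regime = regime,
      seed = as.numeric(seed), duration = as.numeric(duration))
}

#' Apply a stress event to a population
#'
#' Every cell alive at the stress onset implodes independently with its
#' class probability (mother versus daughter, classified at onset).
#' Imploded cells receive an implosion time uniform over the stress window
#' and leave the count series from that time. Survivors of recoverable
#' stresses (zinc shock, rapamycin) are assigned a recovery time after
#' their class delay.
#'
#' @param tree a \code{\link{LineageTree}}.
#' @param stress a \code{\link{StressParams}} (see
#'   \code{\link{stressPreset}}).
#' @param seed integer seed for the implosion draws.
#' @return the tree with statuses, implosion and recovery times updated
#'   and the stress recorded.
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 2, 800, seed = 1)
#' st <- applyStress(tr, stressPreset("osmotic", start = 700), seed = 2)
#' table(cells(st)$status)
#' @export
applyStress <- function(tree, stress, seed = 1) {
  stopifnot(is(tree, "LineageTree"), is(stress, "StressParams"))
  validObject(stress)
  if (stress@start < 0 || stress@start > tree@duration)
    stop("stress window must start within the simulated span [0, ",
         tree@duration, "]")
  cl <- cells(tree)
  dv <- divisions(tree)
  if (!nrow(cl)) return(tree)
  mothersAt <- unique(dv$mother_id[dv$time <= stress@start])
  exposed <- which(cl$birth_time <= stress@start & cl$status != "imploded")
  recoverable <- stress@kind %in% c("zinc_shock", "rapamycin")
  for (i in exposed) {
    id <- cl$id[i]
    isM <- id %in% mothersAt
    cl$exposed_class[i] <- if (isM) "mother" else "daughter"
    p <- if (isM) stress@pImplodeMother else stress@pImplodeDaughter
    u <- .withDrawSeed(seed, id, 900001L, stats::runif(2))
    if (u[1] < p) {
      cl$status[i] <- "imploded"
      cl$implosion_time[i] <- stress@start + u[2] * stress@duration
    } else if (recoverable) {
      delay <- if (isM) stress@recoveryDelayMother else
        stress@recoveryDelayDaughter
      cl$recovery_time[i] <- stress@start + stress@duration + delay
      cl$status[i] <- "alive"
    }
  }
  initialize(tree, cells = cl, stress = stress)
}

#' Cell-count time series of a lineage tree
#'
#' Samples the population at a fixed interval. At each time t a cell is
#' counted when born at or before t and not yet imploded; it counts as a
#' mother when it has at least one division at or before t.
#'
#' @param tree a \code{\link{LineageTree}}.
#' @param interval sampling interval in minutes (> 0; 6 matches the
#'   imaging cadence emulated by the renderer).
#' @param horizon last sample time; defaults to the tree's span.
#' @return a \code{\link{CountSeries}}.
#' @examples
#' tr <- simulatePopulation(regimePreset("rich"), 1, 600, seed = 1)
#' head(counts(countSeries(tr)))
#' @export
countSeries <- function(tree, interval = 6, horizon = NULL) {
  stopifnot(is(tree, "LineageTree"))
  if (interval <= 0) stop("interval must be > 0")
  if (is.null(horizon)) horizon <- tree@duration
  times <- seq(0, horizon, by = interval)
  cl <- cells(tree)
  dv <- divisions(tree)
  firstDiv <- rep(Inf, nrow(cl))
  if (nrow(dv)) {
    agg <- tapply(dv$time, dv$mother_id, min)
    firstDiv[match(as.integer(names(agg)), cl$id)] <- agg
  }
  impl <- ifelse(is.na(cl$implosion_time), Inf, cl$implosion_time)
  rows <- vapply(times, function(t) {
    here <- cl$birth_time <= t & impl > t
    mo <- here & firstDiv <= t
    c(total = sum(here), mothers = sum(mo), daughters = sum(here & !mo),
      imploded = sum(impl <= t))
  }, numeric(4))
  d <- data.frame(time_min = times, total = as.integer(rows["total", ]),
                  mothers = as.integer(rows["mothers", ]),
                  daughters = as.integer(rows["daughters", ]),
                  imploded = as.integer(rows["imploded", ]))
  new("CountSeries", data = d, interval = as.numeric(interval))
}

#' Size of cells at a given time
#'
#' For simulated trees the size follows the generative growth law: a cell
#' keeps its birth size until its pool first reaches the critical resource
#' level, then grows linearly to the regime's critical size. For
#' reconstructed trees the size is read from the tracked segment areas at
#' the nearest frame.
#'
#' @param x a \code{\link{LineageTree}}.
#' @param t time in minutes.
#' @param ids cells to evaluate (default: all).
#' @return named numeric vector of sizes (arbitrary units).
#' @rdname cellSizeAt
#' @export
setMethod("cellSizeAt", "LineageTree", function(x, t, ids = NULL) {
  cl <- cells(x)
  if (is.null(ids)) ids <- cl$id
  i <- match(ids, cl$id)
  if (anyNA(i)) stop("unknown cell ids: ",
                     paste(ids[is.na(i)], collapse = ", "))
  if (!is.null(x@regime)) {
    reg <- x@regime
    gs <- cl$growth_start[i]
    s0 <- cl$size_birth[i]
    grown <- !is.na(gs) & t > gs
    sz <- s0
    sz[grown] <- pmin(reg@criticalSize,
                      s0[grown] + reg@sizeGrowthRate * (t - gs[grown]))
    return(setNames(sz, ids))
  }
  tk <- x@tracks
  if (!nrow(tk)) stop("tree has neither a regime nor tracks to read sizes")
  sz <- vapply(ids, function(id) {
    ti <- tk[tk$cell_label == id, ]
    if (!nrow(ti)) return(NA_real_)
    ti$size[which.min(abs(ti$time_min - t))]
  }, numeric(1))
  setNames(sz, ids)
})
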