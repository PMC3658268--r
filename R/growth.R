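# Growth-curve fitting and population statistics.

.seriesData <- function(series) {
  if (is(series, "CountSeries")) counts(series) else as.data.frame(series)
}

#' Pool count series from several colonies
#'
#' Sums counts of multiple fields of view at matched sample times.
#'
#' @param seriesList list of \code{\link{CountSeries}} with identical time
#'   grids.
#' @return a pooled \code{CountSeries}.
#' @export
poolCountSeries <- function(seriesList) {
  stopifnot(length(seriesList) >= 1)
  d0 <- .seriesData(seriesList[[1]])
  out <- d0
  for (s in seriesList[-1]) {
    d <- .seriesData(s)
    if (!isTRUE(all.equal(d$time_min, d0$time_min)))
      stop("count series must share the same sample times to be pooled")
    for (col in c("total", "mothers", "daughters", "imploded"))
      out[[col]] <- out[[col]] + d[[col]]
  }
  iv <- if (is(seriesList[[1]], "CountSeries")) seriesList[[1]]@interval
        else diff(d0$time_min[1:2])
  new("CountSeries", data = out, interval = iv)
}

#' Exponential growth-curve fit
#'
#' Ordinary least squares on log2(count) versus time; the doubling time is
#' the inverse slope. Fitting in log space stabilises the variance of the
#' counts and makes the doubling time a direct slope inverse. Zero counts
#' cannot be log-transformed; they are dropped and the window shrunk, with
#' a flag recording it.
#'
#' @param series a \code{\link{CountSeries}} or a data.frame with columns
#'   \code{time_min} and \code{total}.
#' @param window numeric(2) time window in minutes; default, all samples.
#' @param column which count column to fit.
#' @return a \code{\link{GrowthFit}} with \code{model = "exponential"}.
#' @examples
#' d <- data.frame(time_min = seq(0, 600, 6))
#' d$total <- 4 * 2^(d$time_min / 103)
#' fitExponential(d)  # tau = 103, r2 = 1
#' @export
fitExponential <- function(series, window = NULL, column = "total") {
  d <- .seriesData(series)
  if (is.null(window)) window <- range(d$time_min)
  d <- d[d$time_min >= window[1] & d$time_min <= window[2], ]
  flags <- character()
  if (any(d[[column]] <= 0)) {
    d <- d[d[[column]] > 0, ]
    flags <- c(flags, "zero-counts-dropped")
  }
  if (nrow(d) < 4) stop("need at least 4 positive samples in the window")
  y <- log2(d[[column]])
  fit <- stats::lm(y ~ d$time_min)
  slope <- unname(stats::coef(fit)[2])
  r2 <- .rsq(y, stats::fitted(fit))
  tau <- if (is.finite(slope) && slope > 1e-10) 1 / slope else NA_real_
  if (is.na(tau)) flags <- c(flags, "nonpositive-slope")
  new("GrowthFit", model = "exponential", tau = tau, rate = slope,
      intercept = unname(stats::coef(fit)[1]), r2 = r2,
      window = range(d$time_min), flags = flags)
}

# Longest suffix window (earliest feasible start) whose linear fit reaches
# the r2 floor; used to isolate the "linear part" of a growth curve.
.autoLinearWindow <- function(d, r2Floor, minStart, column) {
  n <- nrow(d)
  starts <- which(d$time_min >= minStart)
  starts <- starts[starts <= n - 3]
  if (!length(starts)) starts <- max(1L, n - 3L)
  best <- NULL
  for (i in starts) {
    y <- d[[column]][i:n]
    x <- d$time_min[i:n]
    r2 <- .rsq(y, stats::fitted(stats::lm(y ~ x)))
    if (is.null(best) || r2 > best$r2) best <- list(i = i, r2 = r2)
    if (r2 >= r2Floor) return(list(i = i, r2 = r2, met = TRUE))
  }
  c(best, met = FALSE)
}

#' Linear growth-curve fit
#'
#' Ordinary least squares on counts versus time. With
#' \code{autoWindow = TRUE} the fitted window is the longest suffix of the
#' series whose linear fit reaches \code{r2Floor}, starting no earlier
#' than \code{shiftTime + transitionExclude} so the transition period
#' after a medium shift is excluded.
#'
#' @inheritParams fitExponential
#' @param autoWindow select the linear part automatically.
#' @param r2Floor minimal r2 for the automatic window.
#' @param shiftTime medium-shift time in minutes (0 when none).
#' @param transitionExclude minutes after the shift excluded from fitting.
#' @return a \code{\link{GrowthFit}} with \code{model = "linear"};
#'   \code{rate} is the slope in cells/min.
#' @examples
#' d <- data.frame(time_min = seq(0, 600, 6))
#' d$total <- 10 + 0.2 * d$time_min
#' fitLinear(d)  # slope 0.2, r2 = 1
#' @export
fitLinear <- function(series, autoWindow = FALSE, window = NULL,
                      r2Floor = 0.98, shiftTime = 0,
                      transitionExclude = 120, column = "total") {
  d <- .seriesData(series)
  if (nrow(d) < 4) stop("need at least 4 samples")
  flags <- character()
  if (autoWindow) {
    w <- .autoLinearWindow(d, r2Floor, shiftTime + transitionExclude, column)
    if (!isTRUE(w$met)) flags <- c(flags, "r2-floor-not-met")
    d <- d[w$i:nrow(d), ]
  } else if (!is.null(window)) {
    d <- d[d$time_min >= window[1] & d$time_min <= window[2], ]
  }
  y <- d[[column]]
  fit <- stats::lm(y ~ d$time_min)
  new("GrowthFit", model = "linear", tau = NA_real_,
      rate = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = .rsq(y, stats::fitted(fit)),
      window = range(d$time_min), flags = flags)
}

#' Classify a count series as exponential or linear growth
#'
#' Fits both models on a common window (the whole series minus the
#' transition period after any medium shift) and compares their
#' coefficients of determination. A margin below \code{margin} is declared
#' ambiguous.
#'
#' @inheritParams fitLinear
#' @param margin minimal r2 difference to call a winner.
#' @return \code{"exponential"}, \code{"linear"} or \code{"ambiguous"}.
#' @examples
#' d <- data.frame(time_min = seq(0, 600, 6))
#' d$total <- round(4 * 2^(d$time_min / 103))
#' classifyGrowthMode(d)
#' @export
classifyGrowthMode <- function(series, margin = 0.01, shiftTime = 0,
                               transitionExclude = 120, column = "total") {
  d <- .seriesData(series)
  if (nrow(d) < 8) stop("need at least 8 samples to classify growth mode")
  dw <- d[d$time_min >= shiftTime + transitionExclude, ]
  if (nrow(dw) < 8) dw <- d[max(1, nrow(d) - 7):nrow(d), ]
  lin <- fitLinear(dw, column = column)
  if (all(dw[[column]] <= 0)) return("ambiguous")
  expo <- tryCatch(fitExponential(dw, column = column),
                   error = function(e) NULL)
  r2e <- if (is.null(expo)) -Inf else expo@r2
  if (abs(r2e - lin@r2) < margin) return("ambiguous")
  if (r2e > lin@r2) "exponential" else "linear"
}

#' Per-generation inter-division times
#'
#' For each mother, the successive differences of its division times,
#' indexed by the division's rank. With \code{postShiftOnly} the ranks
#' count only cycles completed after the medium shift (both ends of the
#' cycle at or after \code{shiftTime}).
#'
#' @param tree a \code{\link{LineageTree}} with at least one division.
#' @param postShiftOnly restrict to post-shift cycles.
#' @return data.frame with columns \code{division_index}, \code{mean_min},
#'   \code{sd_min}, \code{n}; the raw per-cycle table is attached as
#'   attribute \code{"cycles"} (columns \code{mother_id}, \code{index},
#'   \code{cycle_min}).
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 2, 1500, seed = 1)
#' interdivisionStats(tr)
#' @export
interdivisionStats <- function(tree, postShiftOnly = TRUE) {
  stopifnot(is(tree, "LineageTree"))
  dv <- divisions(tree)
  if (!nrow(dv)) stop("tree has no divisions")
  shift <- if (!is.null(tree@regime)) tree@regime@shiftTime else 0
  rows <- list()
  for (m in unique(dv$mother_id)) {
    tt <- sort(dv$time[dv$mother_id == m])
    if (postShiftOnly) tt <- tt[tt >= shift]
    if (length(tt) < 2) next
    cyc <- diff(tt)
    rows[[length(rows) + 1L]] <- data.frame(
      mother_id = m, index = seq_along(cyc), cycle_min = cyc)
  }
  if (!length(rows))
    stop("no mother has two or more ", if (postShiftOnly) "post-shift ",
         "divisions")
  cyc <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(cyc$cycle_min, cyc$index), function(v)
    data.frame(mean_min = mean(v), sd_min = stats::sd(v), n = length(v))))
  out <- data.frame(division_index = as.integer(rownames(agg)), agg,
                    row.names = NULL)
  out <- out[order(out$division_index), ]
  attr(out, "cycles") <- cyc
  out
}

#' Cycle durations grouped by generation
#'
#' The duration of the cycle ending at each division (time since the
#' mother's previous division, or since her birth for a first division),
#' aggregated by the dividing cell's generation. Under symmetric dilution
#' of the limiting pool (whi5-like regimes) the per-generation means
#' lengthen progressively; under mother-retention they stay flat.
#' Founders' first cycles are excluded (they start at an arbitrary
#' cell-cycle phase). With \code{postShiftOnly} only cells born at or
#' after the medium shift contribute, so every pool in a generation was
#' set by post-shift partitioning rather than by pre-shift replenishment;
#' note that the highest observed generation is right-censored (only its
#' fastest cycles complete before the horizon).
#'
#' @param tree a \code{\link{LineageTree}}.
#' @param postShiftOnly restrict to divisions of cells born at or after
#'   the medium shift.
#' @return data.frame with columns \code{generation}, \code{mean_min},
#'   \code{sd_min}, \code{n}; raw per-event table attached as attribute
#'   \code{"cycles"}.
#' @examples
#' tr <- simulatePopulation(regimePreset("whi5"), 5, 1100, seed = 1)
#' cycleTimesByGeneration(tr)
#' @export
cycleTimesByGeneration <- function(tree, postShiftOnly = TRUE) {
  stopifnot(is(tree, "LineageTree"))
  dv <- divisions(tree)
  cl <- cells(tree)
  if (!nrow(dv)) stop("tree has no divisions")
  shift <- if (!is.null(tree@regime)) tree@regime@shiftTime else 0
  rows <- list()
  for (m in unique(dv$mother_id)) {
    tt <- sort(dv$time[dv$mother_id == m])
    i <- match(m, cl$id)
    starts <- c(cl$birth_time[i], tt[-length(tt)])
    firstOfFounder <- is.na(cl$parent_id[i]) &
      seq_along(tt) == 1L
    keep <- !firstOfFounder
    if (postShiftOnly)
      keep <- keep & tt >= shift & cl$birth_time[i] >= shift
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      generation = cl$generation[i], cycle_min = (tt - starts)[keep])
  }
  if (!length(rows)) stop("no usable cycles in the tree")
  cyc <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(cyc$cycle_min, cyc$generation),
    function(v) data.frame(mean_min = mean(v), sd_min = stats::sd(v),
                           n = length(v))))
  out <- data.frame(generation = as.integer(rownames(agg)), agg,
                    row.names = NULL)
  out <- out[order(out$generation), ]
  attr(out, "cycles") <- cyc
  out
}

#' Mother/daughter size distributions at a time point
#'
#' Sizes of cells alive at time \code{t}, split by mother/daughter class.
#' With \code{ageCorrect} every cell's growth curve is shifted so that all
#' births align, and sizes are read at a common age (the median age of the
#' alive cells), removing the age-driven component of the size difference.
#' The relative gap is \code{1 - median(daughter)/median(mother)}.
#'
#' @param tree a \code{\link{LineageTree}}.
#' @param t evaluation time in minutes, within the observed span.
#' @param ageCorrect align births before reading sizes.
#' @return list with \code{mothers}, \code{daughters} (numeric size
#'   vectors), \code{gap} (NA with a \code{flag} when a class has fewer
#'   than 3 cells) and \code{common_age} (when corrected).
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 5, 800, seed = 1)
#' sizeDistributions(tr, t = 700)$gap
#' @export
sizeDistributions <- function(tree, t, ageCorrect = FALSE) {
  stopifnot(is(tree, "LineageTree"))
  if (t < 0 || t > tree@duration)
    stop("t must lie within the observed span [0, ", tree@duration, "]")
  cl <- cells(tree)
  impl <- ifelse(is.na(cl$implosion_time), Inf, cl$implosion_time)
  alive <- cl$birth_time <= t & impl > t
  mo <- isMother(tree, t) & alive
  da <- alive & !mo
  commonAge <- NA_real_
  if (ageCorrect) {
    commonAge <- stats::median(t - cl$birth_time[alive])
    sz <- rep(NA_real_, nrow(cl))
    for (i in which(alive))
      sz[i] <- cellSizeAt(tree, cl$birth_time[i] + commonAge, cl$id[i])
  } else {
    sz <- rep(NA_real_, nrow(cl))
    sz[alive] <- cellSizeAt(tree, t, cl$id[alive])
  }
  mSizes <- sz[mo]
  dSizes <- sz[da]
  gap <- NA_real_
  flag <- NULL
  if (length(mSizes) >= 3 && length(dSizes) >= 3) {
    gap <- 1 - stats::median(dSizes) / stats::median(mSizes)
  } else flag <- "class-with-fewer-than-3-cells"
  list(mothers = mSizes, daughters = dSizes, gap = gap,
       common_age = commonAge, flag = flag)
}

#' Vacuole partition fractions at division
#'
#' For every division the fraction of the segregated vacuolar pool
#' received by the daughter and retained by the mother. Fractions are
#' computed on the pool as it is partitioned (before the per-division
#' loss is consumed), so they sum to one and recover the regime's
#' partition fraction directly. Divisions with a zero pool are excluded
#' and counted in \code{n_undefined}.
#'
#' @param tree a simulated \code{\link{LineageTree}} (resource recorded at
#'   each division).
#' @param binMinutes width of the division-time bins.
#' @return list with \code{events} (per-division data.frame: \code{time},
#'   \code{mother_fraction}, \code{daughter_fraction}), \code{bins}
#'   (per-bin means and counts) and \code{n_undefined}.
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 3, 900, seed = 1)
#' vacuoleFraction(tr)$bins
#' @export
vacuoleFraction <- function(tree, binMinutes = 60) {
  stopifnot(is(tree, "LineageTree"))
  dv <- divisions(tree)
  if (!nrow(dv)) stop("tree records no divisions")
  if (all(is.na(dv$daughter_resource)))
    stop("tree does not record resource at divisions ",
         "(reconstructed trees do not)")
  tot <- dv$mother_resource_before
  ok <- tot > 0
  ev <- data.frame(time = dv$time[ok],
                   mother_fraction = 1 - dv$daughter_resource[ok] / tot[ok],
                   daughter_fraction = dv$daughter_resource[ok] / tot[ok])
  bin <- floor(ev$time / binMinutes) * binMinutes
  bins <- do.call(rbind, lapply(split(ev, bin), function(g)
    data.frame(bin_start = min(floor(g$time / binMinutes) * binMinutes),
               mother_fraction = mean(g$mother_fraction),
               daughter_fraction = mean(g$daughter_fraction),
               n = nrow(g))))
  rownames(bins) <- NULL
  list(events = ev, bins = bins[order(bins$bin_start), ],
       n_undefined = sum(!ok))
}

#' Stress-survival tallies per cell class
#'
#' Counts exposed, imploded and recovered cells per class (mother versus
#' daughter at stress onset) after \code{\link{applyStress}}, with
#' binomial standard errors on the implosion fractions.
#'
#' @param tree a \code{\link{LineageTree}} to which a stress was applied.
#' @return data.frame with one row per class: \code{class},
#'   \code{n_exposed}, \code{n_imploded}, \code{n_recovered},
#'   \code{implosion_fraction}, \code{se}.
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 2, 800, seed = 1)
#' st <- applyStress(tr, stressPreset("osmotic", start = 700), seed = 2)
#' stressSurvival(st)
#' @export
stressSurvival <- function(tree) {
  stopifnot(is(tree, "LineageTree"))
  cl <- cells(tree)
  out <- lapply(c("mother", "daughter"), function(k) {
    e <- cl[!is.na(cl$exposed_class) & cl$exposed_class == k, ]
    n <- nrow(e)
    ni <- sum(e$status == "imploded")
    nr <- sum(!is.na(e$recovery_time) & e$status != "imploded")
    frac <- if (n > 0) ni / n else NA_real_
    data.frame(class = k, n_exposed = n, n_imploded = ni, n_recovered = nr,
               implosion_fraction = frac,
               se = if (n > 0) sqrt(frac * (1 - frac) / n) else NA_real_)
  })
  do.call(rbind, out)
}
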