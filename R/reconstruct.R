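# Image-analysis pipeline: segment the last frame, track every segment
# backwards to the first frame, call nuclear-separation and birth events
# from the marker channels, and assemble the lineage tree. Segmentation
# and tracking operate on the intensity channels only; the movie's
# ground-truth label masks are never read (they exist for testing).

#' Tracking and event-calling thresholds
#'
#' @param dropThreshold minimal fractional drop of the (median-smoothed)
#'   bud-neck trace between consecutive frames to call a birth.
#' @param windowMin association window in minutes: a birth must follow
#'   nuclear separation by at most this much.
#' @param nucK nuclear detection threshold in background sds above the
#'   background mean.
#' @param neckRadius radius in pixels of the neck-measurement disc.
#' @return list of settings for the reconstruction functions.
#' @export
trackingParams <- function(dropThreshold = 0.5, windowMin = 30, nucK = 5,
                           neckRadius = 4) {
  list(dropThreshold = dropThreshold, windowMin = windowMin, nucK = nucK,
       neckRadius = neckRadius)
}

# Background statistics and detection thresholds estimated from a frame.
# The background dominates the pixel population, so its level and spread
# are taken as the median and mad; a floor of a quarter of the dynamic
# range keeps the threshold meaningful on noiseless input (mad 0).
.channelThreshold <- function(x, k) {
  bg <- stats::median(x)
  s <- stats::mad(x)
  hi <- stats::quantile(x, 0.999, names = FALSE)
  list(bg = bg, sd = s, thr = bg + max(k * s, 0.25 * (hi - bg), 1e-6))
}

# 3x3 box smoothing of noisy frames before thresholding; noiseless
# frames pass through untouched.
.prepFrame <- function(x, noisy) {
  if (!noisy) return(x)
  EBImage::filter2(x, matrix(1 / 9, 3, 3), boundary = "replicate")
}

.frameStats <- function(seg, nuc) {
  idx <- which(seg > 0)
  if (!length(idx))
    return(data.frame(label = integer(), area = integer(), x = numeric(),
                      y = numeric(), nuc_mean = numeric(),
                      nuc_max = numeric()))
  nr <- nrow(seg)
  lab <- seg[idx]
  ys <- ((idx - 1L) %% nr) + 1L
  xs <- ((idx - 1L) %/% nr) + 1L
  area <- as.vector(rowsum(rep(1L, length(idx)), lab))
  labs <- sort(unique(lab))
  nucMax <- vapply(split(nuc[idx], lab), max, numeric(1))
  data.frame(label = labs, area = area,
             x = as.vector(rowsum(as.numeric(xs), lab)) / area,
             y = as.vector(rowsum(as.numeric(ys), lab)) / area,
             nuc_mean = as.vector(rowsum(nuc[idx], lab)) / area,
             nuc_max = unname(nucMax))
}

#' Segment the final frame of a movie
#'
#' Thresholds the cytoplasm channel (median-filtered when noisy) and
#' splits touching cells by seeded region growing from the nuclear-marker
#' peaks. Regions with no nuclear seed (unborn buds) are merged into the
#' nearest seeded region of the same foreground component or dropped.
#'
#' @param movie a \code{\link{Movie}}.
#' @param pars settings from \code{\link{trackingParams}}.
#' @return integer label matrix for the last frame (0 = background).
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 1, 400, seed = 1)
#' mv <- renderMovie(tr, renderParams(fieldSize = c(160L, 160L)))
#' length(setdiff(unique(as.vector(segmentFinalFrame(mv))), 0L))
#' @export
segmentFinalFrame <- function(movie, pars = trackingParams()) {
  stopifnot(is(movie, "Movie"))
  if (nFrames(movie) == 0L) stop("movie has no frames")
  noisy <- movie@params@noiseSd > 0
  cy <- .prepFrame(movie@cyto[[nFrames(movie)]], noisy)
  nu <- .prepFrame(movie@nuclear[[nFrames(movie)]], noisy)
  thC <- .channelThreshold(cy, pars$nucK)
  thN <- .channelThreshold(nu, pars$nucK)
  fg <- cy > thC$thr
  seeds <- EBImage::bwlabel(nu > thN$thr)
  seeds[!fg] <- 0
  if (all(seeds == 0)) return(matrix(0L, nrow(cy), ncol(cy)))
  seg <- EBImage::propagate(cy / max(cy), seeds = seeds, mask = fg)
  matrix(as.integer(seg), nrow(cy), ncol(cy))
}

#' Track final-frame segments backwards to the first frame
#'
#' Each segment of the last frame is propagated frame by frame towards the
#' beginning: the previous frame's foreground is assigned to the labels it
#' overlaps, with contested pixels resolved by seeded region growing. A
#' label with no foreground overlap in a frame terminates there (a
#' daughter's track ends where its bud appears), and tracking never
#' creates a track that is absent from the final frame.
#'
#' @param movie a \code{\link{Movie}}.
#' @param finalLabels label matrix from \code{\link{segmentFinalFrame}}.
#' @param pars settings from \code{\link{trackingParams}}.
#' @return list with \code{tracks} (data.frame: \code{cell_label},
#'   \code{frame}, \code{time_min}, \code{x}, \code{y}, \code{area_px},
#'   \code{nuclear_mean}) and \code{segments} (list of per-frame label
#'   matrices).
#' @export
trackBackwards <- function(movie, finalLabels, pars = trackingParams()) {
  stopifnot(is(movie, "Movie"))
  K <- nFrames(movie)
  noisy <- movie@params@noiseSd > 0
  thC <- .channelThreshold(.prepFrame(movie@cyto[[K]], noisy), pars$nucK)
  segs <- vector("list", K)
  segs[[K]] <- finalLabels
  if (K > 1) for (k in (K - 1):1) {
    cy <- .prepFrame(movie@cyto[[k]], noisy)
    fg <- cy > thC$thr
    seeds <- segs[[k + 1]]
    seeds[!fg] <- 0L
    segs[[k]] <- if (all(seeds == 0L)) {
      matrix(0L, nrow(cy), ncol(cy))
    } else {
      matrix(as.integer(
        EBImage::propagate(cy / max(max(cy), 1), seeds = seeds, mask = fg)),
        nrow(cy), ncol(cy))
    }
  }
  rows <- lapply(seq_len(K), function(k) {
    st <- .frameStats(segs[[k]], movie@nuclear[[k]])
    if (!nrow(st)) return(NULL)
    data.frame(cell_label = st$label, frame = k,
               time_min = movie@times[k], x = st$x, y = st$y,
               area_px = st$area, nuclear_mean = st$nuc_mean,
               nuclear_max = st$nuc_max)
  })
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$cell_label, tracks$frame), ]
  rownames(tracks) <- NULL
  list(tracks = tracks, segments = segs)
}

# Mean bud-neck intensity in a disc at the gap midpoint between a
# daughter and its putative mother, per frame where both exist.
.neckTrace <- function(movie, tracks, motherLab, daughterLab, pars,
                       frameRange = NULL) {
  dims <- dim(movie@budneck[[1]])
  tm <- tracks[tracks$cell_label == motherLab, ]
  td <- tracks[tracks$cell_label == daughterLab, ]
  frames <- intersect(tm$frame, td$frame)
  if (!is.null(frameRange))
    frames <- frames[frames >= frameRange[1] & frames <= frameRange[2]]
  vals <- rep(NA_real_, nFrames(movie))
  for (k in frames) {
    a <- tm[tm$frame == k, ]; b <- td[td$frame == k, ]
    dx <- b$x - a$x; dy <- b$y - a$y
    dd <- sqrt(dx^2 + dy^2)
    if (dd == 0) next
    rm <- sqrt(a$area_px / pi); rd <- sqrt(b$area_px / pi)
    off <- (dd + rm - rd) / 2
    px <- .discIndex(a$x + dx / dd * off, a$y + dy / dd * off,
                     pars$neckRadius, dims)
    if (length(px)) vals[k] <- mean(movie@budneck[[k]][px])
  }
  vals
}

#' Call nuclear-separation and birth events from tracks
#'
#' Nuclear separation of a daughter is the first frame at which its mean
#' nuclear intensity exceeds the detection threshold (background mean plus
#' \code{nucK} background sds). Its birth is the frame of the largest
#' fractional drop of the mother-neck bud-neck trace (3-frame median
#' smoothed) within \code{windowMin} minutes at or after nuclear
#' separation, provided the drop reaches \code{dropThreshold}; otherwise
#' the event is kept with an undefined birth and a reason.
#'
#' @param movie a \code{\link{Movie}}.
#' @param tracking result of \code{\link{trackBackwards}}.
#' @param pars settings from \code{\link{trackingParams}}.
#' @return data.frame with columns \code{mother_label},
#'   \code{daughter_label}, \code{nuclear_separation_time},
#'   \code{birth_time} (NA when no significant drop was found) and
#'   \code{reason}.
#' @export
callEvents <- function(movie, tracking, pars = trackingParams()) {
  tracks <- tracking$tracks
  K <- nFrames(movie)
  noisy <- movie@params@noiseSd > 0
  thN <- .channelThreshold(.prepFrame(movie@nuclear[[K]], noisy), pars$nucK)
  interval <- movie@params@frameInterval
  labs <- unique(tracks$cell_label)
  onset <- setNames(rep(NA_integer_, length(labs)), labs)
  for (l in labs) {
    ti <- tracks[tracks$cell_label == l, ]
    on <- ti$frame[ti$nuclear_max > thN$thr]
    if (length(on)) onset[as.character(l)] <- min(on)
  }
  nucleated <- labs[!is.na(onset)]
  daughters <- nucleated[onset[as.character(nucleated)] > 1]
  ev <- list()
  for (d in daughters) {
    kOn <- onset[as.character(d)]
    here <- tracks[tracks$frame == kOn & tracks$cell_label != d, ]
    # mother candidates: cells already nucleated at the daughter's onset
    cand <- here[here$cell_label %in%
                   nucleated[onset[as.character(nucleated)] <= kOn], ]
    if (!nrow(cand)) next
    me <- tracks[tracks$frame == kOn & tracks$cell_label == d, ]
    dist <- sqrt((cand$x - me$x)^2 + (cand$y - me$y)^2)
    ord <- order(dist, cand$cell_label)
    cand <- cand[ord[seq_len(min(6L, nrow(cand)))], ]
    wEnd <- min(K, kOn + floor(pars$windowMin / interval))
    # the mother is the neighbour whose bud-neck trace shows the largest
    # significant drop near the daughter's nuclear separation
    best <- list(drop = -Inf, m = cand$cell_label[1], birth = NA_real_)
    if (wEnd > kOn) for (ci in seq_len(nrow(cand))) {
      m <- cand$cell_label[ci]
      trace <- .neckTrace(movie, tracks, m, d, pars,
                          frameRange = c(max(1, kOn - 2), wEnd + 1))
      sm <- trace
      good <- which(!is.na(trace))
      if (length(good) >= 3)
        sm[good] <- stats::runmed(trace[good], 3, endrule = "keep")
      js <- kOn:(wEnd - 1)
      frac <- (sm[js] - sm[js + 1]) / sm[js]
      frac[is.na(frac)] <- -Inf
      if (max(frac) > best$drop) {
        jBest <- js[which.max(frac)]
        best <- list(drop = max(frac), m = m,
                     birth = movie@times[jBest + 1])
      }
    }
    found <- is.finite(best$drop) && best$drop >= pars$dropThreshold
    ev[[length(ev) + 1L]] <- data.frame(
      mother_label = best$m, daughter_label = d,
      nuclear_separation_time = movie@times[kOn],
      birth_time = if (found) best$birth else NA_real_,
      reason = if (found) NA_character_ else
        "no-significant-budneck-drop-in-window")
  }
  if (!length(ev))
    return(data.frame(mother_label = integer(), daughter_label = integer(),
                      nuclear_separation_time = numeric(),
                      birth_time = numeric(), reason = character()))
  do.call(rbind, ev)
}

#' Assemble a lineage tree from tracks and events
#'
#' Cells are the founders (tracks present and nucleated at the first
#' frame) plus every daughter with a confirmed birth; parent links come
#' from the events, and a cell is classified a mother once it mothers at
#' least one confirmed birth. Cell sizes are the tracked segment areas
#' divided by the movie's area scale.
#'
#' @param movie a \code{\link{Movie}}.
#' @param tracking result of \code{\link{trackBackwards}}.
#' @param events result of \code{\link{callEvents}}.
#' @return a \code{\link{LineageTree}} (no regime; \code{tracks} filled,
#'   resource columns NA).
#' @export
buildTree <- function(movie, tracking, events) {
  tracks <- tracking$tracks
  interval <- movie@params@frameInterval
  areaScale <- movie@params@areaScale
  confirmed <- events[!is.na(events$birth_time), , drop = FALSE]
  if (nrow(confirmed) &&
      !all(confirmed$daughter_label %in% tracks$cell_label))
    stop("event references an unknown track")
  # founders: tracks present AND nucleated at the first frame
  noisy <- movie@params@noiseSd > 0
  thN <- .channelThreshold(
    .prepFrame(movie@nuclear[[nFrames(movie)]], noisy), 5)
  t1 <- tracks[tracks$frame == 1, ]
  founders <- t1$cell_label[t1$nuclear_max > thN$thr]
  founders <- setdiff(founders, confirmed$daughter_label)
  ids <- c(founders, confirmed$daughter_label)
  birth <- c(rep(0, length(founders)), confirmed$birth_time)
  parent <- c(rep(NA_integer_, length(founders)), confirmed$mother_label)
  # drop (recursively) daughters whose mother is not itself a cell, e.g.
  # when the mother's own birth could not be confirmed
  repeat {
    keep <- is.na(parent) | parent %in% ids
    if (all(keep)) break
    ids <- ids[keep]; birth <- birth[keep]; parent <- parent[keep]
  }
  gen <- setNames(rep(NA_integer_, length(ids)), ids)
  gen[as.character(ids[is.na(parent)])] <- 0L
  while (anyNA(gen)) {
    todo <- which(is.na(gen))
    progress <- FALSE
    for (i in todo) {
      g <- gen[as.character(parent[i])]
      if (!is.na(g)) { gen[i] <- g + 1L; progress <- TRUE }
    }
    if (!progress) { gen[is.na(gen)] <- NA_integer_; break }
  }
  tracks$size <- tracks$area_px / areaScale
  sizeAtBirth <- vapply(seq_along(ids), function(i) {
    ti <- tracks[tracks$cell_label == ids[i], ]
    ti$size[which.min(abs(ti$time_min - birth[i]))]
  }, numeric(1))
  sizeFinal <- vapply(ids, function(id) {
    ti <- tracks[tracks$cell_label == id, ]
    ti$size[which.max(ti$frame)]
  }, numeric(1))
  nd <- vapply(ids, function(id)
    sum(confirmed$mother_label == id), integer(1))
  cl <- data.frame(
    id = ids, parent_id = as.integer(parent), birth_time = birth,
    generation = as.integer(gen), born_pre_shift = NA,
    size_birth = sizeAtBirth, size_final = sizeFinal,
    resource_birth = NA_real_, resource_final = NA_real_,
    n_divisions = nd, growth_start = NA_real_,
    status = "alive", exposed_class = NA_character_,
    implosion_time = NA_real_, recovery_time = NA_real_)
  dvKeep <- confirmed[confirmed$mother_label %in% ids &
                        confirmed$daughter_label %in% ids, , drop = FALSE]
  nk <- nrow(dvKeep)
  dv <- data.frame(
    mother_id = as.integer(dvKeep$mother_label),
    daughter_id = as.integer(dvKeep$daughter_label),
    time = as.numeric(dvKeep$birth_time),
    mother_resource_before = rep(NA_real_, nk),
    mother_resource_after = rep(NA_real_, nk),
    daughter_resource = rep(NA_real_, nk),
    mother_size = rep(NA_real_, nk), daughter_size = rep(NA_real_, nk),
    f_used = rep(NA_real_, nk), post_shift = rep(NA, nk),
    clipped = rep(NA, nk))
  dv <- dv[order(dv$time, dv$mother_id), ]
  rownames(dv) <- NULL
  new("LineageTree", cells = cl, divisions = dv, regime = NULL,
      seed = NA_real_,
      duration = max(movie@times), tracks = tracks)
}

#' Reconstruct a lineage tree from a movie
#'
#' Convenience wrapper running \code{\link{segmentFinalFrame}},
#' \code{\link{trackBackwards}}, \code{\link{callEvents}} and
#' \code{\link{buildTree}}.
#'
#' @param movie a \code{\link{Movie}}.
#' @param pars settings from \code{\link{trackingParams}}.
#' @return list with \code{tree} (\code{\link{LineageTree}}),
#'   \code{tracks}, \code{events} and \code{finalLabels}.
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 1, 400, seed = 1)
#' mv <- renderMovie(tr, renderParams(fieldSize = c(160L, 160L)))
#' rec <- reconstructLineage(mv)
#' rec$tree
#' @export
reconstructLineage <- function(movie, pars = trackingParams()) {
  seg <- segmentFinalFrame(movie, pars)
  tk <- trackBackwards(movie, seg, pars)
  ev <- callEvents(movie, tk, pars)
  tree <- buildTree(movie, tk, ev)
  list(tree = tree, tracks = tk$tracks, events = ev, finalLabels = seg)
}
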