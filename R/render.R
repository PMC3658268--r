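# Renders a simulated lineage tree into a synthetic time-lapse movie
# carrying exactly the cues the reconstruction algorithm uses: a cytoplasm
# (bright-field proxy) channel for segmentation, a nuclear marker that
# switches on in the bud at nuclear separation, and a bud-neck marker that
# drops sharply at cell birth. Geometry is planar, mimicking growth in a
# flow cell: non-overlapping discs, each daughter placed at the first free
# angular position clockwise from the mother's previous bud site.

# Pixel count of a disc of radius r centred on a pixel.
.discCount <- function(r) {
  dy <- seq(-floor(r), floor(r))
  sum(2 * floor(sqrt(pmax(0, r^2 - dy^2))) + 1)
}

# Radius whose integer-centred rasterization best matches a target pixel
# area; keeps labelled areas within rasterization tolerance of the size
# they encode.
.radiusForArea <- function(area) {
  r0 <- sqrt(area / pi)
  grid <- seq(max(0.8, r0 - 1.5), r0 + 1.5, by = 0.02)
  counts <- vapply(grid, .discCount, numeric(1))
  grid[which.min(abs(counts - area))]
}

.discIndex <- function(cx, cy, r, dims) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(dims[2], ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(dims[1], ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer())
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  (g$x[keep] - 1L) * dims[1] + g$y[keep]
}

# Deterministic planar layout: founders on a grid, every daughter at the
# first free angle clockwise from the mother's previous bud site, centers
# separated by the cells' reserved (maximal) radii.
.layoutTree <- function(tree, params) {
  cl <- cells(tree)
  if (!nrow(cl)) return(data.frame())
  reg <- tree@regime
  dims <- params@fieldSize
  maxSize <- ifelse(is.na(cl$growth_start) & cl$size_birth < reg@criticalSize,
                    cl$size_birth, reg@criticalSize)
  resR <- sqrt(maxSize * params@areaScale / pi) + 2
  ord <- order(cl$birth_time, cl$id)
  pos <- data.frame(id = cl$id, x = NA_real_, y = NA_real_, reserved = resR)
  lastAngle <- setNames(rep(pi / 2, nrow(cl)), cl$id)
  founders <- cl$id[is.na(cl$parent_id)]
  ncolF <- ceiling(sqrt(length(founders)))
  nrowF <- ceiling(length(founders) / ncolF)
  for (fi in seq_along(founders)) {
    gx <- (fi - 1) %% ncolF
    gy <- (fi - 1) %/% ncolF
    i <- match(founders[fi], pos$id)
    pos$x[i] <- round(dims[2] * (gx + 0.5) / ncolF)
    pos$y[i] <- round(dims[1] * (gy + 0.5) / nrowF)
  }
  placed <- !is.na(pos$x)
  for (i in ord) {
    if (placed[i]) next
    pid <- cl$parent_id[i]
    j <- match(pid, pos$id)
    dist0 <- pos$reserved[j] + pos$reserved[i]
    ok <- FALSE
    for (mult in c(1, 1.15, 1.3, 1.5, 1.75, 2, 2.3)) {
      a0 <- lastAngle[as.character(pid)]
      for (s in seq_len(24)) {
        ang <- a0 - s * pi / 12  # clockwise from the previous bud site
        x <- round(pos$x[j] + cos(ang) * dist0 * mult)
        y <- round(pos$y[j] - sin(ang) * dist0 * mult)
        if (x < pos$reserved[i] + 1 || x > dims[2] - pos$reserved[i] ||
            y < pos$reserved[i] + 1 || y > dims[1] - pos$reserved[i]) next
        d2 <- (pos$x[placed] - x)^2 + (pos$y[placed] - y)^2
        if (all(d2 >= (pos$reserved[placed] + pos$reserved[i])^2)) {
          pos$x[i] <- x; pos$y[i] <- y
          lastAngle[as.character(pid)] <- ang
          lastAngle[as.character(cl$id[i])] <- ang + pi
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    if (!ok)
      stop("overcrowded layout: cannot place cell ", cl$id[i],
           " (born at frame ",
           floor(cl$birth_time[i] / params@frameInterval) + 1, ")")
    placed[i] <- TRUE
  }
  pos
}

#' Render a lineage tree as a synthetic time-lapse movie
#'
#' Cells are drawn as non-overlapping discs with pixel area proportional
#' to their current size. A bud carrying the daughter's label appears
#' attached to the mother \code{budPeriod} minutes before each division
#' and grows until birth. The daughter's nuclear signal switches on at
#' nuclear separation (\code{anaphaseOffset} minutes before birth), and a
#' bud-neck ring between mother and bud is bright from bud emergence and
#' drops by \code{budneckContrast} at birth. Gaussian pixel noise of sd
#' \code{noiseSd} is added to the intensity channels; rendering is
#' deterministic given the parameters' seed.
#'
#' @param tree a simulated \code{\link{LineageTree}}.
#' @param params a \code{\link{RenderParams}}.
#' @param horizon last frame time in minutes (default: the tree's span).
#' @return a \code{\link{Movie}}.
#' @examples
#' tr <- simulatePopulation(regimePreset("low_metal"), 1, 500, seed = 1)
#' mv <- renderMovie(tr, renderParams(fieldSize = c(192L, 192L)))
#' mv
#' @export
renderMovie <- function(tree, params = renderParams(), horizon = NULL) {
  stopifnot(is(tree, "LineageTree"), is(params, "RenderParams"))
  validObject(params)
  if (is.null(tree@regime) && nrow(cells(tree)))
    stop("renderMovie needs a simulated tree (with its regime)")
  if (is.null(horizon)) horizon <- tree@duration
  times <- seq(0, horizon, by = params@frameInterval)
  dims <- params@fieldSize
  cl <- cells(tree)
  dv <- divisions(tree)
  pos <- if (nrow(cl)) .layoutTree(tree, params) else data.frame()

  # per-division bud emergence and nuclear onset times
  if (nrow(dv)) {
    prevDiv <- vapply(seq_len(nrow(dv)), function(i) {
      tt <- dv$time[dv$mother_id == dv$mother_id[i] & dv$time < dv$time[i]]
      if (length(tt)) max(tt) else
        cl$birth_time[match(dv$mother_id[i], cl$id)]
    }, numeric(1))
    emergence <- pmax(dv$time - params@budPeriod, prevDiv + 1e-6)
    jitter <- if (params@nuclearOnsetJitter > 0) {
      vapply(dv$daughter_id, function(id)
        .withDrawSeed(params@seed, id, 700001L,
          sample(-params@nuclearOnsetJitter:params@nuclearOnsetJitter, 1)),
        numeric(1)) * params@frameInterval
    } else rep(0, nrow(dv))
    nucOnset <- pmax(dv$time - params@anaphaseOffset + jitter, emergence)
  }
  founderIds <- cl$id[is.na(cl$parent_id)]

  labels <- cyto <- nuclear <- budneck <- vector("list", length(times))
  npx <- prod(dims)
  radCache <- new.env(parent = emptyenv())
  radFor <- function(area) {
    key <- sprintf("%.3f", area)
    r <- radCache[[key]]
    if (is.null(r)) {
      r <- .radiusForArea(area)
      radCache[[key]] <- r
    }
    r
  }
  for (fr in seq_along(times)) {
    t <- times[fr]
    lab <- matrix(0L, dims[1], dims[2])
    cy <- matrix(params@bgLevel, dims[1], dims[2])
    nu <- matrix(params@bgLevel, dims[1], dims[2])
    bn <- matrix(params@bgLevel, dims[1], dims[2])
    if (nrow(cl)) {
      born <- which(cl$birth_time <= t)
      sizes <- if (length(born))
        cellSizeAt(tree, t, cl$id[born]) else numeric()
      for (w in seq_along(born)) {
        i <- born[w]
        r <- radFor(sizes[w] * params@areaScale)
        px <- .discIndex(pos$x[i], pos$y[i], r, dims)
        lab[px] <- cl$id[i]
        cy[px] <- params@cytoLevel
        nucOn <- cl$id[i] %in% founderIds ||
          t >= nucOnset[match(cl$id[i], dv$daughter_id)]
        if (isTRUE(nucOn)) {
          npix <- .discIndex(pos$x[i], pos$y[i], params@nucRadius, dims)
          nu[npix] <- params@nuclearLevel
        }
      }
      if (nrow(dv)) {
        for (e in seq_len(nrow(dv))) {
          if (t < emergence[e] || t > dv$time[e] + 36) next
          di <- match(dv$daughter_id[e], pos$id)
          mi <- match(dv$mother_id[e], pos$id)
          if (t < dv$time[e]) {  # bud phase: growing disc, daughter label
            rF <- radFor(dv$daughter_size[e] * params@areaScale)
            frac <- (t - emergence[e]) / (dv$time[e] - emergence[e])
            r <- max(1.5, rF * frac)
            px <- .discIndex(pos$x[di], pos$y[di], r, dims)
            lab[px] <- dv$daughter_id[e]
            cy[px] <- params@cytoLevel
            if (t >= nucOnset[e]) {
              npix <- .discIndex(pos$x[di], pos$y[di], params@nucRadius,
                                 dims)
              nu[npix] <- params@nuclearLevel
            }
          }
          # bud-neck ring between mother and bud: bright before birth,
          # dropped by the contrast factor for 36 min after it
          dx <- pos$x[di] - pos$x[mi]; dy <- pos$y[di] - pos$y[mi]
          dd <- sqrt(dx^2 + dy^2)
          rm <- radFor(cellSizeAt(tree, t, dv$mother_id[e]) *
                         params@areaScale)
          rd <- radFor(dv$daughter_size[e] * params@areaScale)
          off <- (dd + rm - rd) / 2
          qx <- pos$x[mi] + dx / dd * off
          qy <- pos$y[mi] + dy / dd * off
          val <- if (t < dv$time[e]) params@budneckLevel else
            params@budneckLevel / params@budneckContrast
          bn[.discIndex(qx, qy, params@neckRadius, dims)] <- val
        }
      }
    }
    if (params@noiseSd > 0) {
      cy <- cy + .withDrawSeed(params@seed, fr, 1L,
                               stats::rnorm(npx, 0, params@noiseSd))
      nu <- nu + .withDrawSeed(params@seed, fr, 2L,
                               stats::rnorm(npx, 0, params@noiseSd))
      bn <- bn + .withDrawSeed(params@seed, fr, 3L,
                               stats::rnorm(npx, 0, params@noiseSd))
      cy[cy < 0] <- 0; nu[nu < 0] <- 0; bn[bn < 0] <- 0
    }
    labels[[fr]] <- lab; cyto[[fr]] <- cy
    nuclear[[fr]] <- nu; budneck[[fr]] <- bn
  }
  new("Movie", labels = labels, cyto = cyto, nuclear = nuclear,
      budneck = budneck, times = times, params = params,
      provenance = list(tree_seed = tree@seed, n_cells = nrow(cl),
                        render_seed = params@seed))
}
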