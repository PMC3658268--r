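# Hand-built two-cell movie: a mother (present throughout, nucleated from
# the start) and a neighbouring cell whose nuclear marker switches on at
# `onsetT` and whose shared neck steps down at `dropT` (NA: no drop).
twoCellMovie <- function(onsetT, dropT, horizon = 132, gapPx = 1) {
  p <- renderParams(fieldSize = c(96L, 96L))
  times <- seq(0, horizon, by = p@frameInterval)
  disc <- function(m, cx, cy, r, val) {
    idx <- asymdiv:::.discIndex(cx, cy, r, dim(m))
    m[idx] <- val
    m
  }
  rm <- 9; rd <- 7
  cm <- c(30, 48); cd <- c(30 + rm + rd + gapPx, 48)
  neck <- c(mean(c(cm[1] + rm, cd[1] - rd)), 48)
  labels <- cyto <- nuclear <- budneck <- vector("list", length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    lab <- matrix(0L, 96, 96)
    lab <- disc(lab, cm[1], cm[2], rm, 1L)
    lab <- disc(lab, cd[1], cd[2], rd, 2L)
    cy <- matrix(100, 96, 96)
    cy <- disc(cy, cm[1], cm[2], rm, 500)
    cy <- disc(cy, cd[1], cd[2], rd, 500)
    nu <- matrix(100, 96, 96)
    nu <- disc(nu, cm[1], cm[2], 3, 2000)
    if (t >= onsetT) nu <- disc(nu, cd[1], cd[2], 3, 2000)
    bn <- matrix(100, 96, 96)
    val <- if (!is.na(dropT) && t >= dropT) 200 else 1000
    bn <- disc(bn, neck[1], neck[2], 3, val)
    labels[[k]] <- lab; cyto[[k]] <- cy; nuclear[[k]] <- nu
    budneck[[k]] <- bn
  }
  new("Movie", labels = labels, cyto = cyto, nuclear = nuclear,
      budneck = budneck, times = times, params = p,
      provenance = list())
}

test_that("touching cells with distinct nuclear peaks segment separately", {
  mv <- twoCellMovie(onsetT = 60, dropT = 72, gapPx = -2)  # overlapping
  seg <- segmentFinalFrame(mv)
  expect_equal(length(setdiff(unique(as.vector(seg)), 0L)), 2)
})

test_that("a background-only movie yields no segments and no tracks", {
  p <- renderParams(fieldSize = c(64L, 64L))
  frames <- replicate(5, matrix(100, 64, 64), simplify = FALSE)
  labs <- replicate(5, matrix(0L, 64, 64), simplify = FALSE)
  mv <- new("Movie", labels = labs, cyto = frames, nuclear = frames,
            budneck = frames, times = seq(0, 24, 6), params = p,
            provenance = list())
  seg <- segmentFinalFrame(mv)
  expect_true(all(seg == 0))
})

test_that("event calling pairs nuclear separation with the neck drop in window", {
  mv <- twoCellMovie(onsetT = 60, dropT = 72)
  rec <- reconstructLineage(mv)
  ev <- rec$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$nuclear_separation_time, 60)
  expect_equal(ev$birth_time, 72)
  expect_equal(ev$mother_label, 1)
  tree <- rec$tree
  expect_equal(nCells(tree), 2)
  expect_equal(sum(cells(tree)$n_divisions > 0), 1)
})

test_that("a drop outside the 30 min window leaves the birth unassigned", {
  mv <- twoCellMovie(onsetT = 60, dropT = 96)
  rec <- reconstructLineage(mv)
  ev <- rec$events
  expect_equal(nrow(ev), 1)
  expect_true(is.na(ev$birth_time))
  expect_match(ev$reason, "window")
  # the flagged daughter is not added to the tree
  expect_equal(nCells(rec$tree), 1)
})

test_that("a single non-dividing cell yields one track spanning all frames", {
  reg <- regimeParams("arrest", meanCycleTime = 100, f = 1, preF = 1,
                      regen = 0, preRegen = 0, shiftTime = 0,
                      resourceParams = resourceParams(1, 1, 0.5))
  tr <- simulatePopulation(reg, 1, 120, seed = 1)
  mv <- renderMovie(tr, renderParams(fieldSize = c(96L, 96L)))
  rec <- reconstructLineage(mv)
  expect_equal(nCells(rec$tree), 1)
  tk <- rec$tracks
  expect_equal(sort(unique(tk$frame)), seq_len(nFrames(mv)))
  expect_true(all(tk$area_px > 0))
})

test_that("backwards tracking never invents tracks absent from the final frame", {
  tr <- simulatePopulation(regimePreset("low_metal"), 1, 420, seed = 3)
  mv <- renderMovie(tr, renderParams(fieldSize = c(224L, 224L)))
  seg <- segmentFinalFrame(mv)
  tk <- trackBackwards(mv, seg)
  finalLabels <- setdiff(unique(as.vector(seg)), 0L)
  expect_true(all(tk$tracks$cell_label %in% finalLabels))
})

test_that("noiseless round trip recovers the lineage exactly", {
  tr <- simulatePopulation(regimePreset("low_metal"), 1, 480, seed = 3)
  mv <- renderMovie(tr, renderParams(fieldSize = c(256L, 256L)))
  rec <- reconstructLineage(mv)
  expect_true(treesIsomorphic(tr, rec$tree, tol = 6))
  expect_equal(sum(cells(rec$tree)$n_divisions > 0),
               sum(cells(tr)$n_divisions > 0))
})

test_that("classification stays accurate under strong intensity noise", {
  # noise at 20% of the cytoplasm signal amplitude
  tr <- simulatePopulation(regimePreset("low_metal"), 2, 540, seed = 11)
  mv <- renderMovie(tr, renderParams(fieldSize = c(288L, 288L),
                                     noiseSd = 80, seed = 5))
  rec <- reconstructLineage(mv)
  expect_equal(nCells(rec$tree), nCells(tr))
  expect_true(treesIsomorphic(tr, rec$tree, tol = 6, checkClass = FALSE))
  recMothers <- sum(cells(rec$tree)$n_divisions > 0)
  trueMothers <- sum(cells(tr)$n_divisions > 0)
  expect_gte(1 - abs(recMothers - trueMothers) / nCells(tr), 0.95)
})
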