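# A tiny deterministic tree: one founder dividing twice.
smallTree <- function(duration = 300) {
  simulatePopulation(regimePreset("low_metal", cycleCV = 0), 1, duration,
                     seed = 2)
}

test_that("an empty tree renders as background-only frames", {
  tr <- simulatePopulation(regimePreset("rich"), 0, 60, seed = 1)
  mv <- renderMovie(tr, renderParams(fieldSize = c(64L, 64L)))
  expect_equal(nFrames(mv), 11)
  for (k in seq_len(nFrames(mv))) {
    expect_true(all(mv@labels[[k]] == 0))
    expect_true(all(mv@cyto[[k]] == 100))
  }
})

test_that("rendering is reproducible and sensitive to the noise seed", {
  tr <- smallTree()
  p <- renderParams(fieldSize = c(128L, 128L), noiseSd = 30, seed = 7)
  a <- renderMovie(tr, p)
  b <- renderMovie(tr, p)
  expect_identical(a@cyto, b@cyto)
  expect_identical(a@nuclear, b@nuclear)
  expect_identical(a@labels, b@labels)
  c <- renderMovie(tr, renderParams(fieldSize = c(128L, 128L),
                                    noiseSd = 30, seed = 8))
  expect_false(identical(a@cyto, c@cyto))
})

test_that("labelled areas track cell size within rasterization tolerance", {
  tr <- smallTree(400)
  p <- renderParams(fieldSize = c(160L, 160L))
  mv <- renderMovie(tr, p)
  cl <- cells(tr)
  for (k in seq(5, nFrames(mv), by = 10)) {
    t <- mv@times[k]
    lab <- mv@labels[[k]]
    for (i in which(cl$birth_time <= t)) {
      px <- sum(lab == cl$id[i])
      expected <- cellSizeAt(tr, t, cl$id[i]) * p@areaScale
      expect_lt(abs(px - expected) / expected, 0.05)
    }
  }
})

test_that("the bud-neck trace steps down at birth and the nucleus appears at onset", {
  tr <- smallTree()
  dv <- divisions(tr)
  p <- renderParams(fieldSize = c(160L, 160L))
  mv <- renderMovie(tr, p)
  e <- dv[1, ]
  birthFrame <- findInterval(e$time, mv@times)
  onsetFrame <- findInterval(e$time - p@anaphaseOffset, mv@times)
  d <- e$daughter_id
  # nuclear signal of the daughter's label: absent before onset, on after
  nucAmount <- vapply(seq_len(nFrames(mv)), function(k)
    sum(mv@nuclear[[k]][mv@labels[[k]] == d] > 1000), numeric(1))
  expect_equal(sum(nucAmount[seq_len(onsetFrame - 1)]), 0)
  expect_gt(nucAmount[onsetFrame + 1], 0)
  # bud-neck: bright in the frame before birth, dropped by >= contrast after
  before <- max(mv@budneck[[birthFrame]])
  after <- max(mv@budneck[[birthFrame + 2]])
  expect_gte(before / after, p@budneckContrast - 1e-9)
})

test_that("an overcrowded field raises an error naming the frame", {
  tr <- simulatePopulation(regimePreset("rich"), 1, 600, seed = 3)
  expect_error(renderMovie(tr, renderParams(fieldSize = c(48L, 48L))),
               "overcrowded.*frame")
})
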