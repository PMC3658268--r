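test_that("exponential fit is exact on model-generated series", {
  d <- data.frame(time_min = seq(0, 600, 6))
  d$total <- 4 * 2^(d$time_min / 103)
  f <- fitExponential(d)
  expect_equal(f@tau, 103, tolerance = 1e-9)
  expect_equal(f@r2, 1, tolerance = 1e-9)
})

test_that("constant and zero-contaminated series are flagged", {
  d <- data.frame(time_min = seq(0, 120, 6), total = 7)
  f <- fitExponential(d)
  expect_true(is.na(f@tau))
  expect_true("nonpositive-slope" %in% f@flags)
  d$total[1:3] <- 0
  f <- fitExponential(d)
  expect_true("zero-counts-dropped" %in% f@flags)
  expect_equal(f@window[1], d$time_min[4])
  d$total <- 0
  expect_error(fitExponential(d), "positive samples")
})

test_that("linear fit is exact on a linear series and windows automatically", {
  d <- data.frame(time_min = seq(0, 600, 6))
  d$total <- 10 + 0.2 * d$time_min
  f <- fitLinear(d)
  expect_equal(f@rate, 0.2, tolerance = 1e-9)
  expect_equal(f@r2, 1, tolerance = 1e-9)
  # flat early phase then linear rise: auto window should find the rise
  d2 <- d
  d2$total <- c(rep(10, 40), 10 + 0.5 * (d$time_min[-(1:40)] - d$time_min[41]))
  fa <- fitLinear(d2, autoWindow = TRUE, shiftTime = 0,
                  transitionExclude = 0)
  expect_gt(fa@rate, 0.4)
  expect_gte(fa@r2, 0.98)
})

test_that("growth-mode classification separates the two laws", {
  d <- data.frame(time_min = seq(0, 600, 6))
  dExp <- transform(d, total = round(4 * 2^(time_min / 103)))
  dLin <- transform(d, total = round(10 + 0.3 * time_min))
  dExp$mothers <- dExp$daughters <- dExp$imploded <- 0
  expect_equal(classifyGrowthMode(dExp), "exponential")
  expect_equal(classifyGrowthMode(dLin), "linear")
  flat <- data.frame(time_min = seq(0, 42, 6), total = 5)
  expect_equal(classifyGrowthMode(flat), "ambiguous")
  expect_error(classifyGrowthMode(flat[1:5, ]), "at least 8")
})

test_that("an exponential series fits poorly under the linear model", {
  d <- data.frame(time_min = seq(0, 600, 6))
  d$total <- 4 * 2^(d$time_min / 103)
  expect_lt(fitLinear(d)@r2, fitExponential(d)@r2)
})

test_that("interdivision statistics recover per-mother cycle times", {
  cl <- data.frame(id = 1:4, parent_id = c(NA, 1L, 1L, 1L),
                   birth_time = c(0, 120, 240, 360))
  dv <- data.frame(mother_id = rep(1L, 3), daughter_id = 2:4,
                   time = c(120, 240, 360))
  tr <- lineageTree(cl, dv, duration = 400)
  st <- interdivisionStats(tr, postShiftOnly = FALSE)
  cyc <- attr(st, "cycles")
  expect_equal(cyc$cycle_min, c(120, 120))
  expect_equal(st$mean_min, c(120, 120))
})

test_that("low-metal interdivision times stay near the regime mean across ranks", {
  tr <- simulatePopulation(regimePreset("low_metal"), 12, 1700, seed = 21)
  st <- interdivisionStats(tr)
  big <- st[st$n >= 10, ]
  expect_gt(nrow(big), 3)
  expect_true(all(abs(big$mean_min - 120) / 120 < 0.1))
})

test_that("size gap is zero when all cells share one size", {
  cl <- data.frame(id = 1:8, parent_id = c(NA, NA, NA, NA, 1L, 2L, 3L, 4L),
                   birth_time = c(0, 0, 0, 0, 100, 100, 100, 100))
  dv <- data.frame(mother_id = 1:4, daughter_id = 5:8, time = rep(100, 4))
  tr <- lineageTree(cl, dv, duration = 300)
  tr@tracks <- data.frame(cell_label = rep(1:8, each = 2),
                          frame = rep(1:2, 8),
                          time_min = rep(c(0, 300), 8),
                          size = 1)
  sd0 <- sizeDistributions(tr, 200)
  expect_equal(sd0$gap, 0)
})

test_that("age correction removes the age-driven size component", {
  # mothers and daughters share one growth law; daughters are just younger
  reg <- regimePreset("rich")
  cl <- data.frame(id = 1:6, parent_id = c(NA, NA, NA, 1L, 2L, 3L),
                   birth_time = c(0, 0, 0, 400, 400, 400),
                   size_birth = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                   growth_start = c(0, 0, 0, 400, 400, 400))
  dv <- data.frame(mother_id = 1:3, daughter_id = 4:6, time = rep(400, 3))
  tr <- lineageTree(cl, dv, regime = reg, duration = 500)
  raw <- sizeDistributions(tr, 410, ageCorrect = FALSE)
  corrected <- sizeDistributions(tr, 410, ageCorrect = TRUE)
  expect_gt(raw$gap, 0)
  expect_equal(corrected$gap, 0, tolerance = 1e-9)
  few <- sizeDistributions(tr, 100)   # no daughters born yet
  expect_true(is.na(few$gap))
  expect_match(few$flag, "fewer")
})

test_that("vacuole fractions recover the partition parameter in every regime", {
  for (name in c("rich", "low_metal", "whi5", "vac17")) {
    reg <- regimePreset(name)
    tr <- simulatePopulation(reg, 4, 900, seed = 17)
    vf <- vacuoleFraction(tr)
    ev <- vf$events
    pre <- ev[ev$time < reg@shiftTime, ]
    post <- ev[ev$time >= reg@shiftTime, ]
    if (nrow(pre))
      expect_true(all(abs(pre$mother_fraction - reg@preF) < 0.02))
    if (nrow(post))
      expect_true(all(abs(post$mother_fraction - reg@f) < 0.02))
    expect_equal(ev$mother_fraction + ev$daughter_fraction,
                 rep(1, nrow(ev)), tolerance = 1e-12)
  }
})

test_that("stress survival tallies are empty without stress and sound with it", {
  tr <- simulatePopulation(regimePreset("low_metal"), 3, 900, seed = 4)
  out <- stressSurvival(tr)
  expect_true(all(out$n_exposed == 0))
  st <- applyStress(tr, stressPreset("rapamycin", start = 800), seed = 9)
  out <- stressSurvival(st)
  expect_equal(out$n_exposed, unname(table(cells(st)$exposed_class)[
    c("mother", "daughter")]), ignore_attr = TRUE)
  expect_true(all(out$n_imploded + out$n_recovered <= out$n_exposed))
  expect_equal(out$implosion_fraction, out$n_imploded / out$n_exposed)
})

test_that("rapamycin hits mothers harder; daughters recover more", {
  tr <- makeStressPopulation(200, 200)
  st <- applyStress(tr, stressPreset("rapamycin", start = 300), seed = 2)
  out <- stressSurvival(st)
  m <- out[out$class == "mother", ]
  d <- out[out$class == "daughter", ]
  expect_gt(m$implosion_fraction, d$implosion_fraction)
  expect_gt(d$n_recovered, m$n_recovered)
})
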