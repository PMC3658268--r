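test_that("degenerate inputs are handled: empty populations and bad arguments", {
  reg <- regimePreset("rich")
  tr <- simulatePopulation(reg, 0, 600, seed = 1)
  expect_equal(nCells(tr), 0)
  expect_equal(nrow(divisions(tr)), 0)
  expect_error(simulatePopulation(reg, -1, 600), "non-negative")
  expect_error(simulatePopulation(reg, 1, -5), "non-negative")
})

test_that("identical seed and regime give bit-identical trees", {
  reg <- regimePreset("low_metal")
  a <- simulatePopulation(reg, 3, 900, seed = 99)
  b <- simulatePopulation(reg, 3, 900, seed = 99)
  expect_identical(cells(a), cells(b))
  expect_identical(divisions(a), divisions(b))
  c <- simulatePopulation(reg, 3, 900, seed = 100)
  expect_false(identical(divisions(a), divisions(c)))
})

test_that("extending the duration preserves the earlier history", {
  reg <- regimePreset("low_metal")
  short <- simulatePopulation(reg, 2, 600, seed = 5)
  long <- simulatePopulation(reg, 2, 900, seed = 5)
  dvS <- divisions(short)
  dvL <- divisions(long)
  expect_equal(dvS$time,
               dvL$time[dvL$time <= 600])
  clS <- cells(short)
  clL <- cells(long)
  shared <- intersect(clS$id, clL$id)
  expect_equal(clS$birth_time[match(shared, clS$id)],
               clL$birth_time[match(shared, clL$id)])
})

test_that("resource is conserved at every unclipped division", {
  for (name in c("rich", "low_metal", "whi5")) {
    tr <- simulatePopulation(regimePreset(name), 2, 800, seed = 3)
    dv <- divisions(tr)
    dv <- dv[!dv$clipped, ]
    dz <- regime(tr)@resourceParams@dz
    lhs <- dv$mother_resource_after + dv$daughter_resource + dz
    expect_equal(lhs, dv$mother_resource_before, tolerance = 1e-9)
  }
})

test_that("full retention reproduces the closed-form division capacity", {
  # f = 1, no regeneration: every founder divides floor((Z0-Zc)/dz) times
  reg <- regimePreset("vac17", cycleCV = 0.1)
  rp <- reg@resourceParams
  nExpect <- floor((rp@z0 - rp@zc) / rp@dz)
  expect_equal(nExpect, bruteAsymmetricDivisions(rp@z0, rp@zc, rp@dz))
  tr <- simulatePopulation(reg, 4, 4000, seed = 8)
  cl <- cells(tr)
  dv <- divisions(tr)
  for (f in cl$id[is.na(cl$parent_id)])
    expect_equal(sum(dv$mother_id == f), nExpect)
  # post-shift daughters receive nothing and never divide
  post <- cl[!is.na(cl$parent_id), ]
  expect_true(all(post$n_divisions == 0))
  expect_true(all(post$status == "arrested"))
})

test_that("symmetric no-loss partitioning reaches floor(log2(Z0/Zc)) generations", {
  reg <- regimeParams("sym_test", meanCycleTime = 100, cycleCV = 0.05,
                      f = 0.5, preF = 0.5, regen = 0, preRegen = 0,
                      shiftTime = 0,
                      resourceParams = resourceParams(10, 1, 0))
  tr <- simulatePopulation(reg, 1, 1500, seed = 2)
  cl <- cells(tr)
  mothers <- cl$generation[cl$n_divisions > 0]
  expect_equal(max(mothers), floor(log2(10 / 1)))
})

test_that("count series match brute-force enumeration", {
  tr <- simulatePopulation(regimePreset("low_metal"), 3, 900, seed = 4)
  tr <- applyStress(tr, stressPreset("osmotic", start = 800), seed = 1)
  cs <- counts(countSeries(tr, interval = 30))
  for (i in seq_len(nrow(cs))) {
    ref <- bruteCountsAt(tr, cs$time_min[i])
    expect_equal(cs$total[i], unname(ref["total"]))
    expect_equal(cs$mothers[i], unname(ref["mothers"]))
    expect_equal(cs$daughters[i], unname(ref["daughters"]))
    expect_equal(cs$imploded[i], unname(ref["imploded"]))
  }
})

test_that("a never-dividing cell gives a constant count of one", {
  reg <- regimeParams("arrest", meanCycleTime = 100,
                      f = 1, preF = 1, regen = 0, preRegen = 0,
                      shiftTime = 0,
                      resourceParams = resourceParams(1, 1, 0.5))
  tr <- simulatePopulation(reg, 1, 300, seed = 1)
  expect_equal(nrow(divisions(tr)), 0)
  cs <- counts(countSeries(tr))
  expect_true(all(cs$total == 1))
  expect_true(all(cs$mothers == 0))
})

test_that("daughters born after the shift arrest while earlier cells divide", {
  tr <- simulatePopulation(regimePreset("low_metal"), 5, 1200, seed = 6)
  cl <- cells(tr)
  lateBorn <- cl[cl$birth_time > regime(tr)@shiftTime, ]
  expect_gt(nrow(lateBorn), 20)
  expect_true(all(lateBorn$n_divisions == 0))
  expect_true(all(lateBorn$resource_birth <
                    regime(tr)@resourceParams@zc))
  preBorn <- cl[cl$birth_time < regime(tr)@shiftTime, ]
  expect_true(all(preBorn$n_divisions > 0))
})

test_that("stress with extreme probabilities behaves deterministically", {
  tr <- simulatePopulation(regimePreset("low_metal"), 3, 900, seed = 4)
  none <- applyStress(tr, stressParams("osmotic", 800, 60,
                                       pImplodeMother = 0,
                                       pImplodeDaughter = 0), seed = 1)
  expect_identical(cells(none)$status, cells(tr)$status)
  all <- applyStress(tr, stressParams("osmotic", 800, 60,
                                      pImplodeMother = 1,
                                      pImplodeDaughter = 1), seed = 1)
  exposed <- cells(all)$birth_time <= 800
  expect_true(all(cells(all)$status[exposed] == "imploded"))
  expect_error(stressParams("osmotic", 800, 60, pImplodeMother = 1.2),
               "probability")
  expect_error(applyStress(tr, stressPreset("osmotic", start = 2000), 1),
               "within the simulated span")
})

test_that("recoverable stresses assign class-specific recovery delays", {
  tr <- makeStressPopulation(50, 50)
  st <- applyStress(tr, stressPreset("zinc_shock", start = 500,
                                     duration = 60), seed = 3)
  cl <- cells(st)
  surv <- cl[!is.na(cl$recovery_time), ]
  expect_gt(nrow(surv), 0)
  mRec <- surv$recovery_time[surv$exposed_class == "mother"]
  dRec <- surv$recovery_time[surv$exposed_class == "daughter"]
  # daughters recover only after a long delay
  expect_true(all(dRec - mRec[1] == 240))
})
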