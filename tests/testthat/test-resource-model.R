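test_that("symmetric capacity matches closed form and brute-force halving", {
  r <- symmetricCapacity(resourceParams(16, 1))
  expect_equal(r@ns, 16)
  expect_equal(r@cyclesSymmetric, 4)
  expect_equal(r@cellsSymmetricDiscrete, 16)

  r <- symmetricCapacity(resourceParams(5, 5))
  expect_equal(r@ns, 1)
  expect_equal(r@cyclesSymmetric, 0)
  expect_equal(r@cellsSymmetricDiscrete, 1)

  # 10 -> 5 -> 2.5 stops below 3 after one feasible halving
  r <- symmetricCapacity(resourceParams(10, 3))
  expect_equal(r@ns, 10 / 3)
  expect_equal(r@cyclesSymmetric, bruteSymmetricCycles(10, 3))
  expect_equal(r@cyclesSymmetric, 1)
  expect_equal(r@cellsSymmetricDiscrete, 2)
})

test_that("asymmetric capacity handles finite loss and the unbounded case", {
  expect_equal(asymmetricCapacity(resourceParams(16, 1, 1))@nas, 15)
  expect_equal(asymmetricCapacity(resourceParams(5, 5, 0.5))@nas, 0)
  r <- asymmetricCapacity(resourceParams(16, 1, 0))
  expect_true(r@unbounded)
  expect_identical(r@nas, Inf)
})

test_that("invalid resource parameters raise domain errors naming the bound", {
  expect_error(resourceParams(16, 0, 1), "zc must be > 0")
  expect_error(resourceParams(1, 2, 1), "z0 must be >= zc")
  expect_error(resourceParams(16, 1, -1), "dz must be >= 0")
  expect_error(preferredStrategy(resourceParams(16, 1, 0)), "deltaZ > 0")
})

test_that("preferred strategy compares the continuous capacities", {
  expect_equal(preferredStrategy(resourceParams(16, 1, 0.1)), "asymmetric")
  expect_equal(preferredStrategy(resourceParams(16, 1, 1)), "symmetric")
  # Ns = Nas = 2 exactly
  expect_equal(preferredStrategy(resourceParams(2, 1, 0.5)), "tie")
})

test_that("capacities agree with brute-force depletion over random parameters", {
  set.seed(42)
  for (i in seq_len(200)) {
    zc <- runif(1, 0.1, 5)
    z0 <- zc * runif(1, 1, 50)
    dz <- runif(1, 0.05, 3)
    p <- resourceParams(z0, zc, dz)
    expect_equal(symmetricCapacity(p)@cyclesSymmetric,
                 bruteSymmetricCycles(z0, zc))
    expect_equal(floor(asymmetricCapacity(p)@nas + 1e-12),
                 bruteAsymmetricDivisions(z0, zc, dz))
  }
})

test_that("capacities are monotone in the expected directions", {
  zc <- 1
  nasAt <- function(dz) asymmetricCapacity(resourceParams(16, zc, dz))@nas
  dzs <- c(0.1, 0.5, 1, 2, 4)
  expect_true(all(diff(vapply(dzs, nasAt, numeric(1))) < 0))
  z0s <- c(2, 4, 8, 16, 32)
  ns <- vapply(z0s, function(z) symmetricCapacity(
    resourceParams(z, zc))@ns, numeric(1))
  nas <- vapply(z0s, function(z) asymmetricCapacity(
    resourceParams(z, zc, 0.5))@nas, numeric(1))
  expect_true(all(diff(ns) > 0))
  expect_true(all(diff(nas) > 0))
})

test_that("the strategy flips at the predicted per-division loss", {
  z0 <- 16; zc <- 1
  dzCross <- (z0 - zc) / (z0 / zc)   # Nas = Ns at this loss
  expect_equal(preferredStrategy(resourceParams(z0, zc, dzCross * 0.9)),
               "asymmetric")
  expect_equal(preferredStrategy(resourceParams(z0, zc, dzCross * 1.1)),
               "symmetric")
  expect_equal(preferredStrategy(resourceParams(z0, zc, dzCross)), "tie")
})

test_that("capacityTable evaluates the grid", {
  tb <- capacityTable(z0 = c(8, 16), zc = 1, dz = c(0.1, 1))
  expect_equal(nrow(tb), 4)
  expect_equal(tb$ns, c(8, 16, 8, 16))
  expect_equal(tb$strategy[tb$z0 == 16 & tb$dz == 0.1], "asymmetric")
})
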