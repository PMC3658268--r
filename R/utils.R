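# Internal numerics shared across modules.

# Deterministic per-(cell, draw) seeding: every random draw in a simulation
# is keyed by (master seed, cell id, draw index), so extending a run or
# adding cells never perturbs draws already taken by existing cells.
.drawSeed <- function(seed, id, k) {
  s <- (abs(seed) + id * 1000003 + k * 10007) %% 2147483629
  as.integer(s)
}

.withDrawSeed <- function(seed, id, k, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(.drawSeed(seed, id, k))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Lognormal with a given mean and coefficient of variation; guarantees
# positive cycle times.
.rlnormMeanCV <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Coefficient of determination on the fitted scale; 0 when the response is
# constant (no variance to explain).
.rsq <- function(obs, fitted) {
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) return(0)
  1 - sum((obs - fitted)^2) / sstot
}

.assertCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(name, " must be a single non-negative integer")
  as.integer(x)
}
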