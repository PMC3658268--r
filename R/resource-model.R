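#' Closed-form division capacity under symmetric partitioning
#'
#' When a non-replenishable resource is halved at every division, the pool
#' of each descendant after k cycles is \code{z0/2^k}. Division stops once
#' the pool would fall below the critical level \code{zc}, after
#' \code{floor(log2(z0/zc))} cycles, and the population can grow at most by
#' the continuous factor \code{Ns = z0/zc}.
#'
#' @param params a \code{\link{ResourceParams}}.
#' @return a \code{\link{CapacityResult}} with \code{ns},
#'   \code{cyclesSymmetric} and \code{cellsSymmetricDiscrete} populated.
#' @examples
#' symmetricCapacity(resourceParams(z0 = 16, zc = 1))
#' @seealso \code{\link{asymmetricCapacity}}, \code{\link{preferredStrategy}}
#' @export
symmetricCapacity <- function(params) {
  stopifnot(is(params, "ResourceParams"))
  validObject(params)
  ns <- params@z0 / params@zc
  cycles <- floor(log2(ns))
  # guard against floating point: 2^(cycles+1) might still be feasible
  while (params@z0 / 2^(cycles + 1) >= params@zc) cycles <- cycles + 1
  while (cycles > 0 && params@z0 / 2^cycles < params@zc) cycles <- cycles - 1
  new("CapacityResult", ns = ns, cyclesSymmetric = cycles,
      cellsSymmetricDiscrete = 2^cycles)
}

#' Progeny capacity under full asymmetric retention
#'
#' If the progenitor retains the whole pool and loses \code{dz} at each
#' division, it can produce \code{Nas = (z0 - zc)/dz} daughters before the
#' pool reaches the critical level. With \code{dz = 0} nothing is lost and
#' division can proceed indefinitely (\code{unbounded}).
#'
#' @param params a \code{\link{ResourceParams}}.
#' @return a \code{\link{CapacityResult}} with \code{nas} (and
#'   \code{unbounded}) populated; \code{nas} is \code{Inf} in the
#'   unbounded case.
#' @examples
#' asymmetricCapacity(resourceParams(z0 = 16, zc = 1, dz = 1))
#' asymmetricCapacity(resourceParams(z0 = 16, zc = 1, dz = 0))
#' @export
asymmetricCapacity <- function(params) {
  stopifnot(is(params, "ResourceParams"))
  validObject(params)
  if (params@dz == 0) {
    new("CapacityResult", nas = Inf, unbounded = TRUE)
  } else {
    new("CapacityResult", nas = (params@z0 - params@zc) / params@dz)
  }
}

#' Which partitioning strategy yields the larger population?
#'
#' Compares the continuous capacities \code{Ns = z0/zc} (symmetric) and
#' \code{Nas = (z0 - zc)/dz} (asymmetric). Asymmetric retention wins when
#' the per-division loss is small relative to the critical level.
#'
#' @param params a \code{\link{ResourceParams}} with \code{dz > 0}.
#' @param tol relative tolerance under which the two capacities are
#'   declared equal.
#' @return \code{"symmetric"}, \code{"asymmetric"} or \code{"tie"}.
#' @examples
#' preferredStrategy(resourceParams(16, 1, dz = 0.1)) # asymmetric
#' preferredStrategy(resourceParams(16, 1, dz = 1))   # symmetric
#' @export
preferredStrategy <- function(params, tol = 1e-9) {
  stopifnot(is(params, "ResourceParams"))
  validObject(params)
  if (params@dz <= 0)
    stop("preferredStrategy requires deltaZ > 0 (with no loss the ",
         "asymmetric strategy is unbounded)")
  ns <- params@z0 / params@zc
  nas <- (params@z0 - params@zc) / params@dz
  if (abs(nas - ns) <= tol * max(abs(ns), abs(nas), 1)) return("tie")
  if (nas > ns) "asymmetric" else "symmetric"
}

#' Capacity table over a parameter grid
#'
#' Evaluates both capacities and the preferred strategy over the cartesian
#' grid of the supplied parameter vectors.
#'
#' @param z0,zc,dz numeric vectors of model parameters.
#' @return data.frame with one row per combination and columns \code{z0},
#'   \code{zc}, \code{dz}, \code{ns}, \code{cycles}, \code{cells_discrete},
#'   \code{nas}, \code{strategy}.
#' @examples
#' capacityTable(z0 = c(8, 16), zc = 1, dz = c(0.1, 1))
#' @export
capacityTable <- function(z0, zc, dz) {
  grid <- expand.grid(z0 = z0, zc = zc, dz = dz, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- resourceParams(grid$z0[i], grid$zc[i], grid$dz[i])
    s <- symmetricCapacity(p)
    a <- asymmetricCapacity(p)
    strat <- if (p@dz > 0) preferredStrategy(p) else "asymmetric"
    data.frame(z0 = p@z0, zc = p@zc, dz = p@dz, ns = s@ns,
               cycles = s@cyclesSymmetric,
               cells_discrete = s@cellsSymmetricDiscrete,
               nas = a@nas, strategy = strat)
  })
  do.call(rbind, res)
}
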