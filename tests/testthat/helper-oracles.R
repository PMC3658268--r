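# Independent brute-force oracles and tree-comparison helpers.

# Halve a single pool until it falls below zc; returns the number of
# feasible symmetric cycles.
bruteSymmetricCycles <- function(z0, zc) {
  pool <- z0
  cycles <- 0L
  while (pool / 2 >= zc) {
    pool <- pool / 2
    cycles <- cycles + 1L
  }
  cycles
}

# Retain the whole pool, subtract dz per division while the retained pool
# stays at or above zc; returns the number of feasible divisions.
bruteAsymmetricDivisions <- function(z0, zc, dz) {
  pool <- z0
  n <- 0L
  while (pool - dz >= zc - 1e-12) {
    pool <- pool - dz
    n <- n + 1L
    if (n > 1e6) stop("runaway brute force")
  }
  n
}

# Brute-force per-class population counts at a single time.
bruteCountsAt <- function(tree, t) {
  cl <- cells(tree)
  dv <- divisions(tree)
  impl <- ifelse(is.na(cl$implosion_time), Inf, cl$implosion_time)
  present <- cl$birth_time <= t & impl > t
  nm <- 0L
  for (i in which(present)) {
    if (sum(dv$mother_id == cl$id[i] & dv$time <= t) >= 1) nm <- nm + 1L
  }
  c(total = sum(present), mothers = nm,
    daughters = sum(present) - nm, imploded = sum(impl <= t))
}

# Recursive ordered comparison of two lineage trees: identical topology,
# matching birth times within `tol`, and (optionally) matching
# mother/daughter classification. Children are matched in birth order.
treesIsomorphic <- function(a, b, tol = 6, checkClass = TRUE) {
  ca <- cells(a); da <- divisions(a)
  cb <- cells(b); db <- divisions(b)
  if (nrow(ca) != nrow(cb)) return(FALSE)
  childrenOf <- function(dv, id) {
    ch <- dv[dv$mother_id == id, , drop = FALSE]
    ch[order(ch$time), "daughter_id"]
  }
  cmp <- function(ia, ib) {
    ra <- ca[match(ia, ca$id), ]
    rb <- cb[match(ib, cb$id), ]
    if (abs(ra$birth_time - rb$birth_time) > tol) return(FALSE)
    if (checkClass && (ra$n_divisions > 0) != (rb$n_divisions > 0))
      return(FALSE)
    cha <- childrenOf(da, ia)
    chb <- childrenOf(db, ib)
    if (length(cha) != length(chb)) return(FALSE)
    all(vapply(seq_along(cha), function(k) cmp(cha[k], chb[k]), logical(1)))
  }
  fa <- ca$id[is.na(ca$parent_id)]
  fb <- cb$id[is.na(cb$parent_id)]
  if (length(fa) != length(fb)) return(FALSE)
  fa <- fa[order(ca$birth_time[match(fa, ca$id)], fa)]
  # founders all start at t = 0; match them greedily by subtree
  used <- logical(length(fb))
  for (ia in fa) {
    hit <- FALSE
    for (j in seq_along(fb)) {
      if (!used[j] && cmp(ia, fb[j])) {
        used[j] <- TRUE
        hit <- TRUE
        break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# A hand-built population of founders that each divided once: nM mothers
# with one arrested daughter each, plus standalone arrested daughters so
# classes can be balanced at will.
makeStressPopulation <- function(nMothers, nDaughters, divTime = 100,
                                 duration = 600) {
  ids <- seq_len(nMothers * 2)
  cl <- data.frame(
    id = ids,
    parent_id = c(rep(NA_integer_, nMothers), seq_len(nMothers)),
    birth_time = c(rep(0, nMothers), rep(divTime, nMothers)))
  dv <- data.frame(mother_id = seq_len(nMothers),
                   daughter_id = nMothers + seq_len(nMothers),
                   time = rep(divTime, nMothers))
  extra <- nDaughters - nMothers
  if (extra > 0) {
    cl2 <- data.frame(id = max(ids) + seq_len(extra),
                      parent_id = NA_integer_,
                      birth_time = rep(0, extra))
    cl <- rbind(cl, cl2)
  }
  lineageTree(cl, dv, duration = duration)
}
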