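# Loop-explicit reference implementation of the two-stage multi-read
# assignment: unique-informed initial split, then EM reassignment
# proportional to length-normalized totals with below-one-count zeroing and
# the >=10-count / <1% auto-convergence rule. Written scalar-by-scalar and
# independent of the package internals; used as the equivalence oracle.

refAssign <- function(inst, iterations = "auto", maxIter = 100,
                      zeroing = "per-step") {
  C_U <- inst$C_U; L_U <- inst$L_U
  C_fixed <- inst$C_fixed; l <- inst$l
  frags <- inst$frags

  fr <- list()
  for (fid in names(frags)) {
    cand <- frags[[fid]]
    N <- length(cand)
    n0 <- 0
    for (k in cand) if (C_U[[k]] == 0) n0 <- n0 + 1
    wsum <- 0
    for (k in cand) if (C_U[[k]] > 0) wsum <- wsum + C_U[[k]] / L_U[[k]]
    f <- stats::setNames(numeric(N), cand)
    for (k in cand) {
      f[[k]] <- if (C_U[[k]] == 0) 1 / N
                else (1 - n0 / N) * (C_U[[k]] / L_U[[k]]) / wsum
    }
    fr[[fid]] <- f
  }

  totals <- function(fr) {
    C <- C_fixed
    for (fid in names(fr))
      for (k in names(fr[[fid]]))
        C[[k]] <- C[[k]] + fr[[fid]][[k]]
    C
  }
  estep <- function(fr, C, zero) {
    for (fid in names(fr)) {
      cand <- names(fr[[fid]])
      w <- stats::setNames(numeric(length(cand)), cand)
      for (k in cand) {
        eligible <- if (zero) C[[k]] >= 1 else TRUE
        w[[k]] <- if (eligible) C[[k]] / l[[k]] else 0
      }
      if (sum(w) > 0) fr[[fid]] <- w / sum(w)
      else fr[[fid]][] <- 1 / length(cand)
    }
    fr
  }

  C <- totals(fr)
  initC <- C
  it <- 0
  auto <- identical(iterations, "auto")
  while ((auto && it < maxIter) || (!auto && it < iterations)) {
    Cprev <- C
    fr <- estep(fr, C, zero = identical(zeroing, "per-step"))
    C <- totals(fr)
    it <- it + 1
    if (auto) {
      settled <- TRUE
      for (k in inst$keys) {
        if (Cprev[[k]] >= 10 &&
            abs(C[[k]] - Cprev[[k]]) / max(Cprev[[k]], 1) >= 0.01)
          settled <- FALSE
      }
      if (settled) break
    }
  }
  if (identical(zeroing, "final") && it > 0) {
    fr <- estep(fr, C, TRUE)
    C <- totals(fr)
  }
  list(C = C, initC = initC, fr = fr, nIter = it)
}
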