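# Independent brute-force LP oracle: enumerates basic solutions (vertices)
# of {S v = 0, lb <= v <= ub} directly from the model, with no shared code
# with solve_lp(). Only usable for small models (<= ~10 reactions).
oracle_lp <- function(model, objective_id, sense = "max", big_bound = 1e6,
                      tol = 1e-7) {
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  lb[!is.finite(lb)] <- -big_bound
  ub[!is.finite(ub)] <- big_bound
  n <- ncol(S)
  j_obj <- match(objective_id, colnames(S))
  r <- qr(S)$rank
  better <- if (sense == "max") `>` else `<`
  best <- NA_real_

  consider <- function(v) {
    if (max(abs(S %*% v)) > tol) return()
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    obj <- v[j_obj]
    if (is.na(best) || better(obj, best)) best <<- obj
  }

  if (r == n) {
    consider(rep(0, n))  # only v = 0 solves S v = 0 with full column rank
  } else {
    basics <- utils::combn(n, r)
    nf <- n - r
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nf)))
    for (k in seq_len(ncol(basics))) {
      B <- basics[, k]
      SB <- S[, B, drop = FALSE]
      qB <- qr(SB)
      if (qB$rank < r) next
      N <- setdiff(seq_len(n), B)
      for (g in seq_len(nrow(grid))) {
        v <- numeric(n)
        v[N] <- ifelse(grid[g, ], ub[N], lb[N])
        rhs <- -S[, N, drop = FALSE] %*% v[N]
        vB <- qr.coef(qB, rhs)
        if (anyNA(vB)) next
        if (max(abs(SB %*% vB - rhs)) > tol) next
        v[B] <- vB
        consider(v)
      }
    }
  }
  best  # NA means infeasible
}

# random toy-class model spec, reproducible under the given seed
random_toy_spec <- function(seed, n_aa = NULL) {
  withr::with_seed(seed, {
    if (is.null(n_aa)) n_aa <- sample(2:5, 1L)
    codes <- LETTERS[seq_len(n_aa)]
    toy_model_spec(
      yields = stats::setNames(runif(n_aa, 0.3, 3), codes),
      biomass_composition = stats::setNames(runif(n_aa, 0.2, 2), codes),
      substrate_uptake = runif(1, 5, 20))
  })
}

# random residue-frequency vector over a toy alphabet
random_freq <- function(codes, seed) {
  withr::with_seed(seed, {
    f <- stats::rgamma(length(codes), 1)
    stats::setNames(f / sum(f), codes)
  })
}
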