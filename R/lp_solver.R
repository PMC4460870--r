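# Bounded-variable primal simplex with Bland's anti-cycling rule.
#
# Solves  max c'x  subject to  A x = b, 0 <= x <= u  (u may be Inf).
# Flux-balance problems are highly degenerate (every equality has zero
# right-hand side after the bound shift), so the implementation uses a
# two-phase scheme in which phase-1 artificial variables are simply frozen
# at zero for phase 2 — redundant mass-balance rows then never require a
# basis repair — and Bland's rule guarantees termination under the
# degenerate pivots this produces.
bounded_simplex <- function(cc, A, b, u, eps = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(u) == n, all(u >= -eps))

  # make b >= 0 so the artificial basis is feasible
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  Ax <- cbind(A, diag(m))
  ux <- c(u, rep(Inf, m))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)   # nonbasic state; basic entries ignored
  if (is.null(max_iter)) max_iter <- 200L * (n + m)

  run_phase <- function(obj, basis, at_upper) {
    for (iter in seq_len(max_iter)) {
      B <- Ax[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(n + m), basis)
      xN <- ifelse(at_upper[nonbasic], ux[nonbasic], 0)
      rhs <- b - Ax[, nonbasic, drop = FALSE] %*% xN
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular"))
      xB <- as.vector(xB)
      y <- as.vector(solve(t(B), obj[basis]))
      rc <- obj[nonbasic] - as.vector(y %*% Ax[, nonbasic, drop = FALSE])

      enter_ok <- ux[nonbasic] > eps &        # frozen variables never enter
        ((!at_upper[nonbasic] & rc > eps) | (at_upper[nonbasic] & rc < -eps))
      if (!any(enter_ok)) {
        x <- numeric(n + m)
        x[nonbasic] <- xN
        x[basis] <- xB
        return(list(status = "optimal", x = x, basis = basis,
                    at_upper = at_upper,
                    value = sum(obj * x)))
      }
      j <- nonbasic[enter_ok][which.min(nonbasic[enter_ok])]  # Bland
      dir <- if (at_upper[j]) -1 else 1
      d <- as.vector(solve(B, Ax[, j]))

      # how far can the entering variable move?
      t_best <- if (is.finite(ux[j])) ux[j] else Inf  # flip to opposite bound
      leave <- 0L; leave_to_upper <- FALSE
      delta <- dir * d
      for (i in seq_len(m)) {
        if (delta[i] > eps) {            # basic i decreases toward 0
          ti <- xB[i] / delta[i]
          if (ti < t_best - eps ||
              (ti < t_best + eps && leave > 0L && basis[i] < basis[leave])) {
            t_best <- ti; leave <- i; leave_to_upper <- FALSE
          }
        } else if (delta[i] < -eps && is.finite(ux[basis[i]])) {
          ti <- (ux[basis[i]] - xB[i]) / (-delta[i])  # increases toward upper
          if (ti < t_best - eps ||
              (ti < t_best + eps && leave > 0L && basis[i] < basis[leave])) {
            t_best <- ti; leave <- i; leave_to_upper <- TRUE
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded"))
      }
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]     # bound flip, basis unchanged
      } else {
        at_upper[basis[leave]] <- leave_to_upper
        basis[leave] <- j
        at_upper[j] <- FALSE            # entering becomes basic
      }
    }
    list(status = "iteration_limit")
  }

  # phase 1: minimize the artificial sum
  obj1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(obj1, basis, at_upper)
  if (p1$status != "optimal") {
    return(list(status = if (p1$status == "unbounded") "infeasible"
                else p1$status))
  }
  if (-p1$value > 1e-7) return(list(status = "infeasible"))

  # phase 2: freeze artificials at zero (covers degenerate basic artificials
  # on redundant rows) and optimize the true objective
  ux[n + seq_len(m)] <- 0
  obj2 <- c(cc, rep(0, m))
  p2 <- run_phase(obj2, p1$basis, p1$at_upper)
  if (p2$status != "optimal") return(list(status = p2$status))
  list(status = "optimal", x = p2$x[seq_len(n)], value = sum(cc * p2$x[seq_len(n)]))
}
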