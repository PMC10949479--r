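# Bounded-variable primal simplex, two phases, dense.
#
# Solves  min/max c'x  s.t.  A x = b,  lo <= x <= up  (lo finite; up may be
# +Inf). This is the package's LP engine: constraint-based models produce
# small but highly degenerate LPs with linearly dependent equality rows, and
# the solver must report infeasible/unbounded outcomes reliably. Anti-cycling
# is by Dantzig pricing with a switch to Bland's rule, plus periodic basis
# refactorization against numerical drift.

simplex_bounded <- function(cost, A, b, lo, up, maximize = FALSE,
                            tol = 1e-9, max_iter = 20000L) {
  n <- length(cost)
  A <- matrix(A, ncol = n)
  m <- nrow(A)
  stopifnot(length(b) == m, length(lo) == n, length(up) == n)
  if (any(!is.finite(lo)))
    stop("simplex_bounded: lower bounds must be finite", call. = FALSE)
  if (any(lo > up + tol))
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  up <- pmax(up, lo)
  cc <- if (maximize) -cost else cost

  # drop linearly dependent equality rows (b is consistent by construction
  # for homogeneous systems; verify residuals at the end regardless)
  if (m > 1L) {
    qa <- qr(t(A), tol = 1e-10)
    if (qa$rank < m) {
      keep <- sort(qa$pivot[seq_len(qa$rank)])
      A <- A[keep, , drop = FALSE]
      b <- b[keep]
      m <- nrow(A)
    }
  }
  if (m == 0L) {
    # box problem: each variable sits at its cheapest bound
    x <- ifelse(cc > 0, lo, ifelse(cc < 0, up, lo))
    if (any(cc < 0 & !is.finite(up)))
      return(list(status = "unbounded", objval = NA_real_, x = NULL))
    return(list(status = "optimal", objval = sum(cost * x), x = x))
  }

  # phase-1 artificials with signed identity columns
  x <- ifelse(is.finite(lo), lo, 0)
  r <- b - as.numeric(A %*% x)
  s <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(s, m))
  lo_e <- c(lo, rep(0, m))
  up_e <- c(up, rep(Inf, m))
  ntot <- n + m
  xv <- c(x, abs(r))
  bas <- n + seq_len(m)
  stat <- c(rep(-1L, n), rep(0L, m))     # -1 at lb, +1 at ub, 0 basic
  Binv <- diag(1 / s, m)

  run_phase <- function(ph_cost, xv, bas, stat, Binv, bland_after = 500L) {
    it <- 0L
    refresh <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter)
        return(list(status = "iteration_limit", xv = xv, bas = bas,
                    stat = stat, Binv = Binv))
      refresh <- refresh + 1L
      if (refresh >= 60L) {
        Binv <- tryCatch(solve(Aext[, bas, drop = FALSE]),
                         error = function(e) Binv)
        xv[bas] <- as.numeric(Binv %*%
          (b - Aext[, -bas, drop = FALSE] %*% xv[-bas]))
        refresh <- 0L
      }
      w <- as.numeric(crossprod(ph_cost[bas], Binv))
      d <- ph_cost - as.numeric(w %*% Aext)
      fixed <- lo_e >= up_e - tol
      cand <- which((stat == -1L & d < -tol & !fixed) |
                    (stat == +1L & d > tol & !fixed))
      if (!length(cand))
        return(list(status = "optimal", xv = xv, bas = bas, stat = stat,
                    Binv = Binv))
      j <- if (it > bland_after) cand[1L]
           else cand[which.max(abs(d[cand]))]
      sigma <- if (stat[j] == -1L) 1 else -1
      u <- as.numeric(Binv %*% Aext[, j])
      step <- -sigma * u                     # d x_B / d t
      t_best <- if (is.finite(up_e[j])) up_e[j] - lo_e[j] else Inf
      leave <- 0L
      for (i in seq_len(m)) {
        if (step[i] < -tol) {
          ti <- (xv[bas[i]] - lo_e[bas[i]]) / (-step[i])
        } else if (step[i] > tol) {
          ti <- if (is.finite(up_e[bas[i]]))
            (up_e[bas[i]] - xv[bas[i]]) / step[i] else Inf
        } else next
        if (ti < t_best - tol || (ti < t_best + tol && leave == 0L)) {
          t_best <- ti
          leave <- i
        }
      }
      if (!is.finite(t_best))
        return(list(status = "unbounded", xv = xv, bas = bas, stat = stat,
                    Binv = Binv))
      t_best <- max(t_best, 0)
      xv[bas] <- xv[bas] + t_best * step
      xv[j] <- xv[j] + sigma * t_best
      if (leave == 0L) {                      # bound flip, basis unchanged
        stat[j] <- -stat[j]
        next
      }
      out <- bas[leave]
      stat[out] <- if (step[leave] < 0) -1L else +1L
      xv[out] <- if (stat[out] == -1L) lo_e[out] else up_e[out]
      stat[j] <- 0L
      bas[leave] <- j
      piv <- u[leave]
      Brow <- Binv[leave, ] / piv
      Binv <- Binv - u %o% Brow
      Binv[leave, ] <- Brow
    }
  }

  ph1_cost <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(ph1_cost, xv, bas, stat, Binv)
  if (p1$status == "iteration_limit")
    return(list(status = "iteration_limit", objval = NA_real_, x = NULL))
  if (sum(p1$xv[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  # pin artificials to zero for phase 2
  up_e[n + seq_len(m)] <- 0
  xv <- p1$xv; xv[n + seq_len(m)] <- 0
  ph2_cost <- c(cc, rep(0, m))
  p2 <- run_phase(ph2_cost, xv, p1$bas, p1$stat, p1$Binv)
  if (p2$status %in% c("iteration_limit", "unbounded"))
    return(list(status = p2$status, objval = NA_real_, x = NULL))
  x <- p2$xv[seq_len(n)]
  x <- pmin(pmax(x, lo), ifelse(is.finite(up), up, x))
  resid <- max(abs(A %*% x - b))
  if (resid > 1e-6)
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  list(status = "optimal", objval = sum(cost * x), x = x)
}
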