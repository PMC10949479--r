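#' Solve a bounded linear program
#'
#' Package-internal LP interface: optimise `obj' v` subject to
#' `A_eq v = b_eq` and `lb <= v <= ub`, via the bounded-variable two-phase
#' simplex in `simplex_bounded()`. Infinite upper bounds are supported (the
#' flux cone used by coupling analysis); unboundedness and infeasibility are
#' reported as statuses, never as numbers.
#'
#' @param obj numeric objective coefficients (names propagate to `x`).
#' @param A_eq equality constraint matrix (dependent rows tolerated).
#' @param b_eq equality right-hand side (defaults to zero).
#' @param lb,ub variable bounds; `lb` must be finite.
#' @param direction `"max"` or `"min"`.
#' @param tol pivot/optimality tolerance.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `objval` and the solution vector `x`.
#' @keywords internal
solve_lp <- function(obj, A_eq, b_eq = NULL, lb, ub,
                     direction = c("max", "min"), tol = 1e-9) {
  direction <- match.arg(direction)
  n <- length(obj)
  A_eq <- matrix(A_eq, ncol = n)
  if (is.null(b_eq)) b_eq <- numeric(nrow(A_eq))
  stopifnot(length(lb) == n, length(ub) == n, length(b_eq) == nrow(A_eq))
  res <- simplex_bounded(as.numeric(obj), A_eq, b_eq, lb, ub,
                         maximize = direction == "max", tol = tol)
  if (!is.null(res$x)) names(res$x) <- names(obj)
  res
}

# Assemble the LP data (S plus ratio rows, bounds) for a model once, so FBA /
# FVA / coupling loops do not rebuild the matrix per solve.
model_lp_data <- function(model) {
  S <- build_stoich_matrix(model)
  if (length(model$ratio_constraints)) {
    extra <- t(vapply(model$ratio_constraints, function(rc) {
      row <- numeric(ncol(S))
      names(row) <- colnames(S)
      row[rc$numerator] <- 1
      row[rc$denominator] <- -rc$ratio
      row
    }, numeric(ncol(S))))
    S <- rbind(S, extra)
  }
  list(A = S, lb = lower_bounds(model), ub = upper_bounds(model),
       rxns = rxn_ids(model))
}
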