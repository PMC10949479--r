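#' Expression profile container
#'
#' @param condition condition label (e.g. `"3FL"`).
#' @param values named numeric vector of nonnegative normalized counts,
#'   gene id -> value.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(condition, values) {
  stopifnot(is.character(condition), length(condition) == 1L,
            is.numeric(values), !is.null(names(values)))
  if (any(values < 0)) stop("normalized counts must be nonnegative", call. = FALSE)
  structure(list(condition = condition, values = values),
            class = "expression_profile")
}

#' Read an expression matrix (genes x conditions) from TSV
#'
#' @param path TSV with gene ids in the first column and one column per
#'   condition.
#' @return Named list of [expression_profile()] objects, one per condition.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  out <- lapply(names(df)[-1], function(cond)
    expression_profile(cond, stats::setNames(as.numeric(df[[cond]]), genes)))
  stats::setNames(out, names(df)[-1])
}

#' Write expression profiles as a TSV matrix
#' @param profiles list of [expression_profile()] sharing a gene set.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(profiles, path) {
  genes <- sort(unique(unlist(lapply(profiles, function(p) names(p$values)))))
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (p in profiles) df[[p$condition]] <- unname(p$values[genes])
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reaction-level expression via GPR mapping
#'
#' `and` rules take the minimum (lowest-expressed subunit limits the complex),
#' `or` rules the maximum (best isozyme carries the reaction). Reactions
#' without a GPR get `NA` and are never thresholded; rules whose genes are all
#' unmeasured get `Inf` (never penalized) with a warning.
#'
#' @param model a `metabolic_model`.
#' @param profile an [expression_profile()].
#' @return Named numeric vector over reactions.
#' @export
reaction_expression <- function(model, profile) {
  stopifnot(inherits(profile, "expression_profile"))
  vals <- vapply(model$reactions, function(r)
    gpr_expression(r$gpr, profile$values), numeric(1))
  unmeasured <- setdiff(unique(unlist(lapply(model$reactions,
                                             function(r) gpr_genes(r$gpr)))),
                        names(profile$values))
  if (length(unmeasured))
    warning("genes without measurements treated as above-threshold: ",
            paste(unmeasured, collapse = ", "))
  vals
}

#' Percentile expression threshold
#'
#' The GIMME low/high expression cutoff: the given percentile of the per-gene
#' value distribution, with linear interpolation between order statistics
#' (percentile 0 is the minimum, 100 the maximum).
#'
#' @param profile an [expression_profile()].
#' @param percentile percentile in [0, 100]; 30 by default.
#' @return The threshold value.
#' @export
expression_threshold <- function(profile, percentile = 30) {
  stopifnot(inherits(profile, "expression_profile"),
            percentile >= 0, percentile <= 100)
  if (!length(profile$values)) stop("empty expression profile", call. = FALSE)
  unname(stats::quantile(profile$values, percentile / 100, type = 7))
}

#' GIMME extraction of a context-specific model
#'
#' Solves the GIMME linear program: minimise the penalised usage
#' `sum_i (threshold - x_i) * |v_i|` over reactions whose expression `x_i`
#' falls below the threshold, subject to mass balance, bounds, and biomass at
#' or above `biomass_fraction` of its unconstrained optimum. Below-threshold
#' reactions carrying no flux in the solution are deactivated (bounds zeroed)
#' in the returned context model; a below-threshold reaction that the LP is
#' forced to use (the sole route to biomass) is retained and contributes to
#' the inconsistency score. Reactions with `NA`/`Inf` expression (no GPR, or
#' unmeasured genes) are never penalised or deactivated.
#'
#' @param model a `metabolic_model` that grows (`fba` optimal, mu > 0).
#' @param rxn_expr named reaction-level expression from
#'   [reaction_expression()].
#' @param threshold expression threshold from [expression_threshold()].
#' @param biomass_fraction fraction of optimal growth the context model must
#'   retain (0.9 by default).
#' @param condition label stored in the result.
#' @param tol zero-flux tolerance for deactivation.
#' @return An object of class `context_model`: `model` (deactivated copy),
#'   `condition`, `threshold_value`, `deactivated_reactions`,
#'   `inconsistency_score`, `solution` (the GIMME flux solution) and `mu`.
#' @export
gimme_extract <- function(model, rxn_expr, threshold, biomass_fraction = 0.9,
                          condition = "condition", tol = 1e-6) {
  stage1 <- fba(model)
  if (stage1$status != "optimal" || stage1$mu <= tol)
    stop("GIMME requires a growing base model (status: ", stage1$status,
         ", mu = ", format(stage1$mu), ")", call. = FALSE)
  lp <- model_lp_data(model)
  n <- length(lp$rxns)
  x <- rxn_expr[lp$rxns]
  penalty <- ifelse(is.na(x) | !is.finite(x), 0, pmax(threshold - x, 0))
  lb <- lp$lb; ub <- lp$ub
  j <- match(model$objective, lp$rxns)
  lb[j] <- max(lb[j], biomass_fraction * stage1$mu - 1e-9 * max(1, stage1$mu))
  if (lb[j] > ub[j])
    stop("biomass_fraction ", biomass_fraction,
         " is infeasible; lower the fraction", call. = FALSE)
  A2 <- cbind(lp$A, -lp$A)
  lb2 <- rep(0, 2L * n)
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  pos_lb <- lb > 0; neg_ub <- ub < 0
  lb2[seq_len(n)][pos_lb] <- lb[pos_lb]
  lb2[n + seq_len(n)][neg_ub] <- -ub[neg_ub]
  pen2 <- rep(penalty, 2L)
  sol <- solve_lp(pen2, A2, lb = lb2, ub = ub2, direction = "min")
  if (sol$status != "optimal")
    stop("GIMME LP failed (status: ", sol$status, "); biomass_fraction ",
         biomass_fraction, " may be infeasible", call. = FALSE)
  # lexicographic second stage: at (near-)minimal penalty, maximise biomass
  eps <- 1e-9 * max(1, abs(sol$objval))
  A3 <- rbind(cbind(A2, 0), c(pen2, 1))
  b3 <- c(numeric(nrow(A2)), sol$objval + eps)
  obj3 <- c(rep(0, n), rep(0, n), 0)
  obj3[j] <- 1; obj3[n + j] <- -1
  sol2 <- solve_lp(obj3, A3, b_eq = b3, lb = c(lb2, 0), ub = c(ub2, eps),
                   direction = "max")
  if (sol2$status == "optimal") {
    # final parsimony stage: canonical (minimal-total-flux) solution at the
    # achieved penalty and growth, so deactivation is reproducible
    mu2 <- sum(obj3 * sol2$x)
    lb3 <- c(lb2, 0)
    lb3[j] <- max(lb3[j], mu2 - 1e-9 * max(1, abs(mu2)))
    sol3 <- solve_lp(c(rep(1, 2L * n), 0), A3, b_eq = b3, lb = lb3,
                     ub = c(ub2, eps), direction = "min")
    pick <- if (sol3$status == "optimal") sol3 else sol2
    sol <- list(status = "optimal", objval = sol$objval,
                x = pick$x[seq_len(2L * n)])
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  names(v) <- lp$rxns
  below <- !is.na(penalty) & penalty > 0
  deactivated <- lp$rxns[below & abs(v) <= tol]
  ctx <- model
  if (length(deactivated)) ctx <- set_bounds(ctx, deactivated, lower = 0, upper = 0)
  structure(list(model = ctx, condition = condition,
                 threshold_value = threshold,
                 deactivated_reactions = deactivated,
                 inconsistency_score = sol$objval,
                 solution = flux_solution("optimal", unname(v[model$objective]),
                                          v, model$objective),
                 mu = unname(v[model$objective]),
                 base_mu = stage1$mu),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf(
    "<context_model '%s'> threshold=%.4g, %d deactivated, inconsistency=%.4g, mu=%.4g\n",
    x$condition, x$threshold_value, length(x$deactivated_reactions),
    x$inconsistency_score, x$mu))
  invisible(x)
}

#' Summarise context-specific models across conditions
#'
#' One row per condition: deactivated reaction count, GIMME growth rate,
#' re-optimised context growth rate, biomass yield and product yields when a
#' medium/product table is supplied.
#'
#' @param context_models list of [gimme_extract()] results.
#' @param media optional named list of [medium_spec()] per condition.
#' @param product_mws optional named MW vector for product yields.
#' @return A data frame, one row per context model.
#' @export
context_report <- function(context_models, media = NULL, product_mws = numeric()) {
  stopifnot(length(context_models) >= 1L)
  rows <- lapply(context_models, function(cm) {
    refit <- fba(cm$model)
    row <- data.frame(condition = cm$condition,
                      deactivated = length(cm$deactivated_reactions),
                      inconsistency = cm$inconsistency_score,
                      mu_gimme = cm$mu,
                      mu_context = refit$mu,
                      stringsAsFactors = FALSE)
    if (!is.null(media) && cm$condition %in% names(media)) {
      med <- media[[cm$condition]]
      yld <- compute_yields(refit, cm$model, med, product_mws)
      row$biomass_yield <- yld$biomass_yield
      for (p in names(yld$metabolite_yields))
        row[[paste0("yield_", p)]] <- yld$metabolite_yields[[p]]
    }
    row
  })
  do.call(rbind, rows)
}
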