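#' Flux balance analysis
#'
#' Solves the canonical linear program: optimise the objective flux subject to
#' steady-state mass balance `S v = 0` and the flux bounds `lb <= v <= ub`
#' (plus any product-ratio rows attached with [add_ratio_constraint()]). The
#' optimum of the biomass reaction is the specific growth rate mu (h^-1).
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimise; defaults to the model objective.
#' @param direction `"max"` (default) or `"min"`.
#' @return A `flux_solution`: list with `status`, `mu` (objective value) and
#'   the named flux vector `fluxes`. Non-optimal outcomes carry `status` only.
#' @export
fba <- function(model, objective = model$objective,
                direction = c("max", "min")) {
  direction <- match.arg(direction)
  validate_model(model)
  if (!objective %in% rxn_ids(model))
    stop("objective reaction '", objective, "' not in the model", call. = FALSE)
  lp <- model_lp_data(model)
  obj <- stats::setNames(numeric(length(lp$rxns)), lp$rxns)
  obj[objective] <- 1
  sol <- solve_lp(obj, lp$A, lb = lp$lb, ub = lp$ub, direction = direction)
  flux_solution(sol$status, sol$objval, sol$x, objective)
}

flux_solution <- function(status, mu, fluxes, objective) {
  structure(list(status = status,
                 mu = if (identical(status, "optimal")) mu else NA_real_,
                 fluxes = fluxes, objective = objective),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status=%s objective[%s]=%s\n", x$status,
              x$objective, format(x$mu, digits = 6)))
  invisible(x)
}

#' Parsimonious FBA
#'
#' Two-stage solve: (1) plain [fba()] for the optimal objective value; (2) with
#' the objective pinned at that optimum (less a 1e-9 relative slack so the
#' floating-point optimum stays feasible), minimise the total absolute flux
#' sum(|v|), with reversible reactions split into nonnegative forward/backward
#' halves. This selects the enzymatically cheapest of the alternate optima and
#' suppresses loops.
#'
#' @inheritParams fba
#' @return A `flux_solution` whose `mu` equals the FBA optimum to within the
#'   slack and whose fluxes minimise total absolute flux at that optimum.
#' @export
pfba <- function(model, objective = model$objective) {
  stage1 <- fba(model, objective)
  if (stage1$status != "optimal")
    stop("pFBA stage 1 not optimal (status: ", stage1$status, ")", call. = FALSE)
  mu_star <- stage1$mu
  lp <- model_lp_data(model)
  n <- length(lp$rxns)
  lb <- lp$lb; ub <- lp$ub
  j <- match(objective, lp$rxns)
  lb[j] <- mu_star - 1e-9 * max(1, abs(mu_star))
  if (lb[j] > ub[j]) lb[j] <- ub[j]
  # split v = p - q with p, q >= 0
  A2 <- cbind(lp$A, -lp$A)
  lb2 <- rep(0, 2L * n)
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  # enforce original lower bounds: p - q >= lb  and  p - q <= ub
  # encoded via extra equality-free box is not enough when lb > 0 or ub < 0;
  # add rows p_i - q_i = v_i only implicitly: bounds suffice unless lb_i > 0
  # or ub_i < 0, which we pin by raising the matching half's lower bound.
  pos_lb <- lb > 0; neg_ub <- ub < 0
  lb2[seq_len(n)][pos_lb] <- lb[pos_lb]
  lb2[n + seq_len(n)][neg_ub] <- -ub[neg_ub]
  obj <- rep(1, 2L * n)
  sol <- solve_lp(obj, A2, lb = lb2, ub = ub2, direction = "min")
  if (sol$status != "optimal")
    stop("pFBA stage 2 failed (status: ", sol$status,
         "); check solver tolerances", call. = FALSE)
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  names(v) <- lp$rxns
  flux_solution("optimal", unname(v[objective]), v, objective)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective stays at or above `fraction` of its optimum (0.99 by default,
#' i.e. flux ranges within 99 % of the optimal growth rate).
#'
#' @inheritParams fba
#' @param fraction required fraction of the optimal objective, in (0, 1].
#' @param reactions reaction ids to scan (default: all).
#' @return A data frame with columns `reaction`, `min_flux`, `max_flux` and an
#'   `optimality_fraction` attribute.
#' @export
fva <- function(model, objective = model$objective, fraction = 0.99,
                reactions = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  stage1 <- fba(model, objective)
  if (stage1$status != "optimal")
    stop("FVA requires an optimal FBA solution (status: ", stage1$status, ")",
         call. = FALSE)
  lp <- model_lp_data(model)
  j <- match(objective, lp$rxns)
  lb <- lp$lb; ub <- lp$ub
  lb[j] <- max(lb[j], fraction * stage1$mu - 1e-9 * max(1, abs(stage1$mu)))
  fva_ranges(lp$A, lb, ub, lp$rxns, reactions, fraction)
}

fva_ranges <- function(A, lb, ub, rxns, reactions = NULL, fraction = NA_real_) {
  if (is.null(reactions)) reactions <- rxns
  stopifnot(all(reactions %in% rxns))
  out <- data.frame(reaction = reactions,
                    min_flux = rep(NA_real_, length(reactions)),
                    max_flux = rep(NA_real_, length(reactions)),
                    stringsAsFactors = FALSE)
  obj <- stats::setNames(numeric(length(rxns)), rxns)
  for (k in seq_along(reactions)) {
    obj[] <- 0
    obj[reactions[k]] <- 1
    lo <- solve_lp(obj, A, lb = lb, ub = ub, direction = "min")
    hi <- solve_lp(obj, A, lb = lb, ub = ub, direction = "max")
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for '", reactions[k], "' returned ",
           lo$status, "/", hi$status, call. = FALSE)
    out$min_flux[k] <- lo$objval
    out$max_flux[k] <- hi$objval
  }
  attr(out, "optimality_fraction") <- fraction
  out
}

#' Constrain the ratio of two product fluxes
#'
#' Appends the homogeneous equality `v_num - ratio * v_den = 0` to the model's
#' steady-state system, e.g. a 3.5:2 acetate:lactate secretion ratio is
#' `ratio = 1.75` on the two exchange reactions. The constraint is applied to
#' exchanges (measured extracellular products), and the all-zero flux vector
#' always remains feasible.
#'
#' @param model a `metabolic_model`.
#' @param numerator,denominator reaction ids (numerator = ratio * denominator).
#' @param ratio positive ratio value.
#' @return The model with the ratio row attached.
#' @export
add_ratio_constraint <- function(model, numerator, denominator, ratio) {
  stopifnot(ratio > 0)
  missing <- setdiff(c(numerator, denominator), rxn_ids(model))
  if (length(missing))
    stop("ratio constraint references unknown reactions: ",
         paste(missing, collapse = ", "), call. = FALSE)
  model$ratio_constraints <- c(model$ratio_constraints,
                               list(list(numerator = numerator,
                                         denominator = denominator,
                                         ratio = ratio)))
  model
}

#' Drop all ratio constraints from a model
#' @param model a `metabolic_model`.
#' @return The model without ratio rows.
#' @export
clear_ratio_constraints <- function(model) {
  model$ratio_constraints <- list()
  model
}

#' Detect blocked reactions
#'
#' A reaction is blocked when it can carry no flux in any steady state allowed
#' by the model bounds (FVA without an objective constraint gives the range
#' [0, 0]). Exchange openness is taken from the model bounds as given.
#'
#' @param model a `metabolic_model`.
#' @param tol zero tolerance on the flux range.
#' @return Character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, tol = 1e-6) {
  lp <- model_lp_data(model)
  rng <- fva_ranges(lp$A, lp$lb, lp$ub, lp$rxns)
  rng$reaction[abs(rng$min_flux) <= tol & abs(rng$max_flux) <= tol]
}

#' Expressed-but-blocked consistency check
#'
#' Lists reactions whose GPR is satisfied by the expressed gene set but which
#' cannot carry flux while biomass stays at or above `biomass_fraction` of its
#' optimum — the model-gap report used when reconciling a reconstruction with
#' transcriptome evidence.
#'
#' @param model a `metabolic_model`.
#' @param expressed_genes character vector of expressed gene ids; ids not in
#'   the model are warned about and ignored.
#' @param biomass_fraction required biomass fraction (0 checks plain flux
#'   capability).
#' @param tol zero tolerance.
#' @return Character vector of expressed-but-blocked reaction ids.
#' @export
consistency_check <- function(model, expressed_genes, biomass_fraction = 0,
                              tol = 1e-6) {
  extra <- setdiff(expressed_genes, model$genes)
  if (length(extra))
    warning("expressed genes not in the model: ", paste(extra, collapse = ", "))
  silent <- setdiff(model$genes, expressed_genes)
  supported <- vapply(model$reactions, function(r)
    !gpr_is_empty(r$gpr) && gpr_active(r$gpr, silent), logical(1))
  lp <- model_lp_data(model)
  lb <- lp$lb; ub <- lp$ub
  if (biomass_fraction > 0) {
    ref <- fba(model)
    if (ref$status != "optimal" || ref$mu <= tol)
      stop("consistency_check: model cannot grow, cannot impose a biomass fraction",
           call. = FALSE)
    j <- match(model$objective, lp$rxns)
    lb[j] <- max(lb[j], biomass_fraction * ref$mu - 1e-9)
  }
  ids <- lp$rxns[supported]
  rng <- fva_ranges(lp$A, lb, ub, lp$rxns, reactions = ids)
  rng$reaction[abs(rng$min_flux) <= tol & abs(rng$max_flux) <= tol]
}

#' Biomass and product yields of a flux solution
#'
#' Biomass yield is mu / (uptake mass flow) in gDCW per g substrate; each
#' product yield is (export flux x MW / 1000) / mu in g per gDCW. Yields are
#' intensive: scaling all bounds leaves them unchanged.
#'
#' @param solution an optimal `flux_solution`.
#' @param model the model the solution was computed on.
#' @param medium the [medium_spec()] naming the carbon source and its MW.
#' @param product_mws named numeric vector: exchange reaction id -> molecular
#'   weight of the exported metabolite (g·mol^-1).
#' @return A list of class `yield_report` with `biomass_yield` (gDCW·g^-1) and
#'   `metabolite_yields` (g·gDCW^-1); metabolite yields are `NA` (flagged) when
#'   mu is zero.
#' @export
compute_yields <- function(solution, model, medium, product_mws = numeric()) {
  stopifnot(inherits(solution, "flux_solution"),
            identical(solution$status, "optimal"))
  uptake <- solution$fluxes[[medium$carbon_source_id]]
  mass_in <- abs(uptake) * medium$molecular_weight / 1000  # g substrate /gDCW/h
  mu <- solution$fluxes[[model$objective]]
  biomass_yield <- if (mass_in > 0) mu / mass_in else NA_real_
  grows <- mu > 1e-9
  met_yields <- vapply(names(product_mws), function(ex) {
    if (!grows) return(NA_real_)
    flux <- solution$fluxes[[ex]]
    max(flux, 0) * product_mws[[ex]] / 1000 / mu
  }, numeric(1))
  structure(list(biomass_yield = biomass_yield,
                 metabolite_yields = met_yields,
                 growth = grows),
            class = "yield_report")
}

#' Write a flux table as TSV
#'
#' @param solution a `flux_solution`.
#' @param path output file; FVA ranges are merged in when supplied.
#' @param fva_table optional [fva()] result.
#' @return The path, invisibly.
#' @export
write_flux_tsv <- function(solution, path, fva_table = NULL) {
  df <- data.frame(reaction = names(solution$fluxes),
                   flux = unname(solution$fluxes),
                   stringsAsFactors = FALSE)
  if (!is.null(fva_table))
    df <- merge(df, fva_table, by = "reaction", all.x = TRUE, sort = FALSE)
  df <- df[order(df$reaction), , drop = FALSE]
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export fluxes as a flat Escher-compatible JSON map
#'
#' @param solution a `flux_solution`.
#' @param path output `.json` file.
#' @return The path, invisibly.
#' @export
write_flux_json <- function(solution, path) {
  jsonlite::write_json(as.list(solution$fluxes), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
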