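#' Pipeline configuration
#'
#' Collects the knobs of the per-condition pipeline. Defaults follow the
#' study design: a 3.5:2 acetate:lactate secretion ratio on the two product
#' exchanges, FVA at 99 % of the optimum, GIMME at the 30th expression
#' percentile with 90 % biomass retention.
#'
#' @param conditions condition names to run.
#' @param ratio_constraint `TRUE` to impose the acetate:lactate ratio during
#'   flux estimation, GIMME and coupling analysis.
#' @param ratio acetate:lactate value (1.75 = 3.5:2).
#' @param fva_fraction FVA optimality fraction.
#' @param gimme_percentile expression-threshold percentile.
#' @param biomass_fraction GIMME biomass retention fraction.
#' @param seed seed for fixture expression noise.
#' @param uptake_bound reference lactose uptake bound.
#' @param seeds exchange ids anchoring the coupled networks (major
#'   fermentation end products).
#' @return A list of class `run_config`.
#' @export
run_config <- function(conditions = c("lactose", "3FL", "6SL", "LNnT"),
                       ratio_constraint = TRUE, ratio = 1.75,
                       fva_fraction = 0.99, gimme_percentile = 30,
                       biomass_fraction = 0.9, seed = 1L, uptake_bound = 10,
                       seeds = c("EX_lac", "EX_ac", "EX_succ", "EX_for",
                                 "EX_etoh", "EX_12ppd")) {
  stopifnot(fva_fraction > 0, fva_fraction <= 1,
            gimme_percentile >= 0, gimme_percentile <= 100,
            biomass_fraction > 0, biomass_fraction <= 1, ratio > 0)
  structure(list(conditions = conditions, ratio_constraint = ratio_constraint,
                 ratio = ratio, fva_fraction = fva_fraction,
                 gimme_percentile = gimme_percentile,
                 biomass_fraction = biomass_fraction, seed = as.integer(seed),
                 uptake_bound = uptake_bound, seeds = seeds),
            class = "run_config")
}

#' Run the full pipeline for one condition
#'
#' Medium application, FBA + pFBA + FVA under the product-ratio constraint,
#' yield calculation, GIMME context extraction, a single-gene deletion scan
#' (on the medium-bounded model without the ratio row, which is a
#' measurement-derived constraint rather than physiology), and flux-coupling
#' network construction on the context model. When `outdir` is given, writes
#' `flux.tsv` (pFBA fluxes + FVA ranges), `fluxes.json` (Escher-style flat
#' map), `yields.tsv`, `context.tsv`, `essentiality.tsv` and
#' `network.graphml`.
#'
#' @param model the base `metabolic_model`.
#' @param profile the condition's [expression_profile()].
#' @param condition condition name (must have a [bifid_medium()] mapping).
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @return A list bundle with `condition`, `medium`, `fba`, `pfba`, `fva`,
#'   `yields`, `context`, `essentiality`, `coupling`, `network`.
#' @export
run_condition <- function(model, profile, condition, config = run_config(),
                          outdir = NULL) {
  medium <- bifid_medium(condition, config$uptake_bound)
  bounded <- apply_medium(model, medium)
  constrained <- if (config$ratio_constraint)
    add_ratio_constraint(bounded, "EX_ac", "EX_lac", config$ratio)
  else bounded
  sol_fba <- fba(constrained)
  if (sol_fba$status != "optimal")
    stop("condition '", condition, "': FBA ", sol_fba$status, call. = FALSE)
  sol_pfba <- pfba(constrained)
  fva_tbl <- fva(constrained, fraction = config$fva_fraction)
  yields <- compute_yields(sol_pfba, constrained, medium,
                           intersect_mws(constrained))
  rxn_expr <- reaction_expression(constrained, profile)
  thr <- expression_threshold(profile, config$gimme_percentile)
  ctx <- gimme_extract(constrained, rxn_expr, thr,
                       biomass_fraction = config$biomass_fraction,
                       condition = condition)
  ess <- single_gene_deletions(model, stats::setNames(list(bounded), condition))
  ess_cls <- classify_essentiality(ess)
  coupling <- fca(ctx$model)
  network <- build_coupled_network(coupling, intersect(config$seeds,
                                                       rxn_ids(model)),
                                   model = model, condition = condition)
  bundle <- list(condition = condition, medium = medium, fba = sol_fba,
                 pfba = sol_pfba, fva = fva_tbl, yields = yields,
                 context = ctx, essentiality = ess_cls, coupling = coupling,
                 network = network)
  if (!is.null(outdir)) write_condition_bundle(bundle, outdir)
  bundle
}

intersect_mws <- function(model)
  fixture_product_mws()[intersect(names(fixture_product_mws()),
                                  rxn_ids(model))]

write_condition_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_flux_tsv(bundle$pfba, file.path(outdir, "flux.tsv"), bundle$fva)
  write_flux_json(bundle$pfba, file.path(outdir, "fluxes.json"))
  yld <- bundle$yields
  ydf <- data.frame(quantity = c("biomass_yield_gDCW_per_g",
                                 paste0("yield_g_per_gDCW.",
                                        names(yld$metabolite_yields))),
                    value = c(yld$biomass_yield,
                              unname(yld$metabolite_yields)),
                    stringsAsFactors = FALSE)
  utils::write.table(format(ydf, digits = 10, trim = TRUE, scientific = FALSE),
                     file.path(outdir, "yields.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ctx_df <- data.frame(deactivated_reaction = sort(
    bundle$context$deactivated_reactions), stringsAsFactors = FALSE)
  utils::write.table(ctx_df, file.path(outdir, "context.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_essentiality_tsv(bundle$essentiality,
                         file.path(outdir, "essentiality.tsv"))
  write_network_graphml(bundle$network, file.path(outdir, "network.graphml"))
  invisible(outdir)
}

#' Run all conditions and aggregate cross-condition results
#'
#' Runs [run_condition()] per condition, then assembles the context-model
#' comparison table, the essentiality intersection (genes essential on every
#' carbon source), and the consensus coupled network with per-node rewiring
#' (Dn) scores. With `outdir` set, per-condition bundles land in
#' subdirectories plus `context_report.tsv`, `dn_scores.tsv`,
#' `core_essential.tsv` and `consensus.graphml` at the top level.
#'
#' @param model base model (default: the synthetic bifid-shunt fixture).
#' @param profiles named list of expression profiles per condition (default:
#'   generated from the fixture with `config$seed`).
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @return A list with `bundles`, `context_report`, `core_essential`,
#'   `rewiring` (scores + consensus graph) and `config`.
#' @export
run_all <- function(model = NULL, profiles = NULL, config = run_config(),
                    outdir = NULL) {
  if (length(config$conditions) < 2L)
    stop("run_all needs at least two conditions", call. = FALSE)
  opts <- fixture_options(uptake_bound = config$uptake_bound,
                          random_seed = config$seed)
  if (is.null(model)) model <- build_bifid_fixture(opts)
  if (is.null(profiles)) {
    profiles <- lapply(config$conditions, function(cond)
      build_expression_fixture(model, cond, opts))
    names(profiles) <- config$conditions
  }
  bundles <- lapply(config$conditions, function(cond)
    run_condition(model, profiles[[cond]], cond, config,
                  outdir = if (!is.null(outdir)) file.path(outdir, cond)))
  names(bundles) <- config$conditions
  media <- lapply(config$conditions, bifid_medium, config$uptake_bound)
  names(media) <- config$conditions
  ctx_report <- context_report(lapply(bundles, function(b) b$context),
                               media = media,
                               product_mws = intersect_mws(model))
  ess_tables <- do.call(rbind, lapply(bundles, function(b)
    b$essentiality$table))
  ess_all <- classify_essentiality(ess_tables)
  rewiring <- dn_rewiring(lapply(bundles, function(b) b$network))
  out <- list(bundles = bundles, context_report = ctx_report,
              core_essential = ess_all$core_essential,
              essentiality = ess_all, rewiring = rewiring, config = config)
  if (!is.null(outdir)) {
    utils::write.table(format(ctx_report, digits = 10, trim = TRUE,
                              scientific = FALSE),
                       file.path(outdir, "context_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(format(rewiring$scores, digits = 10, trim = TRUE,
                              scientific = FALSE),
                       file.path(outdir, "dn_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene = out$core_essential),
                       file.path(outdir, "core_essential.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_network_graphml(rewiring$consensus,
                          file.path(outdir, "consensus.graphml"))
  }
  out
}

#' Predict growth across the substrates of a phenotype design
#'
#' For every substrate with a medium, bounds the model and records the FBA
#' optimum; substrates without an exchange in the model predict no growth
#' (`NA`). Media are applied without the product-ratio row: this probes
#' binary growth capability.
#'
#' @param model a `metabolic_model`.
#' @param growth_table result of [build_growth_table()].
#' @return Named numeric vector substrate -> predicted mu.
#' @export
predict_growth <- function(model, growth_table) {
  vapply(growth_table$phenotypes$substrate, function(s) {
    med <- growth_table$media[[s]]
    if (is.null(med)) return(NA_real_)
    sol <- fba(apply_medium(model, med))
    if (sol$status == "optimal") sol$mu else 0
  }, numeric(1))
}

#' Growth-prediction evaluation on a phenotype design
#'
#' Convenience wrapper: [predict_growth()], [compare_growth()], then F-score,
#' MCC and (when rates are present) the growth-rate RMSE.
#'
#' @param model a `metabolic_model`.
#' @param growth_table result of [build_growth_table()].
#' @return A list with `counts`, `f_score`, `mcc`, `rmse` and the
#'   per-substrate comparison table.
#' @export
evaluate_growth_predictions <- function(model,
                                        growth_table = build_growth_table()) {
  pred <- predict_growth(model, growth_table)
  counts <- compare_growth(pred, growth_table$phenotypes)
  obs_rate <- if ("observed_rate" %in% names(growth_table$phenotypes))
    stats::setNames(growth_table$phenotypes$observed_rate,
                    growth_table$phenotypes$substrate) else NULL
  rmse <- if (!is.null(obs_rate) && any(!is.na(obs_rate)))
    rmse_growth(pred, obs_rate) else NA_real_
  list(counts = counts, f_score = f_score(counts), mcc = mcc(counts),
       rmse = rmse, per_substrate = attr(counts, "per_substrate"))
}
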