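test_that("percentile thresholds use linear interpolation", {
  p <- expression_profile("x", stats::setNames(as.numeric(1:10),
                                               paste0("g", 1:10)))
  expect_equal(expression_threshold(p, 0), 1)
  expect_equal(expression_threshold(p, 100), 10)
  p4 <- expression_profile("x", c(a = 10, b = 20, c = 30, d = 40))
  expect_equal(expression_threshold(p4, 30), 19)
  expect_error(expression_threshold(expression_profile("x",
                stats::setNames(numeric(), character())), 30), "empty")
  expect_error(expression_profile("x", c(g = -1)), "nonnegative")
})

test_that("reaction expression follows the GPR min/max convention", {
  fx <- build_bifid_fixture()
  vals <- stats::setNames(rep(100, length(fx$genes)), fx$genes)
  vals["Blon_9032"] <- 2   # LDH isozyme 1
  vals["Blon_9033"] <- 8   # LDH isozyme 2
  vals["Blon_9030"] <- 3   # LGLY subunit (and-rule)
  vals["Blon_9031"] <- 9
  prof <- expression_profile("t", vals)
  rexpr <- reaction_expression(fx, prof)
  expect_equal(unname(rexpr[["LDH"]]), 8)      # or -> highest
  expect_equal(unname(rexpr[["LGLY"]]), 3)     # and -> lowest
  expect_true(is.na(rexpr[["EX_glc"]]))        # no GPR
  # hand-evaluated recursion for every <= 3 gene rule in the fixture
  for (id in rxn_ids(fx)) {
    tree <- fx$reactions[[id]]$gpr
    genes <- gpr_genes(tree)
    if (length(genes) == 0 || length(genes) > 3) next
    expected <- switch(tree$kind,
                       leaf = vals[[tree$gene]],
                       and = min(vals[genes]),
                       or = max(vals[genes]))
    expect_equal(unname(rexpr[[id]]), unname(expected), info = id)
  }
})

gimme_lactose_setup <- function(percentile = 30) {
  fx <- build_bifid_fixture()
  # crossed expression off: the off-condition branches are cleanly silent
  prof <- build_expression_fixture(fx, "lactose", crossed_fraction = 0)
  con <- add_ratio_constraint(apply_medium(fx, bifid_medium("lactose")),
                              "EX_ac", "EX_lac", 1.75)
  list(model = con,
       rxn_expr = suppressWarnings(reaction_expression(con, prof)),
       threshold = expression_threshold(prof, percentile))
}

test_that("GIMME keeps growth and deactivates only silent zero-flux reactions", {
  st <- gimme_lactose_setup()
  base_mu <- fba(st$model)$mu
  ctx <- gimme_extract(st$model, st$rxn_expr, st$threshold,
                       condition = "lactose")
  expect_gte(ctx$mu, 0.9 * base_mu - 1e-6)
  # deactivated reactions are below threshold and flux-free in the solution
  for (id in ctx$deactivated_reactions) {
    expect_lt(st$rxn_expr[[id]], st$threshold)
    expect_equal(unname(ctx$solution$fluxes[[id]]), 0, tolerance = 1e-6)
    expect_equal(ctx$model$reactions[[id]]$upper_bound, 0)
  }
  # off-condition feeder routes are switched off on lactose
  expect_true(all(c("FL3t", "SL6t", "LNNTt") %in% ctx$deactivated_reactions))
  # re-solving the context model routes no flux through deactivated reactions
  refit <- fba(ctx$model)
  expect_true(all(abs(refit$fluxes[ctx$deactivated_reactions]) < 1e-9))
  # context biomass yield stays within 10 % of the generic model's
  expect_gt(refit$mu, 0.9 * base_mu - 1e-6)
})

test_that("all-above-threshold expression deactivates nothing", {
  st <- gimme_lactose_setup()
  high <- st$rxn_expr
  high[] <- 1e6
  ctx <- gimme_extract(st$model, high, threshold = 10)
  expect_length(ctx$deactivated_reactions, 0)
  expect_equal(ctx$inconsistency_score, 0, tolerance = 1e-9)
  expect_equal(ctx$mu, fba(st$model)$mu, tolerance = 1e-4)
})

test_that("a silent parallel path is deactivated, an essential one survives", {
  m <- parallel_model(uptake = 10)
  # give routes gene associations by rebuilding with gprs
  rxns <- m$reactions
  rxns[["short"]]$gpr <- parse_gpr("gShort")
  rxns[["long1"]]$gpr <- parse_gpr("gLong")
  rxns[["long2"]]$gpr <- parse_gpr("gLong")
  rxns[["long3"]]$gpr <- parse_gpr("gLong")
  m2 <- metabolic_model(m$metabolites, rxns, objective = "EX_c")
  rexpr <- reaction_expression(m2, expression_profile("t", c(gShort = 100,
                                                             gLong = 1)))
  ctx <- gimme_extract(m2, rexpr, threshold = 50)
  expect_setequal(ctx$deactivated_reactions, c("long1", "long2", "long3"))
  expect_equal(ctx$inconsistency_score, 0, tolerance = 1e-9)
  # now silence the only remaining route: it must survive with a penalty
  rexpr2 <- reaction_expression(m2, expression_profile("t", c(gShort = 1,
                                                              gLong = 2)))
  ctx2 <- gimme_extract(m2, rexpr2, threshold = 50)
  expect_false("short" %in% ctx2$deactivated_reactions)
  expect_gt(ctx2$inconsistency_score, 0)
  expect_gte(ctx2$mu, 0.9 * fba(m2)$mu - 1e-6)
})

test_that("thresholds sweep monotonically: penalties and deactivations grow", {
  fx <- build_bifid_fixture()
  prof <- build_expression_fixture(fx, "lactose")
  con <- add_ratio_constraint(apply_medium(fx, bifid_medium("lactose")),
                              "EX_ac", "EX_lac", 1.75)
  rxn_expr <- suppressWarnings(reaction_expression(con, prof))
  prev_below <- character()
  prev_score <- -1
  for (pct in c(10, 30, 50, 70)) {
    thr <- expression_threshold(prof, pct)
    ctx <- gimme_extract(con, rxn_expr, thr)
    below <- names(which(rxn_expr < thr))
    expect_true(all(prev_below %in% below))
    expect_gte(ctx$inconsistency_score, prev_score - 1e-9)
    prev_below <- below
    prev_score <- ctx$inconsistency_score
  }
  # the coarser comparison of the report: deactivation does not shrink 30 -> 60
  n30 <- length(gimme_extract(con, rxn_expr,
                              expression_threshold(prof, 30))$deactivated_reactions)
  n60 <- length(gimme_extract(con, rxn_expr,
                              expression_threshold(prof, 60))$deactivated_reactions)
  expect_gte(n60, n30)
})

test_that("context report tallies the four fixture conditions", {
  fx <- build_bifid_fixture()
  conds <- c("lactose", "3FL", "6SL", "LNnT")
  ctxs <- lapply(conds, function(cond) {
    prof <- build_expression_fixture(fx, cond, crossed_fraction = 0)
    con <- add_ratio_constraint(apply_medium(fx, bifid_medium(cond)),
                                "EX_ac", "EX_lac", 1.75)
    gimme_extract(con, suppressWarnings(reaction_expression(con, prof)),
                  expression_threshold(prof, 30), condition = cond)
  })
  media <- stats::setNames(lapply(conds, bifid_medium), conds)
  rep <- context_report(ctxs, media, fixture_product_mws())
  expect_equal(nrow(rep), 4L)
  expect_equal(rep$deactivated,
               vapply(ctxs, function(x) length(x$deactivated_reactions),
                      integer(1)))
  # fucose and sialic-acid branch members are off on lactose
  lac <- ctxs[[1]]
  expect_true(all(c("AFUCS", "FUCK", "LCARS") %in%
                    lac$deactivated_reactions))
  expect_true(all(c("SIALD", "NANL") %in% lac$deactivated_reactions))
  # every below-threshold reaction that is blocked on the medium is deactivated
  con_lac <- add_ratio_constraint(apply_medium(fx, bifid_medium("lactose")),
                                  "EX_ac", "EX_lac", 1.75)
  prof_lac <- build_expression_fixture(fx, "lactose", crossed_fraction = 0)
  rexpr_lac <- suppressWarnings(reaction_expression(con_lac, prof_lac))
  below <- names(which(rexpr_lac < expression_threshold(prof_lac, 30)))
  expect_true(all(intersect(below, blocked_reactions(con_lac)) %in%
                    lac$deactivated_reactions))
  # every context keeps at least 90 % of its base growth
  expect_true(all(rep$mu_context >= 0.9 * vapply(ctxs, function(x)
    x$base_mu, numeric(1)) - 1e-6))
})

test_that("expression TSV round-trips through read/write", {
  dir <- withr::local_tempdir()
  fx <- build_bifid_fixture()
  profs <- lapply(c("lactose", "3FL"), function(cond)
    build_expression_fixture(fx, cond))
  write_expression_tsv(profs, file.path(dir, "expr.tsv"))
  back <- read_expression_tsv(file.path(dir, "expr.tsv"))
  expect_setequal(names(back), c("lactose", "3FL"))
  expect_equal(back$lactose$values[names(profs[[1]]$values)],
               profs[[1]]$values, tolerance = 1e-9)
})
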