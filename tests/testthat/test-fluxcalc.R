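test_that("FBA solves textbook cases", {
  m <- chain_model(uptake = 10)
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$mu, 20)                      # 1:2 step doubles the export
  expect_equal(unname(sol$fluxes[["R1"]]), 10)
  # nothing to eat -> zero growth
  closed <- set_bounds(m, "EX_a", lower = 0)
  expect_equal(fba(closed)$mu, 0)
  # direction = min on an export gives zero
  expect_equal(fba(m, "EX_c", direction = "min")$mu, 0)
})

test_that("optimal solutions satisfy mass balance and bounds", {
  for (seed in 1:25) {
    m <- random_small_model(seed)
    sol <- fba(m)
    expect_identical(sol$status, "optimal")
    S <- build_stoich_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes[colnames(S)])), 1e-6)
    expect_true(all(sol$fluxes >= lower_bounds(m) - 1e-6))
    expect_true(all(sol$fluxes <= upper_bounds(m) + 1e-6))
  }
})

test_that("FBA optimum equals the best vertex of the flux polytope", {
  for (seed in 1:40) {
    m <- random_small_model(seed)
    verts <- oracle_vertices_model(m)
    expect_gt(length(verts), 0)
    obj_idx <- match(m$objective, rxn_ids(m))
    best <- max(vapply(verts, `[`, numeric(1), obj_idx))
    expect_equal(fba(m)$mu, best, tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("pFBA keeps the optimum and routes flux through the short path", {
  m <- parallel_model(uptake = 10)
  sol <- pfba(m)
  expect_equal(sol$mu, 10, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes[["short"]]), 10, tolerance = 1e-6)
  expect_equal(unname(sol$fluxes[["long1"]]), 0, tolerance = 1e-6)
  # single-route chain: pFBA equals FBA
  ch <- chain_model()
  expect_equal(pfba(ch)$fluxes, fba(ch)$fluxes, tolerance = 1e-6)
})

test_that("pFBA total flux never exceeds any optimal vertex's", {
  for (seed in 1:40) {
    m <- random_small_model(seed)
    sol_f <- fba(m)
    sol_p <- pfba(m)
    expect_equal(sol_p$mu, sol_f$mu, tolerance = 1e-6)
    verts <- oracle_vertices_model(m)
    obj_idx <- match(m$objective, rxn_ids(m))
    opt <- Filter(function(v) v[obj_idx] >= sol_f$mu - 1e-6, verts)
    for (v in opt)
      expect_lte(sum(abs(sol_p$fluxes)), sum(abs(v)) + 1e-5)
  }
})

test_that("FVA brackets the pFBA flux and relaxing the fraction widens ranges", {
  for (seed in c(3, 7, 11, 19)) {
    m <- random_small_model(seed)
    sol_p <- pfba(m)
    r100 <- fva(m, fraction = 1)
    r90 <- fva(m, fraction = 0.9)
    for (k in seq_len(nrow(r100))) {
      id <- r100$reaction[k]
      expect_gte(sol_p$fluxes[[id]], r100$min_flux[k] - 1e-6)
      expect_lte(sol_p$fluxes[[id]], r100$max_flux[k] + 1e-6)
      expect_lte(r90$min_flux[k], r100$min_flux[k] + 1e-6)
      expect_gte(r90$max_flux[k], r100$max_flux[k] - 1e-6)
    }
  }
})

test_that("FVA collapses on unique-flux networks and splits on parallel paths", {
  ch <- chain_model()
  r <- fva(ch, fraction = 1)
  expect_true(all(r$max_flux - r$min_flux < 1e-6))
  pl <- parallel_model(uptake = 10)
  rp <- fva(pl, fraction = 1)
  expect_equal(rp$min_flux[rp$reaction == "short"], 0, tolerance = 1e-6)
  expect_equal(rp$max_flux[rp$reaction == "short"], 10, tolerance = 1e-6)
  expect_equal(rp$min_flux[rp$reaction == "long1"], 0, tolerance = 1e-6)
  expect_equal(rp$max_flux[rp$reaction == "long1"], 10, tolerance = 1e-6)
})

test_that("ratio constraints force the product ratio whenever flux runs", {
  fx <- build_bifid_fixture()
  b <- apply_medium(fx, bifid_medium("lactose"))
  for (ratio in c(1.6, 1.75)) {
    con <- add_ratio_constraint(b, "EX_ac", "EX_lac", ratio)
    sol <- fba(con)
    expect_gt(sol$mu, 0)
    expect_equal(unname(sol$fluxes[["EX_ac"]] / sol$fluxes[["EX_lac"]]),
                 ratio, tolerance = 1e-5)
  }
  # homogeneous row stays feasible at zero flux
  closed <- set_bounds(add_ratio_constraint(b, "EX_ac", "EX_lac", 1.75),
                       "EX_lcts", lower = 0)
  solc <- fba(closed)
  expect_identical(solc$status, "optimal")
  expect_equal(solc$mu, 0)
  expect_error(add_ratio_constraint(b, "EX_ac", "EX_nope", 2), "unknown")
})

test_that("growth is insensitive to the acetate:lactate ratio within the feasible window", {
  fx <- build_bifid_fixture()
  b <- apply_medium(fx, bifid_medium("lactose"))
  mus <- vapply(c(1.55, 1.6, 1.65, 1.7, 1.75), function(r)
    fba(add_ratio_constraint(b, "EX_ac", "EX_lac", r))$mu, numeric(1))
  expect_true(all(mus > 0))
  expect_lt(diff(range(mus)) / mean(mus), 0.05)
})

test_that("blocked reaction detection finds dead ends and severed branches", {
  # reaction producing a metabolite nothing consumes
  m <- metabolic_model(
    list(ext_met("a_e"), metabolite("a_c"), metabolite("dead_c"),
         ext_met("b_e")),
    list(reaction("EX_a", c(a_e = -1), -10, 1000),
         reaction("At", c(a_e = -1, a_c = 1)),
         reaction("Adead", c(a_c = -1, dead_c = 1)),
         reaction("AB", c(a_c = -1, b_e = 1)),
         reaction("EX_b", c(b_e = -1))),
    objective = "EX_b")
  expect_setequal(blocked_reactions(m), "Adead")
  fx <- build_bifid_fixture()
  glc <- apply_medium(fx, bifid_medium("glucose"))
  bl <- blocked_reactions(glc)
  for (id in c("GLCt", "HEX", "F6PPK", "XPK", "LGLY", "ACK", "EX_ac"))
    expect_false(id %in% bl, info = id)
  # removing the sialidase blocks the whole sialic-acid branch
  sl <- apply_medium(fx, bifid_medium("6SL"))
  cut <- set_bounds(sl, "SIALD", lower = 0, upper = 0)
  bl_cut <- blocked_reactions(cut)
  for (id in c("NANL", "AMANK", "AMANE", "NEUACt", "EX_neuac"))
    expect_true(id %in% bl_cut, info = id)
})

test_that("consistency check reports expressed-but-blocked reactions", {
  fx <- build_bifid_fixture()
  glc <- apply_medium(fx, bifid_medium("glucose"))
  all_genes <- fx$genes
  out <- consistency_check(glc, all_genes)
  # the flux-disabled succinate stub is expressed yet can carry no flux
  expect_true("SUCSYN" %in% out)
  # silencing everything reports nothing (no GPR satisfied)
  expect_length(consistency_check(glc, character()), 0)
  expect_warning(consistency_check(glc, c(all_genes, "ghost")), "ghost")
})

test_that("yields are intensive and follow the flux solution", {
  fx <- build_bifid_fixture()
  med <- bifid_medium("lactose")
  con <- add_ratio_constraint(apply_medium(fx, med), "EX_ac", "EX_lac", 1.75)
  sol <- pfba(con)
  y <- compute_yields(sol, con, med, fixture_product_mws())
  expect_gt(y$biomass_yield, 0)
  expect_equal(unname(y$metabolite_yields[["EX_succ"]]), 0)
  expect_equal(unname(y$metabolite_yields[["EX_12ppd"]]), 0)
  expect_gt(y$metabolite_yields[["EX_ac"]], y$metabolite_yields[["EX_lac"]])
  # doubling the uptake bound doubles mu but leaves yields unchanged
  med2 <- bifid_medium("lactose", uptake_bound = 20)
  con2 <- add_ratio_constraint(apply_medium(fx, med2), "EX_ac", "EX_lac", 1.75)
  sol2 <- pfba(con2)
  y2 <- compute_yields(sol2, con2, med2, fixture_product_mws())
  expect_equal(sol2$mu, 2 * sol$mu, tolerance = 1e-5)
  expect_equal(y2$biomass_yield, y$biomass_yield, tolerance = 1e-5)
  expect_equal(y2$metabolite_yields, y$metabolite_yields, tolerance = 1e-5)
})

test_that("flux tables and Escher JSON export round-trip numerically", {
  dir <- withr::local_tempdir()
  ch <- chain_model()
  sol <- pfba(ch)
  write_flux_tsv(sol, file.path(dir, "flux.tsv"), fva(ch))
  tab <- utils::read.delim(file.path(dir, "flux.tsv"))
  expect_setequal(tab$reaction, rxn_ids(ch))
  expect_equal(tab$flux[tab$reaction == "EX_c"], 20, tolerance = 1e-6)
  write_flux_json(sol, file.path(dir, "flux.json"))
  js <- jsonlite::read_json(file.path(dir, "flux.json"))
  expect_equal(js$EX_c, 20, tolerance = 1e-6)
})
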