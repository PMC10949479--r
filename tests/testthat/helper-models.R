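# Small model builders shared across tests.

ext_met <- function(id, ...) metabolite(id, compartment = "extracellular", ...)

# linear chain with an uptake bound and a 1:2 stoichiometric step
chain_model <- function(uptake = 10) {
  metabolic_model(
    list(ext_met("a_e"), metabolite("a_c"), metabolite("b_c"), ext_met("c_e")),
    list(reaction("EX_a", c(a_e = -1), -uptake, 0),
         reaction("At", c(a_e = -1, a_c = 1)),
         reaction("R1", c(a_c = -1, b_c = 1)),
         reaction("R2", c(b_c = -1, c_e = 2)),
         reaction("EX_c", c(c_e = -1))),
    objective = "EX_c")
}

# two parallel routes from a to c: a short one and a long one
parallel_model <- function(uptake = 10) {
  metabolic_model(
    list(ext_met("a_e"), metabolite("a_c"), metabolite("m1_c"),
         metabolite("m2_c"), metabolite("c_c"), ext_met("c_e")),
    list(reaction("EX_a", c(a_e = -1), -uptake, 0),
         reaction("At", c(a_e = -1, a_c = 1)),
         reaction("short", c(a_c = -1, c_c = 1)),
         reaction("long1", c(a_c = -1, m1_c = 1)),
         reaction("long2", c(m1_c = -1, m2_c = 1)),
         reaction("long3", c(m2_c = -1, c_c = 1)),
         reaction("Ct", c(c_c = -1, c_e = 1)),
         reaction("EX_c", c(c_e = -1))),
    objective = "EX_c")
}

# branch point a -> b with two competing exports
branch_model <- function(uptake = 10) {
  metabolic_model(
    list(ext_met("a_e"), metabolite("a_c"), metabolite("b_c"),
         ext_met("c_e"), ext_met("d_e")),
    list(reaction("EX_a", c(a_e = -1), -uptake, 0),
         reaction("At", c(a_e = -1, a_c = 1)),
         reaction("AB", c(a_c = -1, b_c = 1)),
         reaction("BC", c(b_c = -1, c_e = 1)),
         reaction("BD", c(b_c = -1, d_e = 1)),
         reaction("EX_c", c(c_e = -1)),
         reaction("EX_d", c(d_e = -1))),
    objective = "EX_c")
}

# random small bounded network: m internal metabolites, each with a boundary
# reaction, plus random internal conversions; always feasible (v = 0)
random_small_model <- function(seed, n_mets = 3, n_internal = 4) {
  with_seed(seed, {
    mets <- lapply(seq_len(n_mets), function(i)
      metabolite(paste0("m", i, "_c")))
    rxns <- list()
    for (i in seq_len(n_mets)) {
      u <- sample(c(1, 2, 5), 1)
      rxns[[length(rxns) + 1L]] <-
        reaction(paste0("B", i), stats::setNames(-1, paste0("m", i, "_c")),
                 -u, sample(c(0, u), 1))
    }
    for (k in seq_len(n_internal)) {
      nm <- sample(n_mets, min(n_mets, 2))
      st <- stats::setNames(sample(c(-2, -1, 1, 2), length(nm), replace = TRUE),
                            paste0("m", nm, "_c"))
      if (all(st > 0) || all(st < 0)) st[1] <- -st[1]
      lb <- if (stats::runif(1) < 0.5) -sample(c(1, 2, 5), 1) else 0
      rxns[[length(rxns) + 1L]] <-
        reaction(paste0("R", k), st, lb, sample(c(1, 2, 5), 1))
    }
    obj <- sample(vapply(rxns, `[[`, character(1), "id"), 1)
    metabolic_model(mets, rxns, objective = obj,
                    id = paste0("random", seed))
  })
}

# sign-only bounds variant for coupling tests (cone and bounds agree on
# blocked reactions)
random_cone_model <- function(seed, n_mets = 3, n_internal = 3) {
  m <- random_small_model(seed, n_mets, n_internal)
  for (id in rxn_ids(m)) {
    r <- m$reactions[[id]]
    m <- set_bounds(m, id,
                    lower = if (r$lower_bound < 0) -1000 else 0,
                    upper = if (r$upper_bound > 0) 1000 else 0)
  }
  m
}
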