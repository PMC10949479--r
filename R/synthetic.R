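#' Options for the synthetic bifid-shunt fixture
#'
#' @param gam growth-associated maintenance ATP embedded in the biomass
#'   reaction (mmol ATP·gDCW^-1); 40 by default, 20 being the common
#'   alternative biomass parameterisation.
#' @param include_branches logical flags enabling the optional pathway blocks:
#'   `fucose` (3'FL utilisation ending in lactaldehyde reductase / 1,2-PD),
#'   `neuAc` (6'SL sialic-acid branch), `glcNAc` (LNnT aminosugar kinase
#'   entry), `pfl_ethanol` (pyruvate-formate lyase + alcohol dehydrogenase
#'   NADH valve), `succinate_stub` (a flux-disabled succinate branch).
#' @param uptake_bound reference (lactose) uptake bound, mmol·gDCW^-1·h^-1.
#' @param random_seed seed for expression-noise generation only; the model
#'   itself is deterministic.
#' @return A list of class `fixture_options`.
#' @export
fixture_options <- function(gam = 40,
                            include_branches = c(fucose = TRUE, neuAc = TRUE,
                                                 glcNAc = TRUE,
                                                 pfl_ethanol = TRUE,
                                                 succinate_stub = TRUE),
                            uptake_bound = 10, random_seed = 1L) {
  flags <- c(fucose = TRUE, neuAc = TRUE, glcNAc = TRUE, pfl_ethanol = TRUE,
             succinate_stub = TRUE)
  flags[names(include_branches)] <- include_branches
  stopifnot(gam >= 0, uptake_bound > 0)
  structure(list(gam = gam, include_branches = flags,
                 uptake_bound = uptake_bound,
                 random_seed = as.integer(random_seed)),
            class = "fixture_options")
}

#' Molecular weights used by the fixture media and yield reports
#'
#' @return Named numeric vector, g·mol^-1.
#' @export
hmo_molecular_weights <- function() {
  c(glucose = 180.16, galactose = 180.16, lactose = 342.30,
    `3FL` = 488.44, `6SL` = 633.55, LNnT = 707.63, fucose = 164.16,
    xylose = 150.13,
    acetate = 60.05, lactate = 90.08, formate = 46.03, ethanol = 46.07,
    succinate = 118.09, propanediol_12 = 76.09, pyruvate = 88.06)
}

#' Product molecular weights keyed by fixture exchange id
#' @return Named numeric vector for [compute_yields()].
#' @export
fixture_product_mws <- function() {
  c(EX_ac = 60.05, EX_lac = 90.08, EX_for = 46.03, EX_etoh = 46.07,
    EX_succ = 118.09, EX_12ppd = 76.09, EX_pyr = 88.06)
}

#' Exchange id for each fixture substrate name
#' @return Named character vector.
#' @export
fixture_substrate_exchanges <- function() {
  c(glucose = "EX_glc", galactose = "EX_gal", lactose = "EX_lcts",
    `3FL` = "EX_3fl", `6SL` = "EX_6sl", LNnT = "EX_lnnt", fucose = "EX_fuc")
}

#' Mole-normalised medium for a fixture condition
#'
#' All conditions are prepared at the same weight/volume, so molar uptake
#' scales inversely with molecular weight relative to lactose.
#'
#' @param condition one of `names(fixture_substrate_exchanges())`.
#' @param uptake_bound reference lactose uptake bound.
#' @return A [medium_spec()].
#' @export
bifid_medium <- function(condition, uptake_bound = 10) {
  ex <- fixture_substrate_exchanges()
  mw <- hmo_molecular_weights()
  if (!condition %in% names(ex))
    stop("unknown fixture condition '", condition, "'", call. = FALSE)
  medium_spec(carbon_source_id = unname(ex[condition]),
              molecular_weight = unname(mw[condition]),
              reference_mw = unname(mw["lactose"]),
              base_uptake_bound = uptake_bound,
              allowances = c(EX_nh4 = -1000, EX_pi = -1000))
}

#' Build the synthetic bifid-shunt model
#'
#' A stoichiometrically faithful core of *Bifidobacterium* fermentation:
#' hexoses are phosphorylated and funnelled through fructose-6-phosphate
#' phosphoketolase, transaldolase, transketolase and the pentose-phosphate
#' isomerase/epimerase into acetyl-phosphate and glyceraldehyde-3-phosphate,
#' with lumped lower glycolysis, lactate dehydrogenase and acetate kinase
#' closing the redox and energy balances so that the net conversion is
#' exactly 2 glucose -> 3 acetate + 2 lactate + 5 ATP. Feeder pathways cover
#' lactose (beta-galactosidase + Leloir), 3'FL (fucosidase, fucose ->
#' 1,2-propanediol + pyruvate), 6'SL (sialidase + aminosugar pathway into
#' fructose-6-phosphate), and LNnT (beta-hexosaminidase + GlcNAc kinase).
#' Pyruvate-formate lyase and a lumped aldehyde/alcohol dehydrogenase provide
#' the low-flux NADH valve; a succinate stub ships flux-disabled. Free sialic
#' acid and GlcNAc have export-only exchanges (partial aminosugar spill-over).
#' Every enzymatic reaction carries a 1-3 gene GPR with `and`/`or` variety;
#' gene ids use a deliberately out-of-range synthetic `Blon_9xxx` numbering.
#'
#' @param opts a [fixture_options()] list.
#' @return A `metabolic_model` with objective `BIOMASS` and an ATP drain
#'   `ATPM`.
#' @export
build_bifid_fixture <- function(opts = fixture_options()) {
  stopifnot(inherits(opts, "fixture_options"))
  fl <- opts$include_branches
  cyt <- function(id, name, formula)
    metabolite(id, name, "cytosol", formula)
  ext <- function(id, name, formula)
    metabolite(id, name, "extracellular", formula)

  mets <- list(
    ext("glc_e", "D-glucose", "C6H12O6"),
    ext("gal_e", "D-galactose", "C6H12O6"),
    ext("lcts_e", "lactose", "C12H22O11"),
    ext("fl3_e", "3-fucosyllactose", "C18H32O15"),
    ext("sl6_e", "6-sialyllactose", "C23H39NO19"),
    ext("lnnt_e", "lacto-N-neotetraose", "C26H45NO21"),
    ext("fuc_e", "L-fucose", "C6H12O5"),
    ext("ac_e", "acetate", "C2H4O2"),
    ext("lac_e", "L-lactate", "C3H6O3"),
    ext("for_e", "formate", "CH2O2"),
    ext("etoh_e", "ethanol", "C2H6O"),
    ext("succ_e", "succinate", "C4H6O4"),
    ext("ppd12_e", "1,2-propanediol", "C3H8O2"),
    ext("pyr_e", "pyruvate", "C3H4O3"),
    ext("nh4_e", "ammonium", "H4N"),
    ext("pi_e", "orthophosphate", "HO4P"),
    ext("neuac_e", "N-acetylneuraminate", "C11H19NO9"),
    ext("acgam_e", "N-acetylglucosamine", "C8H15NO6"),
    cyt("glc_c", "D-glucose", "C6H12O6"),
    cyt("gal_c", "D-galactose", "C6H12O6"),
    cyt("lcts_c", "lactose", "C12H22O11"),
    cyt("fl3_c", "3-fucosyllactose", "C18H32O15"),
    cyt("sl6_c", "6-sialyllactose", "C23H39NO19"),
    cyt("lnnt_c", "lacto-N-neotetraose", "C26H45NO21"),
    cyt("fuc_c", "L-fucose", "C6H12O5"),
    cyt("g6p_c", "D-glucose 6-phosphate", "C6H13O9P"),
    cyt("f6p_c", "D-fructose 6-phosphate", "C6H13O9P"),
    cyt("g1p_c", "D-glucose 1-phosphate", "C6H13O9P"),
    cyt("gal1p_c", "D-galactose 1-phosphate", "C6H13O9P"),
    cyt("e4p_c", "D-erythrose 4-phosphate", "C4H9O7P"),
    cyt("s7p_c", "sedoheptulose 7-phosphate", "C7H15O10P"),
    cyt("gap_c", "glyceraldehyde 3-phosphate", "C3H7O6P"),
    cyt("dhap_c", "dihydroxyacetone phosphate", "C3H7O6P"),
    cyt("r5p_c", "D-ribose 5-phosphate", "C5H11O8P"),
    cyt("ru5p_c", "D-ribulose 5-phosphate", "C5H11O8P"),
    cyt("x5p_c", "D-xylulose 5-phosphate", "C5H11O8P"),
    cyt("actp_c", "acetyl phosphate", "C2H5O5P"),
    cyt("accoa_c", "acetyl-CoA", "C23H38N7O17P3S"),
    cyt("coa_c", "coenzyme A", "C21H36N7O16P3S"),
    cyt("pyr_c", "pyruvate", "C3H4O3"),
    cyt("lac_c", "L-lactate", "C3H6O3"),
    cyt("ac_c", "acetate", "C2H4O2"),
    cyt("for_c", "formate", "CH2O2"),
    cyt("etoh_c", "ethanol", "C2H6O"),
    cyt("succ_c", "succinate", "C4H6O4"),
    cyt("fcl_c", "L-fuculose", "C6H12O5"),
    cyt("fc1p_c", "L-fuculose 1-phosphate", "C6H13O8P"),
    cyt("lald_c", "L-lactaldehyde", "C3H6O2"),
    cyt("ppd12_c", "1,2-propanediol", "C3H8O2"),
    cyt("neuac_c", "N-acetylneuraminate", "C11H19NO9"),
    cyt("acmana_c", "N-acetyl-D-mannosamine", "C8H15NO6"),
    cyt("acmanap_c", "N-acetyl-D-mannosamine 6-phosphate", "C8H16NO9P"),
    cyt("acgam_c", "N-acetylglucosamine", "C8H15NO6"),
    cyt("acgam6p_c", "N-acetylglucosamine 6-phosphate", "C8H16NO9P"),
    cyt("gam6p_c", "glucosamine 6-phosphate", "C6H14NO8P"),
    cyt("nh4_c", "ammonium", "H4N"),
    cyt("atp_c", "ATP", "C10H16N5O13P3"),
    cyt("adp_c", "ADP", "C10H15N5O10P2"),
    cyt("pi_c", "orthophosphate", "HO4P"),
    cyt("nad_c", "NAD+", "C21H27N7O14P2"),
    cyt("nadh_c", "NADH", "C21H28N7O14P2"))

  rx <- function(id, st, lb = 0, ub = 1000, gpr = "", name = id, sub = "") {
    reaction(id, st, lb, ub, gpr, name, sub)
  }
  substrate_ex <- function(id, met)
    rx(id, stats::setNames(-1, met), lb = -1000, ub = 1000,
       sub = "Exchange")
  product_ex <- function(id, met)
    rx(id, stats::setNames(-1, met), lb = 0, ub = 1000, sub = "Exchange")

  rxns <- list(
    substrate_ex("EX_glc", "glc_e"),
    substrate_ex("EX_gal", "gal_e"),
    substrate_ex("EX_lcts", "lcts_e"),
    substrate_ex("EX_pi", "pi_e"),
    product_ex("EX_ac", "ac_e"),
    product_ex("EX_lac", "lac_e"),
    product_ex("EX_pyr", "pyr_e"),
    product_ex("EX_nh4", "nh4_e"),
    # uptake transports
    rx("GLCt", c(glc_e = -1, glc_c = 1), gpr = "Blon_9070",
       name = "glucose transport", sub = "Transport"),
    rx("GALt", c(gal_e = -1, gal_c = 1), lb = -1000, gpr = "Blon_9079",
       name = "galactose transport (reversible)", sub = "Transport"),
    rx("LCTSt", c(lcts_e = -1, lcts_c = 1), gpr = "Blon_9071",
       name = "lactose permease", sub = "Transport"),
    # product transports (passive, no gene association)
    rx("ACt", c(ac_c = -1, ac_e = 1), name = "acetate export", sub = "Transport"),
    rx("LACt", c(lac_c = -1, lac_e = 1), name = "lactate export", sub = "Transport"),
    rx("PYRt", c(pyr_c = -1, pyr_e = 1), name = "pyruvate export", sub = "Transport"),
    rx("NH4t", c(nh4_c = -1, nh4_e = 1), name = "ammonium export", sub = "Transport"),
    rx("PIt", c(pi_e = -1, pi_c = 1), name = "phosphate uptake", sub = "Transport"),
    # lactose and Leloir
    rx("LACZ", c(lcts_c = -1, glc_c = 1, gal_c = 1), gpr = "Blon_9001",
       name = "beta-galactosidase", sub = "Lactose utilization"),
    rx("HEX", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
       gpr = "Blon_9010", name = "glucokinase", sub = "Upper glycolysis"),
    rx("PGI", c(g6p_c = -1, f6p_c = 1), lb = -1000, gpr = "Blon_9011",
       name = "glucose-6-phosphate isomerase", sub = "Upper glycolysis"),
    rx("GALK", c(gal_c = -1, atp_c = -1, gal1p_c = 1, adp_c = 1),
       gpr = "Blon_9012", name = "galactokinase", sub = "Leloir pathway"),
    rx("GALT", c(gal1p_c = -1, g1p_c = 1), lb = -1000,
       gpr = "Blon_9013 and Blon_9014",
       name = "uridylyltransferase + UDP-glucose 4-epimerase (lumped)",
       sub = "Leloir pathway"),
    rx("PGMT", c(g1p_c = -1, g6p_c = 1), lb = -1000, gpr = "Blon_9015",
       name = "phosphoglucomutase", sub = "Leloir pathway"),
    # bifid shunt
    rx("F6PPK", c(f6p_c = -1, pi_c = -1, actp_c = 1, e4p_c = 1),
       gpr = "Blon_9020", name = "fructose-6-phosphate phosphoketolase",
       sub = "Bifid shunt"),
    rx("TALA", c(f6p_c = -1, e4p_c = -1, gap_c = 1, s7p_c = 1), lb = -1000,
       gpr = "Blon_9021", name = "transaldolase", sub = "Bifid shunt"),
    rx("TKT", c(s7p_c = -1, gap_c = -1, r5p_c = 1, x5p_c = 1), lb = -1000,
       gpr = "Blon_9022 or Blon_9023", name = "transketolase",
       sub = "Bifid shunt"),
    rx("RPI", c(r5p_c = -1, ru5p_c = 1), lb = -1000, gpr = "Blon_9024",
       name = "ribose-5-phosphate isomerase", sub = "Bifid shunt"),
    rx("RPE", c(ru5p_c = -1, x5p_c = 1), lb = -1000, gpr = "Blon_9025",
       name = "ribulose-5-phosphate epimerase", sub = "Bifid shunt"),
    rx("XPK", c(x5p_c = -1, pi_c = -1, actp_c = 1, gap_c = 1),
       gpr = "Blon_9020", name = "xylulose-5-phosphate phosphoketolase",
       sub = "Bifid shunt"),
    rx("LGLY", c(gap_c = -1, pi_c = -1, nad_c = -1, adp_c = -2,
                 pyr_c = 1, nadh_c = 1, atp_c = 2),
       gpr = "Blon_9030 and Blon_9031",
       name = "lower glycolysis (GAPDH..pyruvate kinase, lumped)",
       sub = "Lower glycolysis"),
    rx("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1),
       gpr = "Blon_9032 or Blon_9033", name = "L-lactate dehydrogenase",
       sub = "Fermentation"),
    rx("ACK", c(actp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
       gpr = "Blon_9034", name = "acetate kinase", sub = "Fermentation"),
    rx("ATPM", c(atp_c = -1, adp_c = 1, pi_c = 1),
       name = "ATP maintenance drain", sub = "Maintenance"),
    rx("BIOMASS", c(g6p_c = -5, pyr_c = -0.25, atp_c = -opts$gam,
                    adp_c = opts$gam, pi_c = opts$gam),
       name = "biomass pseudo-reaction", sub = "Biomass"))

  if (fl[["fucose"]]) rxns <- c(rxns, list(
    substrate_ex("EX_3fl", "fl3_e"),
    substrate_ex("EX_fuc", "fuc_e"),
    product_ex("EX_12ppd", "ppd12_e"),
    rx("FL3t", c(fl3_e = -1, fl3_c = 1),
       gpr = "Blon_9072 and Blon_9073 and Blon_9074",
       name = "3-FL ABC transporter", sub = "Transport"),
    rx("FUCt", c(fuc_e = -1, fuc_c = 1), gpr = "Blon_9078",
       name = "fucose transport", sub = "Transport"),
    rx("PPD12t", c(ppd12_c = -1, ppd12_e = 1),
       name = "1,2-propanediol export", sub = "Transport"),
    rx("AFUCS", c(fl3_c = -1, fuc_c = 1, lcts_c = 1),
       gpr = "Blon_9002 or Blon_9003", name = "alpha-fucosidase",
       sub = "Fucose metabolism"),
    rx("FUCI", c(fuc_c = -1, fcl_c = 1), lb = -1000, gpr = "Blon_9040",
       name = "fucose isomerase", sub = "Fucose metabolism"),
    rx("FUCK", c(fcl_c = -1, atp_c = -1, fc1p_c = 1, adp_c = 1),
       gpr = "Blon_9041", name = "fuculose kinase", sub = "Fucose metabolism"),
    rx("FUCA", c(fc1p_c = -1, dhap_c = 1, lald_c = 1), gpr = "Blon_9042",
       name = "fuculose-1-phosphate aldolase", sub = "Fucose metabolism"),
    rx("TPI", c(dhap_c = -1, gap_c = 1), lb = -1000, gpr = "Blon_9043",
       name = "triose-phosphate isomerase", sub = "Fucose metabolism"),
    rx("LCARS", c(lald_c = -1, nadh_c = -1, ppd12_c = 1, nad_c = 1),
       gpr = "Blon_9044", name = "lactaldehyde reductase",
       sub = "Fucose metabolism")))

  if (fl[["neuAc"]]) rxns <- c(rxns, list(
    substrate_ex("EX_6sl", "sl6_e"),
    product_ex("EX_neuac", "neuac_e"),
    rx("SL6t", c(sl6_e = -1, sl6_c = 1), gpr = "Blon_9075 and Blon_9076",
       name = "6-SL ABC transporter", sub = "Transport"),
    rx("NEUACt", c(neuac_c = -1, neuac_e = 1),
       name = "sialic acid export", sub = "Transport"),
    rx("SIALD", c(sl6_c = -1, neuac_c = 1, lcts_c = 1), gpr = "Blon_9004",
       name = "alpha-sialidase", sub = "Sialic acid metabolism"),
    rx("NANL", c(neuac_c = -1, acmana_c = 1, pyr_c = 1), gpr = "Blon_9050",
       name = "N-acetylneuraminate lyase", sub = "Sialic acid metabolism"),
    rx("AMANK", c(acmana_c = -1, atp_c = -1, acmanap_c = 1, adp_c = 1),
       gpr = "Blon_9051", name = "N-acetylmannosamine kinase",
       sub = "Sialic acid metabolism"),
    rx("AMANE", c(acmanap_c = -1, acgam6p_c = 1), lb = -1000,
       gpr = "Blon_9052", name = "N-acetylmannosamine-6-phosphate epimerase",
       sub = "Sialic acid metabolism")))

  if (fl[["glcNAc"]]) rxns <- c(rxns, list(
    substrate_ex("EX_lnnt", "lnnt_e"),
    product_ex("EX_acgam", "acgam_e"),
    rx("LNNTt", c(lnnt_e = -1, lnnt_c = 1), gpr = "Blon_9077",
       name = "LNnT ABC transporter", sub = "Transport"),
    rx("ACGAMt", c(acgam_c = -1, acgam_e = 1),
       name = "GlcNAc export", sub = "Transport"),
    rx("BHEX", c(lnnt_c = -1, gal_c = 1, acgam_c = 1, lcts_c = 1),
       gpr = "Blon_9005 or Blon_9006 or Blon_9007",
       name = "beta-hexosaminidase route (lumped)",
       sub = "Aminosugar metabolism"),
    rx("ACGAMK", c(acgam_c = -1, atp_c = -1, acgam6p_c = 1, adp_c = 1),
       gpr = "Blon_9053", name = "N-acetylglucosamine kinase",
       sub = "Aminosugar metabolism")))

  if (fl[["neuAc"]] || fl[["glcNAc"]]) rxns <- c(rxns, list(
    rx("AGDC", c(acgam6p_c = -1, gam6p_c = 1, ac_c = 1), gpr = "Blon_9054",
       name = "N-acetylglucosamine-6-phosphate deacetylase",
       sub = "Aminosugar metabolism"),
    rx("G6PDA", c(gam6p_c = -1, f6p_c = 1, nh4_c = 1), gpr = "Blon_9055",
       name = "glucosamine-6-phosphate deaminase",
       sub = "Aminosugar metabolism")))

  if (fl[["pfl_ethanol"]]) rxns <- c(rxns, list(
    product_ex("EX_for", "for_e"),
    product_ex("EX_etoh", "etoh_e"),
    rx("FORt", c(for_c = -1, for_e = 1), name = "formate export",
       sub = "Transport"),
    rx("ETOHt", c(etoh_c = -1, etoh_e = 1), name = "ethanol export",
       sub = "Transport"),
    rx("PFL", c(pyr_c = -1, coa_c = -1, accoa_c = 1, for_c = 1),
       gpr = "Blon_9035 or Blon_9036", name = "pyruvate formate-lyase",
       sub = "Fermentation"),
    rx("ADHE", c(accoa_c = -1, nadh_c = -2, etoh_c = 1, coa_c = 1,
                 nad_c = 2),
       gpr = "Blon_9037", name = "aldehyde/alcohol dehydrogenase (lumped)",
       sub = "Fermentation")))

  if (fl[["succinate_stub"]]) rxns <- c(rxns, list(
    product_ex("EX_succ", "succ_e"),
    rx("SUCCt", c(succ_c = -1, succ_e = 1), name = "succinate export",
       sub = "Transport"),
    rx("SUCSYN", c(pyr_c = -2, nadh_c = -2, succ_c = 1, for_c = 2,
                   nad_c = 2),
       lb = 0, ub = 0, gpr = "Blon_9060",
       name = "succinate production stub (flux-disabled)",
       sub = "TCA stub")))

  metabolic_model(mets, rxns, objective = "BIOMASS",
                  id = "bifid_shunt_fixture", gam = opts$gam)
}

#' Condition-specific synthetic expression profile
#'
#' Emulates the transcriptional layout seen on HMO substrates: bifid-shunt and
#' housekeeping genes high everywhere, feeder-pathway genes high only on their
#' own substrate, off-condition feeder genes low (below a 30th-percentile
#' threshold), the redox-valve and succinate-stub genes low throughout, and a
#' configurable fraction of "crossed" off-condition genes at moderate levels
#' (e.g. a fucosidase expressed on lactose). Values get multiplicative
#' log-normal noise from the seeded generator; calls with equal seeds are
#' identical.
#'
#' @param model the fixture model (supplies the gene list).
#' @param condition `"lactose"`, `"3FL"`, `"6SL"` or `"LNnT"`.
#' @param opts a [fixture_options()]; `random_seed` drives the noise.
#' @param crossed_fraction fraction of off-condition feeder genes expressed at
#'   a moderate level.
#' @param noise_sd standard deviation of the log-normal noise.
#' @return An [expression_profile()].
#' @export
build_expression_fixture <- function(model, condition = c("lactose", "3FL",
                                                          "6SL", "LNnT"),
                                     opts = fixture_options(),
                                     crossed_fraction = 0.15,
                                     noise_sd = 0.2) {
  condition <- match.arg(condition)
  feeder_rxns <- list(
    lactose = c("LCTSt"),
    `3FL` = c("FL3t", "FUCt", "AFUCS", "FUCI", "FUCK", "FUCA", "TPI", "LCARS"),
    `6SL` = c("SL6t", "SIALD", "NANL", "AMANK", "AMANE", "AGDC", "G6PDA"),
    LNnT = c("LNNTt", "BHEX", "ACGAMK", "AGDC", "G6PDA"))
  rxn_genes <- function(ids) unique(unlist(lapply(
    intersect(ids, rxn_ids(model)),
    function(id) gpr_genes(model$reactions[[id]]$gpr))))
  own <- rxn_genes(feeder_rxns[[condition]])
  off <- setdiff(unique(unlist(lapply(feeder_rxns[setdiff(names(feeder_rxns),
                                                          condition)],
                                      rxn_genes))), own)
  valve <- setdiff(rxn_genes(c("PFL", "ADHE", "SUCSYN")), c(own, off))
  core <- setdiff(model$genes, c(own, off, valve))
  cond_offset <- match(condition, names(feeder_rxns))
  values <- with_seed(opts$random_seed + 1000L * cond_offset, {
    base <- c(stats::setNames(rep(400, length(core)), core),
              stats::setNames(rep(250, length(own)), own),
              stats::setNames(rep(15, length(off)), off),
              stats::setNames(rep(18, length(valve)), valve))
    crossed <- off[stats::runif(length(off)) < crossed_fraction]
    base[crossed] <- 120
    noise <- exp(stats::rnorm(length(base), 0, noise_sd))
    round(base * noise, 3)
  })
  expression_profile(condition, values[sort(names(values))])
}

#' Designed growth-phenotype table with matching media
#'
#' Pairs a substrate/observed-growth table with per-substrate media so the
#' prediction pipeline reproduces a designed confusion matrix exactly.
#' Substrates without a fixture exchange get a `NULL` medium (the model then
#' predicts no growth), which is how designed FN/TN cells are created.
#'
#' The default design covers all four confusion cells: five growers the model
#' supports (TP), galactose marked non-growing although the model grows on it
#' (FP), fucose marked growing although the fixture cannot make biomass from
#' it alone (FN), and xylose, absent and non-growing (TN).
#'
#' @param design data frame with columns `substrate`, `observed_growth`,
#'   optional `observed_rate`; `NULL` uses the default design.
#' @param uptake_bound reference uptake bound for the generated media.
#' @return A list with `phenotypes` (data frame) and `media` (named list of
#'   [medium_spec()] or `NULL` for absent substrates).
#' @export
build_growth_table <- function(design = NULL, uptake_bound = 10) {
  if (is.null(design)) {
    design <- data.frame(
      substrate = c("glucose", "lactose", "3FL", "6SL", "LNnT",
                    "galactose", "fucose", "xylose"),
      observed_growth = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
      observed_rate = c(0.42, 0.75, 0.62, 0.55, 0.60, NA, 0.15, NA),
      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(design) || !nrow(design))
    stop("empty growth design", call. = FALSE)
  stopifnot(all(c("substrate", "observed_growth") %in% names(design)))
  ex <- fixture_substrate_exchanges()
  media <- lapply(design$substrate, function(s) {
    if (s %in% names(ex)) bifid_medium(s, uptake_bound) else NULL
  })
  names(media) <- design$substrate
  list(phenotypes = design, media = media)
}

#' Write the complete fixture workspace to disk
#'
#' Emits the JSON model, the four-condition expression TSV and the phenotype
#' TSV so the whole pipeline can be exercised from files.
#'
#' @param dir output directory (created if needed).
#' @param opts a [fixture_options()].
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_workspace <- function(dir, opts = fixture_options()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- build_bifid_fixture(opts)
  paths <- c(model = file.path(dir, "model.json"),
             expression = file.path(dir, "expression.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_model(model, paths["model"], format = "json")
  profiles <- lapply(c("lactose", "3FL", "6SL", "LNnT"),
                     function(cond) build_expression_fixture(model, cond, opts))
  write_expression_tsv(profiles, paths["expression"])
  gt <- build_growth_table(uptake_bound = opts$uptake_bound)
  df <- gt$phenotypes
  df$observed_growth <- as.integer(df$observed_growth)
  utils::write.table(df, paths["phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Net elemental balance of every reaction
#'
#' Multiplies each reaction's stoichiometry by the element counts parsed from
#' metabolite formulas; internal enzymatic reactions should balance (net 0),
#' while exchanges and the biomass pseudo-reaction legitimately do not.
#'
#' @param model a `metabolic_model` with formulas.
#' @param element element symbol, `"C"` by default.
#' @return Named numeric vector of net element change per reaction (`NA` when
#'   a participating metabolite lacks a formula).
#' @export
reaction_element_balance <- function(model, element = "C") {
  count <- function(formula) {
    if (is.na(formula) || !nzchar(formula)) return(NA_real_)
    m <- gregexpr(paste0(element, "(?![a-z])([0-9]*)"), formula, perl = TRUE)[[1]]
    if (m[1] == -1) return(0)
    sum(vapply(regmatches(formula, gregexpr(
      paste0(element, "(?![a-z])([0-9]*)"), formula, perl = TRUE))[[1]],
      function(tok) {
        n <- sub(paste0("^", element), "", tok)
        if (nzchar(n)) as.numeric(n) else 1
      }, numeric(1)))
  }
  counts <- vapply(model$metabolites, function(m) count(m$formula), numeric(1))
  vapply(model$reactions, function(r)
    sum(r$stoichiometry * counts[names(r$stoichiometry)]), numeric(1))
}
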