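#' Specify an in silico growth medium
#'
#' The medium fixes one active carbon source per condition. Because conditions
#' are prepared at equal weight per volume (default 2 % wt/vol), substrates are
#' compared on a mole basis: the uptake bound of the active source is the
#' reference (lactose) bound scaled by `reference_mw / molecular_weight`, so a
#' substrate twice as heavy as lactose gets half the molar uptake.
#'
#' @param carbon_source_id exchange reaction id of the active carbon source.
#' @param molecular_weight substrate molecular weight (g·mol^-1).
#' @param reference_mw molecular weight of the reference substrate
#'   (lactose, 342.3 g·mol^-1 by default).
#' @param base_uptake_bound uptake bound granted to the reference substrate
#'   (mmol·gDCW^-1·h^-1).
#' @param wt_vol_fraction weight/volume fraction of the medium, recorded for
#'   provenance (all conditions share it, so it cancels from the mole ratio).
#' @param allowances named numeric vector of lower bounds for non-carbon
#'   exchanges left open (e.g. ammonium); exchanges not listed here and not the
#'   carbon source have uptake closed.
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(carbon_source_id, molecular_weight,
                        reference_mw = 342.3, base_uptake_bound = 10,
                        wt_vol_fraction = 0.02, allowances = numeric()) {
  stopifnot(is.character(carbon_source_id), length(carbon_source_id) == 1L,
            molecular_weight > 0, reference_mw > 0, base_uptake_bound > 0)
  structure(list(carbon_source_id = carbon_source_id,
                 molecular_weight = molecular_weight,
                 reference_mw = reference_mw,
                 base_uptake_bound = base_uptake_bound,
                 wt_vol_fraction = wt_vol_fraction,
                 allowances = allowances),
            class = "medium_spec")
}

#' Bound a model to a medium
#'
#' Returns a copy of the model with: the active carbon source uptake opened to
#' `base_uptake_bound * reference_mw / molecular_weight` (mole-equivalent for
#' equal wt/vol loadings); the uptake (lower) bound of every other exchange
#' closed to zero unless listed in the medium's `allowances`; export (upper)
#' bounds untouched.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium_spec()].
#' @return The bounded model copy.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "metabolic_model"), inherits(medium, "medium_spec"))
  if (!medium$carbon_source_id %in% rxn_ids(model))
    stop("carbon source exchange '", medium$carbon_source_id,
         "' not in the model", call. = FALSE)
  ex <- rxn_ids(model)[is_exchange(model)]
  if (!medium$carbon_source_id %in% ex)
    stop("'", medium$carbon_source_id, "' is not an exchange reaction", call. = FALSE)
  uptake <- medium$base_uptake_bound * medium$reference_mw / medium$molecular_weight
  for (id in ex) {
    lb <- if (id == medium$carbon_source_id) {
      -uptake
    } else if (id %in% names(medium$allowances)) {
      as.numeric(medium$allowances[[id]])
    } else 0
    model <- set_bounds(model, id, lower = lb)
  }
  model
}
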