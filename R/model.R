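#' Construct a metabolite
#'
#' @param id unique metabolite identifier (e.g. `"glc_c"`).
#' @param name human-readable name.
#' @param compartment `"cytosol"` or `"extracellular"` (the model dialect used
#'   here has exactly two compartments).
#' @param formula optional elemental formula string (e.g. `"C6H12O6"`).
#' @return A list of class `metabolite`.
#' @export
metabolite <- function(id, name = id,
                       compartment = c("cytosol", "extracellular"),
                       formula = NA_character_) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula), class = "metabolite")
}

#' Construct a reaction
#'
#' Stoichiometry follows the usual signed convention: negative coefficients are
#' substrates, positive are products. Fluxes are in mmol·gDCW^-1·h^-1. Exchange
#' reactions are written in the export-positive dialect `met_e ->`, so uptake
#' is a negative flux bounded below by minus the uptake bound.
#'
#' @param id,name reaction identifier and label.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient;
#'   all coefficients must be nonzero and names unique.
#' @param lower_bound,upper_bound flux bounds (mmol·gDCW^-1·h^-1).
#' @param gpr a `gpr` tree or a GPR rule string (parsed with [parse_gpr()]).
#' @param subsystem free-text pathway label.
#' @return A list of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     gpr = "", name = id, subsystem = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(names(stoichiometry)) || anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': stoichiometry must have unique metabolite names",
         call. = FALSE)
  if (any(stoichiometry == 0) || any(!is.finite(stoichiometry)))
    stop("reaction '", id, "': stoichiometric coefficients must be nonzero and finite",
         call. = FALSE)
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound exceeds upper_bound", call. = FALSE)
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  stopifnot(inherits(gpr, "gpr"))
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr, subsystem = subsystem),
            class = "reaction")
}

#' Assemble a metabolic model
#'
#' The container mirrors the usual genome-scale layout: metabolites, reactions
#' with bounds and GPRs, a gene list, and one objective (biomass) reaction.
#' Growth-associated maintenance (GAM, mmol ATP·gDCW^-1) is a property of the
#' biomass reaction recorded here for bookkeeping.
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective id of the objective (biomass) reaction.
#' @param genes character vector of gene ids; defaults to the union of all GPR
#'   genes.
#' @param id model identifier.
#' @param gam growth-associated maintenance embedded in the biomass reaction.
#' @return A validated object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective,
                            genes = NULL, id = "model", gam = NA_real_) {
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(met_ids))
    stop("duplicated metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(rxn_ids))
    stop("duplicated reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  gpr_gene_set <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
  if (is.null(genes)) genes <- sort(gpr_gene_set)
  missing_genes <- setdiff(gpr_gene_set, genes)
  if (length(missing_genes))
    stop("GPR genes absent from the gene list: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  model <- structure(
    list(id = id,
         metabolites = stats::setNames(metabolites, met_ids),
         reactions = stats::setNames(reactions, rxn_ids),
         genes = genes, objective = objective, gam = gam,
         ratio_constraints = list()),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks id uniqueness, resolvable stoichiometry, bound ordering, objective
#' existence, and the exchange convention (an exchange touches exactly one
#' extracellular metabolite).
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- met_ids(model)
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown))
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (r$lower_bound > r$upper_bound)
      stop("reaction '", r$id, "': lower_bound exceeds upper_bound", call. = FALSE)
  }
  if (!model$objective %in% rxn_ids(model))
    stop("objective reaction '", model$objective, "' not in the model", call. = FALSE)
  invisible(model)
}

#' @rdname model_accessors
#' @export
met_ids <- function(model) names(model$metabolites)

#' Model accessors
#'
#' Small helpers over the model container: identifier vectors, bound vectors,
#' and exchange detection (exactly one metabolite, extracellular).
#'
#' @param model a `metabolic_model`.
#' @name model_accessors
#' @return Character or numeric vectors indexed by reaction/metabolite id.
#' @export
rxn_ids <- function(model) names(model$reactions)

#' @rdname model_accessors
#' @export
lower_bounds <- function(model)
  vapply(model$reactions, `[[`, numeric(1), "lower_bound")

#' @rdname model_accessors
#' @export
upper_bounds <- function(model)
  vapply(model$reactions, `[[`, numeric(1), "upper_bound")

#' @rdname model_accessors
#' @export
is_exchange <- function(model) {
  vapply(model$reactions, function(r) {
    mets <- names(r$stoichiometry)
    length(mets) == 1L &&
      model$metabolites[[mets]]$compartment == "extracellular"
  }, logical(1))
}

#' Set flux bounds on one or more reactions
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to modify.
#' @param lower,upper replacement bounds (recycled); `NA` leaves a bound as is.
#' @return The modified model.
#' @export
set_bounds <- function(model, ids, lower = NA, upper = NA) {
  stopifnot(all(ids %in% rxn_ids(model)))
  lower <- rep_len(lower, length(ids))
  upper <- rep_len(upper, length(ids))
  for (k in seq_along(ids)) {
    r <- model$reactions[[ids[k]]]
    if (!is.na(lower[k])) r$lower_bound <- as.numeric(lower[k])
    if (!is.na(upper[k])) r$upper_bound <- as.numeric(upper[k])
    if (r$lower_bound > r$upper_bound)
      stop("reaction '", r$id, "': lower_bound exceeds upper_bound", call. = FALSE)
    model$reactions[[ids[k]]] <- r
  }
  model
}

#' Build the stoichiometric matrix S
#'
#' Entry (i, j) is the coefficient of metabolite i in reaction j; rows follow
#' the metabolite list, columns the reaction list. At steady state the flux
#' vector satisfies S v = 0.
#'
#' @param model a `metabolic_model`.
#' @return A dense numeric matrix with metabolite/reaction dimnames.
#' @export
build_stoich_matrix <- function(model) {
  validate_model(model)
  mets <- met_ids(model)
  rxns <- rxn_ids(model)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s'> %d metabolites, %d reactions, %d genes\n",
              x$id, length(x$metabolites), length(x$reactions), length(x$genes)))
  cat("  objective:", x$objective,
      if (length(x$ratio_constraints))
        sprintf(" | %d ratio constraint(s)", length(x$ratio_constraints)) else "",
      "\n", sep = "")
  invisible(x)
}
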