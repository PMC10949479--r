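#' Read or write a metabolic model
#'
#' Three formats are supported, all text:
#' \describe{
#'   \item{`json`}{the package's documented JSON dialect:
#'     `{metabolites:[{id,name,compartment,formula}],
#'       reactions:[{id,name,metabolites:{id:coeff},lower_bound,upper_bound,
#'       gene_reaction_rule,subsystem}], genes:[...], objective:id, gam:x}`.}
#'   \item{`sbml`}{SBML Level 3 + FBC (bounds as parameters, GPRs as
#'     `fbc:geneProductAssociation`, objective via `fbc:listOfObjectives`);
#'     the subset written here is the subset read back.}
#'   \item{`tabular`}{a reaction-list TSV with columns `id`, `name`,
#'     `equation` (`"2 a_c + b_c -> c_e"`, `"<=>"` for reversible), `lb`,
#'     `ub`, `gpr`, `subsystem`; compartments come from the `_e` suffix.}
#' }
#' Writing then reading any format reproduces ids, bounds, stoichiometry and
#' GPR logic (formulas survive json/sbml; the tabular format does not carry
#' them).
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"` or `"tabular"`; the default guesses from
#'   the file extension.
#' @return `read_model()` returns a `metabolic_model`; `write_model()` its
#'   path, invisibly.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml", "tabular")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         json = read_model_json(path),
         sbml = read_model_sbml(path),
         tabular = read_model_tabular(path))
}

#' @rdname read_model
#' @param model a `metabolic_model`.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml",
                                                "tabular")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path),
         tabular = write_model_tabular(model, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json"
  else if (ext %in% c("xml", "sbml")) "sbml"
  else if (ext %in% c("tsv", "txt")) "tabular"
  else stop("cannot guess model format from extension '", ext, "'",
            call. = FALSE)
}

schema_require <- function(obj, fields, what) {
  missing <- setdiff(fields, names(obj))
  if (length(missing))
    stop("model schema error: ", what, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

# ---- JSON dialect ----------------------------------------------------------

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema_require(doc, c("metabolites", "reactions", "objective"), "model")
  mets <- lapply(doc$metabolites, function(m) {
    schema_require(m, c("id", "compartment"), "metabolite")
    metabolite(m$id, name = m$name %||% m$id, compartment = m$compartment,
               formula = m$formula %||% NA_character_)
  })
  rxns <- lapply(doc$reactions, function(r) {
    schema_require(r, c("id", "metabolites", "lower_bound", "upper_bound"),
                   paste0("reaction '", r$id %||% "?", "'"))
    st <- unlist(r$metabolites)
    if (r$lower_bound > r$upper_bound)
      stop("model schema error: reaction '", r$id,
           "' has lower_bound > upper_bound", call. = FALSE)
    reaction(r$id, st, r$lower_bound, r$upper_bound,
             gpr = r$gene_reaction_rule %||% "", name = r$name %||% r$id,
             subsystem = r$subsystem %||% "")
  })
  metabolic_model(mets, rxns, objective = doc$objective,
                  genes = if (!is.null(doc$genes)) unlist(doc$genes),
                  id = doc$id %||% "model",
                  gam = doc$gam %||% NA_real_)
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(unname(model$metabolites), function(m)
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = m$formula)),
    reactions = lapply(unname(model$reactions), function(r)
      list(id = r$id, name = r$name, metabolites = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_reaction_rule = serialize_gpr(r$gpr),
           subsystem = r$subsystem)),
    genes = model$genes,
    objective = model$objective,
    gam = model$gam)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# ---- tabular reaction list -------------------------------------------------

format_equation <- function(r) {
  side <- function(coeffs) {
    if (!length(coeffs)) return("")
    paste(vapply(names(coeffs), function(m) {
      cf <- abs(coeffs[[m]])
      if (cf == 1) m else paste(format(cf, digits = 10), m)
    }, character(1)), collapse = " + ")
  }
  lhs <- r$stoichiometry[r$stoichiometry < 0]
  rhs <- r$stoichiometry[r$stoichiometry > 0]
  arrow <- if (r$lower_bound < 0) "<=>" else "->"
  trimws(paste(side(lhs), arrow, side(rhs)))
}

parse_equation <- function(eq, id) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else "->"
  halves <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(halves) > 2L)
    stop("reaction '", id, "': malformed equation '", eq, "'", call. = FALSE)
  halves <- c(halves, rep("", 2L - length(halves)))
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    st <- numeric(); nm <- character()
    for (tm in terms) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 2L) {
        st <- c(st, sign * as.numeric(parts[1])); nm <- c(nm, parts[2])
      } else if (length(parts) == 1L) {
        st <- c(st, sign); nm <- c(nm, parts[1])
      } else stop("reaction '", id, "': malformed term '", tm, "'",
                  call. = FALSE)
    }
    stats::setNames(st, nm)
  }
  st <- c(parse_side(halves[1], -1), parse_side(halves[2], 1))
  # merge duplicated metabolites appearing on both sides
  tapply_sum <- tapply(st, names(st), sum)
  st <- st[!duplicated(names(st))]
  st[names(tapply_sum)] <- tapply_sum
  st[st != 0]
}

read_model_tabular <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  schema_require(df, c("id", "equation", "lb", "ub"), "tabular model")
  met_ids <- unique(unlist(lapply(seq_len(nrow(df)), function(i)
    names(parse_equation(df$equation[i], df$id[i])))))
  mets <- lapply(met_ids, function(id)
    metabolite(id, compartment = if (grepl("_e$", id)) "extracellular"
               else "cytosol"))
  rxns <- lapply(seq_len(nrow(df)), function(i) {
    if (df$lb[i] > df$ub[i])
      stop("model schema error: reaction '", df$id[i],
           "' has lb > ub", call. = FALSE)
    reaction(df$id[i], parse_equation(df$equation[i], df$id[i]),
             df$lb[i], df$ub[i],
             gpr = if ("gpr" %in% names(df)) df$gpr[i] else "",
             name = if ("name" %in% names(df)) df$name[i] else df$id[i],
             subsystem = if ("subsystem" %in% names(df)) df$subsystem[i] else "")
  })
  objective <- attr(df, "objective")
  if (is.null(objective))
    objective <- if ("BIOMASS" %in% df$id) "BIOMASS" else df$id[nrow(df)]
  metabolic_model(mets, rxns, objective = objective, id = "tabular_model")
}

write_model_tabular <- function(model, path) {
  df <- data.frame(
    id = rxn_ids(model),
    name = vapply(model$reactions, `[[`, character(1), "name"),
    equation = vapply(model$reactions, format_equation, character(1)),
    lb = lower_bounds(model),
    ub = upper_bounds(model),
    gpr = vapply(model$reactions, function(r) serialize_gpr(r$gpr),
                 character(1)),
    subsystem = vapply(model$reactions, `[[`, character(1), "subsystem"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- SBML Level 3 + FBC ----------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_safe_id <- function(id) gsub("[^A-Za-z0-9_]", "_", id)

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
                            xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_safe_id(model$id),
                             "fbc:strict" = "false")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in c("cytosol", "extracellular"))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    node <- xml2::xml_add_child(sps, "species", id = m$id, name = m$name,
                                compartment = m$compartment,
                                hasOnlySubstanceUnits = "false",
                                boundaryCondition = "false",
                                constant = "false")
    if (!is.na(m$formula))
      xml2::xml_set_attr(node, "fbc:chemicalFormula", m$formula)
  }
  params <- xml2::xml_add_child(mdl, "listOfParameters")
  bound_ids <- character()
  add_bound <- function(value) {
    pid <- paste0("bnd_", gsub("[^0-9A-Za-z]", "_", format(value, digits = 12)))
    if (!pid %in% bound_ids) {
      xml2::xml_add_child(params, "parameter", id = pid,
                          value = format(value, digits = 15),
                          constant = "true")
      bound_ids <<- c(bound_ids, pid)
    }
    pid
  }
  genes <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes)
    xml2::xml_add_child(genes, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", sbml_safe_id(g)),
                        "fbc:label" = g)
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  add_gpr <- function(parent, tree) {
    switch(tree$kind,
      leaf = xml2::xml_add_child(parent, "fbc:geneProductRef",
                                 "fbc:geneProduct" = paste0("G_", sbml_safe_id(tree$gene))),
      and = { node <- xml2::xml_add_child(parent, "fbc:and")
              for (ch in tree$children) add_gpr(node, ch) },
      or = { node <- xml2::xml_add_child(parent, "fbc:or")
             for (ch in tree$children) add_gpr(node, ch) })
  }
  for (r in model$reactions) {
    node <- xml2::xml_add_child(
      rxs, "reaction", id = paste0("R_", sbml_safe_id(r$id)), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = add_bound(r$lower_bound),
      "fbc:upperFluxBound" = add_bound(r$upper_bound))
    if (nzchar(r$subsystem))
      xml2::xml_set_attr(node, "metaid", sbml_safe_id(paste0(r$id, "_", r$subsystem)))
    reac <- xml2::xml_add_child(node, "listOfReactants")
    prod <- xml2::xml_add_child(node, "listOfProducts")
    for (mid in names(r$stoichiometry)) {
      cf <- r$stoichiometry[[mid]]
      xml2::xml_add_child(if (cf < 0) reac else prod, "speciesReference",
                          species = mid,
                          stoichiometry = format(abs(cf), digits = 15),
                          constant = "true")
    }
    if (!gpr_is_empty(r$gpr)) {
      assoc <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      add_gpr(assoc, r$gpr)
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  lof <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lof, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", sbml_safe_id(model$objective)),
                      "fbc:coefficient" = "1")
  if (!is.na(model$gam))
    xml2::xml_set_attr(mdl, "metaid", paste0("gam_", format(model$gam)))
  xml2::write_xml(doc, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("model schema error: no <model> element in SBML file", call. = FALSE)
  mets <- lapply(xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns),
    function(sp) {
      metabolite(xml2::xml_attr(sp, "id"),
                 name = xml2::xml_attr(sp, "name"),
                 compartment = xml2::xml_attr(sp, "compartment"),
                 formula = {
                   f <- xml2::xml_attr(sp, "chemicalFormula")
                   if (is.na(f)) NA_character_ else f
                 })
    })
  param_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  params <- stats::setNames(as.numeric(xml2::xml_attr(param_nodes, "value")),
                            xml2::xml_attr(param_nodes, "id"))
  gene_nodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_label <- stats::setNames(xml2::xml_attr(gene_nodes, "label"),
                                xml2::xml_attr(gene_nodes, "id"))
  read_gpr <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      gpr_tree("leaf", gene = unname(gene_label[ref]))
    } else if (nm %in% c("and", "or")) {
      gpr_tree(nm, children = lapply(xml2::xml_children(node), read_gpr))
    } else stop("model schema error: unknown GPR element <", nm, ">",
                call. = FALSE)
  }
  rxns <- lapply(xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns),
    function(rn) {
      id <- sub("^R_", "", xml2::xml_attr(rn, "id"))
      lb <- params[[xml2::xml_attr(rn, "lowerFluxBound")]]
      ub <- params[[xml2::xml_attr(rn, "upperFluxBound")]]
      sto <- numeric()
      for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns))
        sto[xml2::xml_attr(sr, "species")] <-
          -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns))
        sto[xml2::xml_attr(sr, "species")] <-
          as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      assoc <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
      gpr <- if (inherits(assoc, "xml_missing")) gpr_tree("empty")
             else read_gpr(xml2::xml_child(assoc))
      meta <- xml2::xml_attr(rn, "metaid")
      subsystem <- if (!is.na(meta) && startsWith(meta, sbml_safe_id(paste0(id, "_"))))
        substring(meta, nchar(id) + 2L) else ""
      reaction(id, sto, lb, ub, gpr = gpr,
               name = xml2::xml_attr(rn, "name"), subsystem = subsystem)
    })
  obj_ref <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(obj_ref, "xml_missing"))
    stop("model schema error: SBML file lacks an FBC objective", call. = FALSE)
  objective <- sub("^R_", "", xml2::xml_attr(obj_ref, "reaction"))
  meta <- xml2::xml_attr(mdl, "metaid")
  gam <- if (!is.na(meta) && startsWith(meta, "gam_"))
    as.numeric(substring(meta, 5L)) else NA_real_
  metabolic_model(mets, rxns, objective = objective,
                  genes = unname(gene_label),
                  id = xml2::xml_attr(mdl, "id"), gam = gam)
}
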