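#' Single-gene deletion scan across conditions
#'
#' For every gene: reactions whose GPR evaluates to inactive with the gene
#' removed get both bounds set to zero, growth is re-optimised with plain FBA,
#' and the knockout/wild-type growth ratio is recorded. A gene appearing in no
#' GPR trivially keeps the wild-type optimum.
#'
#' @param model the base `metabolic_model` (supplies GPRs and gene list).
#' @param conditions named list of condition-bounded models (e.g. from
#'   [apply_medium()]); each must grow in the wild type.
#' @param genes genes to scan (default: all model genes).
#' @return A data frame with columns `condition`, `gene`, `mu_wt`, `mu_ko`,
#'   `growth_ratio` and `n_disabled` (reactions disabled by the knockout).
#' @export
single_gene_deletions <- function(model, conditions, genes = model$genes) {
  stopifnot(is.list(conditions), length(conditions) >= 1L,
            !is.null(names(conditions)))
  disabled_by_gene <- lapply(genes, function(g) {
    names(which(vapply(model$reactions, function(r)
      !gpr_active(r$gpr, g), logical(1))))
  })
  names(disabled_by_gene) <- genes
  rows <- list()
  for (cond in names(conditions)) {
    m <- conditions[[cond]]
    wt <- fba(m)
    if (wt$status != "optimal" || wt$mu <= 1e-9)
      stop("wild type does not grow in condition '", cond, "'", call. = FALSE)
    for (g in genes) {
      dis <- disabled_by_gene[[g]]
      mu_ko <- if (!length(dis)) wt$mu else {
        ko <- set_bounds(m, dis, lower = 0, upper = 0)
        sol <- fba(ko)
        if (sol$status == "optimal") sol$mu else 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, gene = g, mu_wt = wt$mu, mu_ko = mu_ko,
        growth_ratio = mu_ko / wt$mu, n_disabled = length(dis),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify deletion outcomes
#'
#' `essential` when the knockout optimum is at or below the zero tolerance
#' (null growth); `reduced_growth` when growth persists but drops by more than
#' `reduction_tol` relative to wild type; `no_effect` otherwise. Also reports
#' the per-condition essential sets and their intersection (genes essential on
#' every carbon source).
#'
#' @param results data frame from [single_gene_deletions()].
#' @param zero_tol absolute zero tolerance on the knockout growth rate (h^-1).
#' @param reduction_tol relative reduction distinguishing `reduced_growth`
#'   from numerically unchanged growth.
#' @return A list with `table` (the results plus a `class` column), `summary`
#'   (per condition: counts and percentages per class) and `core_essential`
#'   (genes essential in all conditions).
#' @export
classify_essentiality <- function(results, zero_tol = 1e-6,
                                  reduction_tol = 0.05) {
  cls <- ifelse(results$mu_ko <= zero_tol, "essential",
                ifelse(results$growth_ratio < 1 - reduction_tol,
                       "reduced_growth", "no_effect"))
  results$class <- factor(cls, levels = c("essential", "reduced_growth",
                                          "no_effect"))
  summary <- do.call(rbind, lapply(split(results, results$condition),
    function(d) {
      counts <- table(d$class)
      data.frame(condition = d$condition[1],
                 class = names(counts),
                 n = as.integer(counts),
                 percent = round(100 * as.integer(counts) / nrow(d), 1),
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  per_cond <- lapply(split(results, results$condition),
                     function(d) d$gene[d$class == "essential"])
  core <- Reduce(intersect, per_cond)
  list(table = results, summary = summary,
       essential_by_condition = per_cond, core_essential = core)
}

#' Write an essentiality table as TSV
#' @param classified result of [classify_essentiality()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_essentiality_tsv <- function(classified, path) {
  df <- classified$table[order(classified$table$condition,
                               classified$table$gene), ]
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
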