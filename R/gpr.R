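#' Gene-protein-reaction (GPR) boolean trees
#'
#' A GPR rule ties a reaction to the genes whose products catalyse it, using
#' `and` (all subunits required, e.g. an ABC transporter complex) and `or`
#' (isozymes) with parentheses. `gpr_tree()` nodes are lists with a `kind`
#' (`"leaf"`, `"and"`, `"or"` or `"empty"`), a `gene` id for leaves, and a
#' `children` list for operators. An empty rule means the reaction has no gene
#' association (typical for exchange and biomass pseudo-reactions) and is never
#' disabled by a knockout.
#'
#' @param kind node kind, one of `"leaf"`, `"and"`, `"or"`, `"empty"`.
#' @param gene gene identifier (leaf nodes only).
#' @param children list of child `gpr` nodes (`and`/`or` nodes, at least two).
#' @return An object of class `gpr`.
#' @export
gpr_tree <- function(kind = c("empty", "leaf", "and", "or"), gene = NULL,
                     children = list()) {
  kind <- match.arg(kind)
  if (kind == "leaf") {
    stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
    children <- list()
  } else if (kind %in% c("and", "or")) {
    if (length(children) < 2L)
      stop("'", kind, "' GPR nodes need at least two children", call. = FALSE)
    gene <- NULL
  } else {
    gene <- NULL
    children <- list()
  }
  structure(list(kind = kind, gene = gene, children = children), class = "gpr")
}

gpr_is_empty <- function(tree) inherits(tree, "gpr") && tree$kind == "empty"

#' Parse a GPR rule string
#'
#' Accepts the conventional rule dialect: gene identifiers combined with the
#' case-insensitive keywords `and` / `or` and parentheses. `and` binds more
#' tightly than `or`. Gene identifiers are opaque strings (anything that is not
#' a keyword or a parenthesis). An empty or all-whitespace string yields the
#' empty tree.
#'
#' @param text a single GPR rule string.
#' @return A `gpr` tree whose [serialize_gpr()] form is logically equivalent to
#'   the input.
#' @examples
#' parse_gpr("(geneA and geneB) or geneC")
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(gpr_tree("empty"))
  padded <- gsub("\\)", " ) ", gsub("\\(", " ( ", text))
  tokens <- strsplit(trimws(padded), "\\s+")[[1]]
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L

  peek <- function() if (state$pos <= length(state$tokens)) state$tokens[state$pos] else NA_character_
  advance <- function() state$pos <- state$pos + 1L
  fail <- function(msg) {
    stop(sprintf("GPR parse error at token %d ('%s'): %s",
                 state$pos, ifelse(is.na(peek()), "<end>", peek()), msg),
         call. = FALSE)
  }
  is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

  parse_or <- function() {
    parts <- list(parse_and())
    while (is_kw(peek(), "or")) {
      advance()
      parts <- c(parts, list(parse_and()))
    }
    if (length(parts) == 1L) parts[[1]] else gpr_tree("or", children = parts)
  }
  parse_and <- function() {
    parts <- list(parse_atom())
    while (is_kw(peek(), "and")) {
      advance()
      parts <- c(parts, list(parse_atom()))
    }
    if (length(parts) == 1L) parts[[1]] else gpr_tree("and", children = parts)
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) fail("expected a gene id or '('")
    if (tok == "(") {
      advance()
      inner <- parse_or()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(inner)
    }
    if (tok == ")") fail("unexpected ')'")
    if (tolower(tok) %in% c("and", "or")) fail("operator where a gene id was expected")
    advance()
    gpr_tree("leaf", gene = tok)
  }

  out <- parse_or()
  if (!is.na(peek())) fail("trailing input after a complete expression")
  out
}

#' Serialize a GPR tree back to rule text
#'
#' @param tree a `gpr` tree.
#' @return A rule string; `""` for the empty tree. Reparsing gives a logically
#'   equivalent tree.
#' @export
serialize_gpr <- function(tree) {
  stopifnot(inherits(tree, "gpr"))
  switch(tree$kind,
    empty = "",
    leaf = tree$gene,
    and = paste(vapply(tree$children, function(ch) {
      s <- serialize_gpr(ch)
      if (ch$kind == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    or = paste(vapply(tree$children, serialize_gpr, character(1)),
               collapse = " or ")
  )
}

#' Evaluate whether a reaction stays active under a gene knockout
#'
#' `and` nodes require all children active, `or` nodes at least one. The empty
#' tree is always active: a reaction without gene association cannot be removed
#' by a deletion.
#'
#' @param tree a `gpr` tree.
#' @param deleted_genes character vector of knocked-out gene ids.
#' @return `TRUE` if the reaction retains catalytic support.
#' @export
gpr_active <- function(tree, deleted_genes = character()) {
  stopifnot(inherits(tree, "gpr"))
  switch(tree$kind,
    empty = TRUE,
    leaf = !(tree$gene %in% deleted_genes),
    and = all(vapply(tree$children, gpr_active, logical(1), deleted_genes)),
    or = any(vapply(tree$children, gpr_active, logical(1), deleted_genes))
  )
}

#' Map gene expression onto a reaction through its GPR
#'
#' Follows the standard transcriptome-integration convention: an `and`
#' association is only as expressed as its lowest-expressed subunit (min),
#' while an `or` association is as expressed as its highest-expressed isozyme
#' (max). The empty tree returns `NA`: such reactions are never thresholded.
#' Genes missing from `expression` are treated as unmeasured, not silent
#' (`Inf`, i.e. never able to drag an `and` down or win an `or` cap); if the
#' whole rule is unmeasured the result is `Inf`, meaning "never penalized".
#'
#' @param tree a `gpr` tree.
#' @param expression named numeric vector of nonnegative normalized counts.
#' @return A single numeric value, `NA` for the empty tree.
#' @export
gpr_expression <- function(tree, expression) {
  stopifnot(inherits(tree, "gpr"), is.numeric(expression))
  switch(tree$kind,
    empty = NA_real_,
    leaf = {
      v <- expression[tree$gene]
      if (length(v) == 0L || is.na(v)) Inf else unname(v)
    },
    and = min(vapply(tree$children, gpr_expression, numeric(1), expression)),
    or = max(vapply(tree$children, gpr_expression, numeric(1), expression))
  )
}

#' List the genes referenced by a GPR tree
#'
#' @param tree a `gpr` tree.
#' @return Character vector of unique gene ids (empty for the empty tree).
#' @export
gpr_genes <- function(tree) {
  stopifnot(inherits(tree, "gpr"))
  switch(tree$kind,
    empty = character(),
    leaf = tree$gene,
    unique(unlist(lapply(tree$children, gpr_genes)))
  )
}

#' @export
print.gpr <- function(x, ...) {
  cat("<GPR> ", if (gpr_is_empty(x)) "(no gene association)" else serialize_gpr(x),
      "\n", sep = "")
  invisible(x)
}
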