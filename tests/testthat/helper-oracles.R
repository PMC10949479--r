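# Independent oracles: brute-force implementations used only to generate
# expected values, never sharing code paths with the package internals.

# --- boolean GPR oracle: evaluate the rule text as an R logical expression
oracle_gpr_eval <- function(rule, active) {
  if (!nzchar(trimws(rule))) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule,
                                      ignore.case = TRUE), ignore.case = TRUE)
  env <- list2env(as.list(active))
  isTRUE(eval(parse(text = expr), envir = env))
}

# --- vertex enumeration of {A v = b, lb <= v <= ub} by activating n - rank
#     bound constraints at a time
oracle_vertices <- function(A, b, lb, ub, tol = 1e-8) {
  n <- ncol(A)
  qa <- qr(t(A), tol = 1e-10)
  keep <- sort(qa$pivot[seq_len(qa$rank)])
  A <- A[keep, , drop = FALSE]
  b <- b[keep]
  r <- nrow(A)
  free_count <- n - r
  verts <- list()
  add_vertex <- function(v) {
    for (w in verts) if (max(abs(w - v)) < 1e-6) return(invisible())
    verts[[length(verts) + 1L]] <<- v
  }
  fixed_sets <- utils::combn(n, free_count, simplify = FALSE)
  if (free_count == 0L) fixed_sets <- list(integer())
  for (Fset in fixed_sets) {
    Bset <- setdiff(seq_len(n), Fset)
    AB <- A[, Bset, drop = FALSE]
    if (length(Bset) && abs(det(AB)) < 1e-10) next
    n_assign <- 2^length(Fset)
    for (mask in seq_len(max(n_assign, 1)) - 1L) {
      vF <- numeric(length(Fset))
      ok <- TRUE
      for (t in seq_along(Fset)) {
        at_ub <- bitwAnd(mask, bitwShiftL(1L, t - 1L)) > 0
        val <- if (at_ub) ub[Fset[t]] else lb[Fset[t]]
        if (!is.finite(val)) { ok <- FALSE; break }
        vF[t] <- val
      }
      if (!ok) next
      rhs <- b - if (length(Fset)) A[, Fset, drop = FALSE] %*% vF else 0
      vB <- if (length(Bset)) tryCatch(solve(AB, rhs),
                                       error = function(e) NULL) else numeric()
      if (is.null(vB)) next
      v <- numeric(n)
      v[Fset] <- vF
      v[Bset] <- vB
      if (all(v >= lb - tol) && all(v <= ub + tol)) add_vertex(v)
    }
  }
  verts
}

oracle_vertices_model <- function(model) {
  S <- build_stoich_matrix(model)
  oracle_vertices(S, numeric(nrow(S)), lower_bounds(model),
                  upper_bounds(model))
}

# --- flux-cone extreme rays by per-orthant support enumeration; coupling
#     relations derived from the aggregated ray set
oracle_rays <- function(model, tol = 1e-8) {
  S <- build_stoich_matrix(model)
  lb <- lower_bounds(model)
  ub <- upper_bounds(model)
  n <- ncol(S)
  rev_idx <- which(lb < -tol & ub > tol)
  fwd_only <- lb >= -tol & ub > tol
  bwd_only <- ub <= tol & lb < -tol
  dead <- lb >= -tol & ub <= tol
  rays <- list()
  add_ray <- function(v) {
    nv <- v / sqrt(sum(v^2))
    for (w in rays) if (max(abs(w - nv)) < 1e-6) return(invisible())
    rays[[length(rays) + 1L]] <<- nv
  }
  orthants <- expand.grid(rep(list(c(1, -1)), length(rev_idx)))
  if (!nrow(orthants)) orthants <- data.frame(row.names = 1)
  for (o in seq_len(nrow(orthants))) {
    sgn <- rep(1, n)
    sgn[bwd_only] <- -1
    if (length(rev_idx)) sgn[rev_idx] <- as.numeric(orthants[o, ])
    sgn[dead] <- 0
    cols <- which(sgn != 0)
    Ao <- S[, cols, drop = FALSE] * rep(sgn[cols], each = nrow(S))
    for (size in seq_len(length(cols))) {
      for (Tset in utils::combn(length(cols), size, simplify = FALSE)) {
        AT <- Ao[, Tset, drop = FALSE]
        if (qr(AT, tol = 1e-10)$rank != length(Tset) - 1L) next
        ATp <- rbind(AT, matrix(0, max(0L, ncol(AT) - nrow(AT) + 1L),
                                ncol(AT)))
        sv <- svd(ATp)
        ns <- sv$v[, ncol(ATp)]
        if (max(abs(AT %*% ns)) > 1e-8) next
        if (all(ns >= -tol)) k <- ns
        else if (all(ns <= tol)) k <- -ns
        else next
        if (any(k[seq_along(Tset)] <= tol)) next  # support must be exactly T
        w <- numeric(n)
        w[cols[Tset]] <- k
        add_ray(w * sgn)
      }
    }
  }
  # minimal-support filter
  supports <- lapply(rays, function(r) which(abs(r) > 1e-7))
  minimal <- vapply(seq_along(rays), function(i) {
    !any(vapply(seq_along(rays), function(j)
      j != i && length(supports[[j]]) < length(supports[[i]]) &&
        all(supports[[j]] %in% supports[[i]]), logical(1)))
  }, logical(1))
  mat <- do.call(rbind, rays[minimal])
  if (is.null(mat)) mat <- matrix(0, 0, n)
  colnames(mat) <- rxn_ids(model)
  mat
}

oracle_coupling <- function(model, tol = 1e-7) {
  rays <- oracle_rays(model)
  ids <- colnames(rays)
  n <- length(ids)
  active <- abs(rays) > tol
  blocked <- ids[colSums(active) == 0]
  keep <- setdiff(ids, blocked)
  forces <- function(a, b) !any(active[, a] & !active[, b])
  rows <- list()
  for (i in seq_along(keep)) for (j in seq_along(keep)) {
    if (j <= i) next
    a <- keep[i]; b <- keep[j]
    fab <- forces(a, b)
    fba <- forces(b, a)
    type <- if (fab && fba) {
      sel <- active[, b]
      rr <- rays[sel, a] / rays[sel, b]
      if (length(rr) && max(rr) - min(rr) <= 1e-6 * max(1, abs(rr[1])))
        "fully" else "partially"
    } else if (fab) "directional_a_to_b"
      else if (fba) "directional_b_to_a"
      else "uncoupled"
    ratio <- if (type == "fully") {
      sel <- active[, b]
      mean(rays[sel, a] / rays[sel, b])
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      reaction_a = a, reaction_b = b, type = type, ratio = ratio,
      stringsAsFactors = FALSE)
  }
  list(blocked = blocked,
       relations = if (length(rows)) do.call(rbind, rows) else NULL)
}
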