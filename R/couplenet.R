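#' Flux coupling analysis
#'
#' Classifies every pair of unblocked reactions by the geometry of the steady
#' state flux cone: reaction bounds contribute only their signs
#' (irreversibility), not their magnitudes, and any ratio-constraint rows
#' participate. Two reactions are fully coupled when their fluxes keep a fixed
#' nonzero ratio in every steady state, partially coupled when each forces the
#' other without a fixed ratio, directionally coupled when flux through one
#' implies flux through the other but not conversely, and uncoupled otherwise.
#' For reversible reactions the relation is determined over all
#' sign-consistent flux directions (`type = "directional_a_to_b"` means
#' nonzero flux through `reaction_a` implies nonzero flux through
#' `reaction_b`).
#'
#' Implementation: blocked reactions are removed first; fully coupled classes
#' are read off the nullspace of the reduced stoichiometry (on a consistent
#' subnetwork, fixed flux ratios are exactly proportional nullspace rows);
#' relations between the remaining classes are decided by signed feasibility
#' LPs (is there a steady state using reaction a but not b?).
#'
#' @param model a `metabolic_model` (ratio rows add couplings).
#' @param tol zero/proportionality tolerance.
#' @param big finite stand-in for the cone's unbounded reversible directions.
#' @return An `fca_result`: `relations` (data frame `reaction_a`,
#'   `reaction_b`, `type`, `ratio` — ratio only for fully coupled pairs,
#'   negative when the pair runs antiparallel), `blocked`, and `reactions`
#'   (ids analysed).
#' @export
fca <- function(model, tol = 1e-6, big = 1e6) {
  blocked <- blocked_reactions(model)
  keep <- setdiff(rxn_ids(model), blocked)
  n <- length(keep)
  empty <- data.frame(reaction_a = character(), reaction_b = character(),
                      type = character(), ratio = numeric(),
                      stringsAsFactors = FALSE)
  if (n < 2L)
    return(structure(list(relations = empty, blocked = blocked,
                          reactions = keep), class = "fca_result"))
  lpd <- model_lp_data(model)
  idx <- match(keep, lpd$rxns)
  A <- lpd$A[, idx, drop = FALSE]
  lo <- ifelse(lpd$lb[idx] < -tol, -big, 0)
  hi <- ifelse(lpd$ub[idx] > tol, Inf, 0)
  zero_obj <- numeric(n)

  cone_feasible <- function(fix_idx, fix_val) {
    lb <- lo; ub <- hi
    lb[fix_idx] <- fix_val; ub[fix_idx] <- fix_val
    identical(solve_lp(zero_obj, A, lb = lb, ub = ub,
                       direction = "min")$status, "optimal")
  }

  usable_pos <- vapply(seq_len(n), function(k)
    hi[k] > 0 && cone_feasible(k, 1), logical(1))
  usable_neg <- vapply(seq_len(n), function(k)
    lo[k] < 0 && cone_feasible(k, -1), logical(1))

  # fully coupled classes from nullspace row proportionality
  qt <- qr(t(A), tol = 1e-10)
  rank <- qt$rank
  Qc <- qr.Q(qt, complete = TRUE)
  N <- if (rank < n) Qc[, (rank + 1L):n, drop = FALSE] else
    matrix(0, n, 0)
  class_id <- integer(n)
  ratios <- rep(NA_real_, n)        # ratio to the class representative
  next_class <- 0L
  for (k in seq_len(n)) {
    if (class_id[k] != 0L) next
    next_class <- next_class + 1L
    class_id[k] <- next_class
    ratios[k] <- 1
    nk <- N[k, ]
    nk2 <- sum(nk^2)
    if (nk2 <= 1e-16) next          # defensively: zero row, stays singleton
    for (j in seq_len(n)) {
      if (class_id[j] != 0L) next
      nj <- N[j, ]
      nj_norm <- sqrt(sum(nj^2))
      if (nj_norm <= 1e-8) next
      r <- sum(nj * nk) / nk2
      if (abs(r) > tol && sqrt(sum((nj - r * nk)^2)) <= 1e-7 * nj_norm) {
        class_id[j] <- next_class
        ratios[j] <- r
      }
    }
  }
  reps <- vapply(seq_len(next_class), function(cl)
    which(class_id == cl)[1L], integer(1))

  # a "forces" b when no steady state uses a without b
  forces <- function(a, b) {
    if (usable_pos[a] && {
      lb <- lo; ub <- hi
      lb[a] <- 1; ub[a] <- 1; lb[b] <- 0; ub[b] <- 0
      identical(solve_lp(zero_obj, A, lb = lb, ub = ub,
                         direction = "min")$status, "optimal")
    }) return(FALSE)
    if (usable_neg[a] && {
      lb <- lo; ub <- hi
      lb[a] <- -1; ub[a] <- -1; lb[b] <- 0; ub[b] <- 0
      identical(solve_lp(zero_obj, A, lb = lb, ub = ub,
                         direction = "min")$status, "optimal")
    }) return(FALSE)
    TRUE
  }

  nrep <- length(reps)
  rep_type <- matrix("", nrep, nrep)
  for (ai in seq_len(nrep)) for (bi in seq_len(nrep)) {
    if (bi <= ai) next
    a <- reps[ai]; b <- reps[bi]
    fab <- forces(a, b)
    fba <- forces(b, a)
    rep_type[ai, bi] <- if (fab && fba) "partially"
      else if (fab) "directional_a_to_b"
      else if (fba) "directional_b_to_a"
      else "uncoupled"
  }

  rows <- vector("list", n * (n - 1L) / 2L)
  cnt <- 0L
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    cnt <- cnt + 1L
    ca <- class_id[a]; cb <- class_id[b]
    if (ca == cb) {
      rows[[cnt]] <- data.frame(reaction_a = keep[a], reaction_b = keep[b],
                                type = "fully",
                                ratio = ratios[a] / ratios[b],
                                stringsAsFactors = FALSE)
    } else {
      ai <- min(ca, cb); bi <- max(ca, cb)
      ty <- rep_type[ai, bi]
      if (ca > cb) {                 # orientation follows the pair order
        if (ty == "directional_a_to_b") ty <- "directional_b_to_a"
        else if (ty == "directional_b_to_a") ty <- "directional_a_to_b"
      }
      rows[[cnt]] <- data.frame(reaction_a = keep[a], reaction_b = keep[b],
                                type = ty, ratio = NA_real_,
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(relations = do.call(rbind, rows), blocked = blocked,
                 reactions = keep),
            class = "fca_result")
}

#' Coupled-reaction network around end-product exchanges
#'
#' Builds the undirected network whose nodes are the seed exchanges plus every
#' reaction fully or partially coupled (transitively, within the coupled
#' component) to at least one seed, with typed full/partial edges. Directional
#' relations do not create edges. A seed with no couplings (e.g. a blocked
#' product exchange) stays as an isolated node, with a warning.
#'
#' @param coupling an [fca()] result.
#' @param seed_exchanges exchange reaction ids to anchor the network.
#' @param model optional model used to annotate nodes with subsystems.
#' @param condition label stored on the network.
#' @return An object of class `reaction_network` wrapping an igraph graph.
#' @export
build_coupled_network <- function(coupling, seed_exchanges, model = NULL,
                                  condition = "network") {
  stopifnot(inherits(coupling, "fca_result"))
  rel <- coupling$relations
  edges <- rel[rel$type %in% c("fully", "partially"), , drop = FALSE]
  all_nodes <- unique(c(seed_exchanges, edges$reaction_a, edges$reaction_b))
  g_all <- igraph::graph_from_data_frame(
    edges[, c("reaction_a", "reaction_b")],
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g_all)
  seed_comps <- unique(comp$membership[seed_exchanges[seed_exchanges %in%
                                                        names(comp$membership)]])
  keep_nodes <- names(comp$membership)[comp$membership %in% seed_comps]
  sel <- edges$reaction_a %in% keep_nodes & edges$reaction_b %in% keep_nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$reaction_a[sel], to = edges$reaction_b[sel],
               type = ifelse(edges$type[sel] == "fully", "full", "partial"),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(keep_nodes), stringsAsFactors = FALSE))
  isolated <- seed_exchanges[igraph::degree(g)[seed_exchanges] == 0]
  if (length(isolated))
    warning("seed exchange(s) without couplings kept as isolated nodes: ",
            paste(isolated, collapse = ", "))
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% seed_exchanges
  if (!is.null(model)) {
    subsys <- vapply(igraph::V(g)$name, function(id)
      if (id %in% rxn_ids(model)) model$reactions[[id]]$subsystem else "",
      character(1))
    igraph::V(g)$subsystem <- subsys
  }
  structure(list(graph = g, seeds = seed_exchanges, condition = condition),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network '%s'> %d nodes, %d edges (%d seeds)\n",
              x$condition, igraph::gorder(x$graph), igraph::gsize(x$graph),
              length(x$seeds)))
  invisible(x)
}

#' Topology metrics of a coupled-reaction network
#'
#' Node/edge counts; mean local clustering coefficient over all nodes with
#' degree-below-2 nodes contributing 0 (the convention of mainstream graph
#' tools, so values are comparable across networks); the degree sequence;
#' unweighted shortest-path edge betweenness; and a power-law fit to the
#' degree distribution (exponent and KS statistic, reported descriptively).
#'
#' @param network a `reaction_network` (or bare igraph graph).
#' @return A list with `n_nodes`, `n_edges`, `clustering_coefficient`,
#'   `degree_sequence`, `edge_betweenness` and `power_law` (`alpha`, `ks_stat`
#'   or `NA` when fewer than two nodes have positive degree).
#' @export
topology_metrics <- function(network) {
  g <- if (inherits(network, "reaction_network")) network$graph else network
  local_cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  deg <- igraph::degree(g)
  pl <- if (sum(deg > 0) >= 2) {
    fit <- igraph::fit_power_law(deg[deg > 0], implementation = "plfit")
    list(alpha = fit$alpha, ks_stat = fit$KS.stat)
  } else list(alpha = NA_real_, ks_stat = NA_real_)
  list(n_nodes = igraph::gorder(g),
       n_edges = igraph::gsize(g),
       clustering_coefficient = if (igraph::gorder(g)) mean(local_cc) else NA_real_,
       degree_sequence = sort(deg, decreasing = TRUE),
       edge_betweenness = igraph::edge_betweenness(g, directed = FALSE),
       power_law = pl)
}

#' Cross-condition rewiring scores and consensus network
#'
#' The consensus is the union of all nodes and edges, each edge annotated with
#' the number of condition networks containing it. Per node, the rewiring
#' score is the mean Euclidean distance between each network's binary
#' neighbour-incidence vector (over the union of the node's neighbours across
#' networks containing it) and their centroid, normalised by the node's mean
#' degree — 0 exactly when the neighbourhood is identical in every network
#' containing the node.
#'
#' @param networks list of >= 2 `reaction_network` objects with comparable
#'   node ids.
#' @return A list with `scores` (data frame: `node`, `dn_score`, one logical
#'   presence column per network) and `consensus` (igraph graph with
#'   `multiplicity` edge attribute and `dn` node attribute).
#' @export
dn_rewiring <- function(networks) {
  if (length(networks) < 2L)
    stop("rewiring needs at least two networks", call. = FALSE)
  graphs <- lapply(networks, function(nw)
    if (inherits(nw, "reaction_network")) nw$graph else nw)
  labels <- vapply(seq_along(networks), function(k) {
    nw <- networks[[k]]
    if (inherits(nw, "reaction_network") && nzchar(nw$condition)) nw$condition
    else paste0("network", k)
  }, character(1))
  neigh <- lapply(graphs, function(g) {
    ns <- lapply(igraph::V(g)$name, function(v)
      igraph::neighbors(g, v)$name)
    stats::setNames(ns, igraph::V(g)$name)
  })
  nodes <- sort(unique(unlist(lapply(graphs, function(g) igraph::V(g)$name))))
  presence <- vapply(neigh, function(nb) nodes %in% names(nb), logical(length(nodes)))
  presence <- matrix(presence, nrow = length(nodes),
                     dimnames = list(nodes, labels))
  dn <- vapply(nodes, function(u) {
    in_nets <- which(presence[u, ])
    if (length(in_nets) < 2L) return(0)
    sets <- lapply(in_nets, function(k) neigh[[k]][[u]])
    universe <- unique(unlist(sets))
    if (!length(universe)) return(0)
    B <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    B <- matrix(as.numeric(B), nrow = length(universe))
    centroid <- rowMeans(B)
    dists <- sqrt(colSums((B - centroid)^2))
    mean_deg <- mean(colSums(B))
    if (mean_deg == 0) 0 else mean(dists) / mean_deg
  }, numeric(1))

  edge_keys <- lapply(graphs, function(g) {
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) return(character())
    apply(t(apply(el, 1, sort)), 1, paste, collapse = "\r")
  })
  all_keys <- unlist(edge_keys)
  mult <- table(all_keys)
  uniq <- names(mult)
  parts <- do.call(rbind, strsplit(uniq, "\r", fixed = TRUE))
  consensus <- igraph::graph_from_data_frame(
    data.frame(from = parts[, 1], to = parts[, 2],
               multiplicity = as.integer(mult), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, dn = unname(dn),
                          stringsAsFactors = FALSE))
  scores <- data.frame(node = nodes, dn_score = unname(dn),
                       stringsAsFactors = FALSE)
  for (k in seq_along(labels)) scores[[labels[k]]] <- presence[, k]
  list(scores = scores[order(-scores$dn_score, scores$node), ],
       consensus = consensus)
}

#' Export a network as GraphML
#'
#' @param network a `reaction_network` or igraph graph (e.g. the consensus
#'   from [dn_rewiring()]); edge betweenness is attached before writing.
#' @param path output `.graphml` file.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- if (inherits(network, "reaction_network")) network$graph else network
  igraph::E(g)$betweenness <- igraph::edge_betweenness(g, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
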