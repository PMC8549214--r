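#' Typed molecular network
#'
#' An undirected, weighted graph over gene and metabolite nodes, used for
#' protein-protein interaction (PPI) analysis and for integrated
#' metabolite-gene networks. Self-loops are disallowed and all edge weights
#' must be positive.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `weight`
#'   (defaults to 1).
#' @param nodes optional data.frame with columns `id` and `kind`
#'   (`"gene"` or `"metabolite"`); nodes appearing only in `edges` default to
#'   kind `"gene"`.
#' @return An object of class `molecular_network` wrapping an
#'   [igraph::graph] with vertex attribute `kind`.
#' @export
molecular_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges must have 'from' and 'to' columns")
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$weight <= 0)) stop("edge weights must be > 0")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  ids <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- data.frame(id = ids, kind = "gene", stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes)
    if (!all(ids %in% nodes$id))
      stop("every edge endpoint must appear in nodes")
    if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = nodes
  )
  structure(list(graph = g), class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  k <- table(igraph::V(x$graph)$kind)
  cat(sprintf("<molecular_network> %d nodes (%s), %d edges\n",
              igraph::vcount(x$graph),
              paste(sprintf("%s=%d", names(k), k), collapse = ", "),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Node ids of a molecular network
#' @param net a [molecular_network].
#' @return Character vector of node ids.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Score nodes by label propagation from a seed set
#'
#' Graph diffusion in the normalized-adjacency form: with `W` the weighted
#' adjacency matrix, `D` the diagonal strength matrix and
#' `S = D^(-1/2) W D^(-1/2)`, iterate `F <- alpha * S F + (1 - alpha) * Y`
#' from the seed indicator `Y` until the sup-norm change falls below `tol`.
#' The fixed point equals the closed form
#' `(1 - alpha) * (I - alpha * S)^(-1) Y`, which is how functional
#' association platforms rank candidate genes around an input list.
#'
#' @param net a [molecular_network].
#' @param seeds character vector of seed node ids (must exist in `net`).
#' @param alpha restart/spreading parameter in `[0, 1)`.
#' @param tol convergence tolerance on the sup-norm of the score update.
#' @param max_iter iteration cap.
#' @return A `propagation_result`: list with `scores` (named, >= 0),
#'   `seeds`, `alpha`, `iterations`, `converged`.
#' @export
label_propagate <- function(net, seeds, alpha = 0.5, tol = 1e-9,
                            max_iter = 1000L) {
  stopifnot(inherits(net, "molecular_network"))
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  ids <- network_nodes(net)
  if (!all(seeds %in% ids)) stop("all seeds must be nodes of the network")
  S <- .norm_adjacency(net)
  y <- as.numeric(ids %in% seeds)
  f <- y
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f_new <- as.numeric(alpha * (S %*% f)) + (1 - alpha) * y
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  structure(
    list(scores = setNames(f, ids), seeds = seeds, alpha = alpha,
         iterations = iter, converged = converged),
    class = "propagation_result"
  )
}

#' Closed-form solution of the propagation system
#'
#' Direct dense linear solve of `(I - alpha * S) F = (1 - alpha) * Y`; used
#' as the independent cross-check of the iterative solver on small graphs.
#'
#' @inheritParams label_propagate
#' @return Named numeric vector of scores.
#' @export
propagate_exact <- function(net, seeds, alpha = 0.5) {
  ids <- network_nodes(net)
  S <- .norm_adjacency(net)
  y <- as.numeric(ids %in% seeds)
  setNames(as.numeric(solve(diag(length(ids)) - alpha * S,
                            (1 - alpha) * y)), ids)
}

# Symmetrically normalized adjacency D^(-1/2) W D^(-1/2); zero rows for
# isolated nodes.
.norm_adjacency <- function(net) {
  W <- as.matrix(igraph::as_adjacency_matrix(net$graph, attr = "weight"))
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  dinv * W * rep(dinv, each = nrow(W))
}

#' Expand a seed gene list with the top-scoring propagated genes
#'
#' Adds the `k` highest-scoring non-seed nodes to the seed set (ties broken
#' by score descending then node id ascending, so the result is
#' reproducible) and returns the subnetwork induced on the augmented set.
#'
#' @param net a [molecular_network].
#' @param result a `propagation_result` from [label_propagate()].
#' @param k number of non-seed genes to add (default 10).
#' @return List with `genes` (augmented id set), `added` (the new ids in
#'   rank order) and `subnetwork` (a [molecular_network]).
#' @export
expand_top_k <- function(net, result, k = 10L) {
  stopifnot(inherits(result, "propagation_result"))
  if (!result$converged) stop("propagation did not converge")
  non_seed <- setdiff(names(result$scores), result$seeds)
  sc <- result$scores[non_seed]
  ord <- non_seed[order(-sc, non_seed)]
  if (k > length(ord)) {
    warning("fewer than k scorable non-seed nodes; returning all")
    k <- length(ord)
  }
  added <- if (k > 0) ord[seq_len(k)] else character(0)
  genes <- c(result$seeds, added)
  sub <- igraph::induced_subgraph(net$graph, genes)
  structure(
    list(genes = genes, added = added,
         subnetwork = structure(list(graph = sub),
                                class = "molecular_network")),
    class = "expanded_gene_set"
  )
}

#' Extract an integrated metabolite-gene subnetwork around seed molecules
#'
#' Builds the subgraph induced on (i) seed metabolites and seed genes that
#' match nodes of the association graph and (ii) "bridge" nodes: non-seed
#' nodes adjacent to at least two matched seeds. Matched seeds that end up
#' with no connection in the subnetwork are dropped. Each retained node is
#' annotated with its origin: `"DM"`, `"DP"`, `"target"` or `"bridge"`.
#'
#' @param net a [molecular_network] of metabolite-gene associations.
#' @param seed_mets character vector of differential-metabolite ids.
#' @param seed_genes character vector of differential-protein/gene ids.
#' @param seed_targets optional character vector of formula signature-target
#'   ids, annotated separately from `seed_genes`.
#' @param min_seed_neighbors minimum matched-seed adjacency for a non-seed
#'   node to be kept as a bridge (default 2; 1 reproduces plain first-order
#'   neighborhoods).
#' @return List with `network` (a [molecular_network]), `nodes`
#'   (data.frame: id, kind, origin) and `unmatched` (seed ids absent from
#'   the graph).
#' @export
extract_metabolite_gene_network <- function(net, seed_mets, seed_genes,
                                            seed_targets = character(0),
                                            min_seed_neighbors = 2L) {
  stopifnot(inherits(net, "molecular_network"))
  ids <- network_nodes(net)
  seeds_all <- unique(c(seed_mets, seed_genes, seed_targets))
  matched <- intersect(seeds_all, ids)
  unmatched <- setdiff(seeds_all, ids)
  if (length(matched) == 0) {
    warning("no seed matched the network; returning empty network")
    empty <- structure(
      list(graph = igraph::make_empty_graph(directed = FALSE)),
      class = "molecular_network")
    return(list(network = empty,
                nodes = data.frame(id = character(0), kind = character(0),
                                   origin = character(0)),
                unmatched = unmatched))
  }
  g <- net$graph
  adj <- igraph::adjacent_vertices(g, matched)
  # count, for every node, how many matched seeds it neighbors
  nb <- table(unlist(lapply(adj, function(v) v$name)))
  bridge <- setdiff(names(nb)[nb >= min_seed_neighbors], matched)
  keep <- c(matched, bridge)
  sub <- igraph::induced_subgraph(g, keep)
  deg <- igraph::degree(sub)
  drop <- intersect(names(deg)[deg == 0], matched)
  if (length(drop)) sub <- igraph::delete_vertices(sub, drop)
  kept <- igraph::V(sub)$name
  origin <- ifelse(kept %in% seed_mets, "DM",
            ifelse(kept %in% seed_genes, "DP",
            ifelse(kept %in% seed_targets, "target", "bridge")))
  list(
    network = structure(list(graph = sub), class = "molecular_network"),
    nodes = data.frame(id = kept, kind = igraph::V(sub)$kind,
                       origin = origin, stringsAsFactors = FALSE),
    unmatched = unmatched
  )
}
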