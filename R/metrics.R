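as_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Binary network edge density
#'
#' Number of realized connections (positive SRI) divided by all potential
#' connections `n(n-1)/2`.
#'
#' @param network a [build_network()] result.
#' @return ratio in \[0, 1\].
#' @export
edge_density <- function(network) {
  n <- nrow(network$weights)
  if (n < 2) stop("edge density undefined for fewer than 2 nodes", call. = FALSE)
  sum(network$weights[upper.tri(network$weights)] > 0) / (n * (n - 1) / 2)
}

#' Global clustering coefficient (transitivity)
#'
#' Ratio of three times the triangle count to the number of connected
#' triples, on the binary positive-weight skeleton.
#'
#' @param network a [build_network()] result.
#' @return ratio in \[0, 1\], or `NA` when the network has no connected
#'   triple (the metric is then undefined and the network is excluded
#'   downstream).
#' @export
global_clustering <- function(network) {
  a <- (network$weights > 0) * 1
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(NA_real_)
  triangles <- sum(diag(a %*% a %*% a)) / 6
  3 * triangles / triples
}

#' Mean edge weight
#'
#' Arithmetic mean of the non-zero SRI edge weights.
#'
#' @param network a [build_network()] result.
#' @return mean SRI in (0, 1\]; errors when the network has no positive edge.
#' @export
mean_edge_weight <- function(network) {
  w <- network$weights[upper.tri(network$weights)]
  w <- w[w > 0]
  if (length(w) == 0) stop("no positive edges: mean edge weight undefined",
                           call. = FALSE)
  mean(w)
}

#' Weighted modularity of a node partition
#'
#' Configuration-model modularity
#' \eqn{Q = \sum_c (e_c/W - (s_c/2W)^2)} with `W` the total edge weight,
#' `e_c` the within-community weight and `s_c` the community strength.
#'
#' @param network a [build_network()] result.
#' @param membership integer community label per node (in node order).
#' @return Q.
#' @export
modularity_q <- function(network, membership) {
  g <- as_igraph(network)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}

#' Edge-betweenness (Girvan-Newman) communities with the best-Q cut
#'
#' Builds the Girvan-Newman dendrogram by iterative removal of the
#' maximum-betweenness edge (delegated to igraph's C implementation, which
#' breaks ties deterministically by internal edge order), then evaluates
#' weighted modularity at every dendrogram cut and returns the maximizing
#' partition. Betweenness is computed with edge length `1/weight` (stronger
#' ties are shorter paths) unless `binary_gn = TRUE`, in which case all
#' edges count equally; modularity always uses the SRI weights as strengths.
#'
#' @param network a [build_network()] result with at least 2 positive edges.
#' @param binary_gn logical; ignore weights in the betweenness computation.
#' @return list: `membership` (named integer vector), `modularity` (Q of the
#'   returned partition), `n_communities`.
#' @export
edge_betweenness_communities <- function(network, binary_gn = FALSE) {
  g0 <- as_igraph(network)
  if (igraph::ecount(g0) < 2) {
    stop("community detection requires at least 2 edges", call. = FALSE)
  }
  w0 <- igraph::E(g0)$weight
  nodes <- igraph::V(g0)$name
  n <- length(nodes)

  len <- if (binary_gn) NULL else 1 / w0
  comm <- suppressWarnings(igraph::cluster_edge_betweenness(
    g0, weights = len, modularity = FALSE, membership = FALSE
  ))
  best_m <- igraph::components(g0)$membership
  best_q <- igraph::modularity(g0, best_m, weights = w0)
  for (k in seq_len(n)) {
    # cut_at warns when k is below the component count; those cuts do not exist
    m <- tryCatch(suppressWarnings(igraph::cut_at(comm, no = k)),
                  error = function(e) NULL)
    if (is.null(m)) next
    q <- igraph::modularity(g0, m, weights = w0)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_m <- m
    }
  }
  list(membership = stats::setNames(as.integer(best_m), nodes),
       modularity = best_q,
       n_communities = length(unique(best_m)))
}

#' Assemble the full metric set of one network
#'
#' Computes the four global metrics plus the classification flags used by
#' the downstream filters. Metrics whose preconditions fail (no triple, no
#' positive edge, fewer than 2 edges for community detection) are reported
#' as `NA` and the reason recorded.
#'
#' @param network a [build_network()] result.
#' @param binary_gn passed to [edge_betweenness_communities()].
#' @param zero_q_threshold threshold below which modularity is classified as
#'   "zero" (default 0.0001).
#' @return one-row data.frame: location_id, year, week, population_size,
#'   n_edges, fully_connected, usable_for_metrics, edge_density,
#'   global_clustering, mean_edge_weight, modularity_q, zero_modularity_flag,
#'   long_event_flag, notes.
#' @export
summarize_network <- function(network, binary_gn = FALSE,
                              zero_q_threshold = 1e-4) {
  cls <- classify_network(network)
  meta <- network$meta
  n <- nrow(network$weights)
  notes <- character(0)

  dens <- if (n >= 2) edge_density(network) else NA_real_
  if (n < 2) notes <- c(notes, "single node")
  clus <- global_clustering_or_na(network, notes)
  notes <- attr(clus, "notes")
  mew <- if (cls$n_edges >= 1) mean_edge_weight(network) else NA_real_
  if (cls$n_edges < 1) notes <- c(notes, "no positive edge")
  q <- NA_real_
  if (cls$n_edges >= 2) {
    q <- edge_betweenness_communities(network, binary_gn = binary_gn)$modularity
  } else {
    notes <- c(notes, "fewer than 2 edges: no community structure")
  }
  data.frame(
    location_id = meta$location_id, year = meta$year, week = meta$week,
    population_size = meta$population_size,
    n_edges = cls$n_edges,
    fully_connected = cls$fully_connected,
    usable_for_metrics = cls$usable_for_metrics,
    edge_density = dens,
    global_clustering = as.numeric(clus),
    mean_edge_weight = mew,
    modularity_q = q,
    zero_modularity_flag = if (is.na(q)) NA else q <= zero_q_threshold,
    long_event_flag = meta$long_event_flag,
    notes = paste(notes, collapse = "; "),
    stringsAsFactors = FALSE
  )
}

global_clustering_or_na <- function(network, notes) {
  n <- nrow(network$weights)
  val <- if (n >= 3) global_clustering(network) else NA_real_
  if (is.na(val)) notes <- c(notes, "no connected triple")
  attr(val, "notes") <- notes
  val
}

#' Metric table for a list of networks
#' @param networks list of `flock_network` objects.
#' @param ... passed to [summarize_network()].
#' @return data.frame, one row per network.
#' @export
metrics_table <- function(networks, ...) {
  do.call(rbind, lapply(networks, summarize_network, ...))
}
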