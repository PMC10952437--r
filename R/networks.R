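#' Simple ratio index between two individuals
#'
#' The proportion of gathering events containing at least one of the two
#' individuals in which both were present:
#' \deqn{SRI = x / (x + y_i + y_j)}
#' where `x` counts events containing both, and `y_i`, `y_j` events with only
#' one of them. Ranges from 0 (never observed together) to 1 (always
#' observed together).
#'
#' @param gbi binary group-by-individual matrix (events x individuals).
#' @param i,j column names or indices of the two individuals.
#' @return the SRI in \[0, 1\].
#' @export
sri <- function(gbi, i, j) {
  ci <- gbi[, i]; cj <- gbi[, j]
  if (sum(ci) == 0 || sum(cj) == 0) {
    stop("SRI undefined: an individual was never observed", call. = FALSE)
  }
  x <- sum(ci == 1 & cj == 1)
  yi <- sum(ci == 1 & cj == 0)
  yj <- sum(ci == 0 & cj == 1)
  x / (x + yi + yj)
}

#' Build the SRI-weighted social network of one location-week
#'
#' All pairwise simple ratio indices are computed at once from the GBI by
#' cross-products: with `X` the binary matrix, `x = X'X` counts joint events
#' and the denominator for a dyad is `n_i + n_j - x_ij` (events containing
#' either individual).
#'
#' @param gbi binary group-by-individual matrix with individual column names.
#' @param location_id,year,week metadata stamped on the network.
#' @param long_event_flag logical; whether the underlying detection contained
#'   an over-long event (see [flag_long_event_networks()]).
#' @return object of class `flock_network`: list with `weights` (symmetric
#'   SRI matrix, zero diagonal, nodes in sorted tag-id order) and `meta`
#'   (location_id, year, week, population_size, long_event_flag). A GBI with
#'   a single individual yields a one-node network (no edges).
#' @export
build_network <- function(gbi, location_id = NA_character_, year = NA_integer_,
                          week = NA_integer_, long_event_flag = FALSE) {
  if (length(gbi) == 0 || nrow(gbi) == 0 || ncol(gbi) == 0) {
    stop("cannot build a network from an empty GBI", call. = FALSE)
  }
  gbi <- gbi[, order(colnames(gbi)), drop = FALSE]
  storage.mode(gbi) <- "double"
  nev <- colSums(gbi)
  if (any(nev == 0)) stop("GBI has individuals with no events", call. = FALSE)
  x <- crossprod(gbi)
  denom <- outer(nev, nev, "+") - x
  w <- x / denom
  diag(w) <- 0
  structure(list(
    weights = w,
    meta = list(location_id = location_id, year = year, week = week,
                population_size = ncol(gbi),
                long_event_flag = isTRUE(long_event_flag))
  ), class = "flock_network")
}

#' Connectivity classification and downstream-usability filter
#'
#' A network is fully connected when every dyad has a positive association;
#' networks with fewer than two edges carry too little structure for the
#' clustering, edge-weight and modularity metrics and are excluded there.
#'
#' @param network a [build_network()] result.
#' @return list: `fully_connected` (NA for one-node networks), `n_edges`
#'   (positive-weight dyad count), `usable_for_metrics` (n_edges >= 2).
#' @export
classify_network <- function(network) {
  w <- network$weights
  n <- nrow(w)
  pos <- w[upper.tri(w)] > 0
  n_edges <- sum(pos)
  list(
    fully_connected = if (n < 2) NA else all(pos),
    n_edges = as.integer(n_edges),
    usable_for_metrics = n_edges >= 2
  )
}
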