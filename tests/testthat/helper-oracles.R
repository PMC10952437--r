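# Brute-force oracles, independent of the package implementations.

# SRI by direct event counting
sri_oracle <- function(gbi, i, j) {
  x <- 0; yi <- 0; yj <- 0
  for (e in seq_len(nrow(gbi))) {
    a <- gbi[e, i] == 1
    b <- gbi[e, j] == 1
    if (a && b) x <- x + 1
    else if (a) yi <- yi + 1
    else if (b) yj <- yj + 1
  }
  x / (x + yi + yj)
}

# random binary GBI with no empty rows or columns
random_gbi <- function(n_events, n_ind, p = 0.4) {
  m <- matrix(rbinom(n_events * n_ind, 1, p), n_events, n_ind)
  for (r in which(rowSums(m) == 0)) m[r, sample.int(n_ind, 1)] <- 1L
  for (cc in which(colSums(m) == 0)) m[sample.int(n_events, 1), cc] <- 1L
  storage.mode(m) <- "integer"
  colnames(m) <- sprintf("B%02d", seq_len(n_ind))
  rownames(m) <- seq_len(n_events)
  m
}

net_from_weights <- function(w, ...) {
  if (is.null(colnames(w))) {
    dimnames(w) <- list(sprintf("N%02d", seq_len(nrow(w))),
                        sprintf("N%02d", seq_len(nrow(w))))
  }
  structure(list(weights = w,
                 meta = list(location_id = "T", year = 1L, week = 1L,
                             population_size = nrow(w),
                             long_event_flag = FALSE)),
            class = "flock_network")
}

# binary density by pair loop
density_oracle <- function(w) {
  n <- nrow(w); cnt <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (w[i, j] > 0) cnt <- cnt + 1
  }
  cnt / tot
}

# transitivity by triple enumeration
clustering_oracle <- function(w) {
  a <- (w > 0) * 1
  n <- nrow(a)
  triples <- 0; triangles <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k) {
      if (a[i, j] == 1 && a[j, k] == 1) {
        triples <- triples + 1
        if (a[i, k] == 1) triangles <- triangles + 1
      }
    }
  }
  if (triples == 0) return(NA_real_)
  triangles / triples  # both counted with multiplicity 2 per unordered object
}

mew_oracle <- function(w) {
  vals <- c()
  n <- nrow(w)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] > 0) vals <- c(vals, w[i, j])
  }
  mean(vals)
}

# weighted configuration-model modularity, direct formula
modularity_oracle <- function(w, membership) {
  W <- sum(w[upper.tri(w)])
  s <- rowSums(w)
  q <- 0
  for (c in unique(membership)) {
    ix <- which(membership == c)
    e_c <- sum(w[ix, ix]) / 2
    q <- q + e_c / W - (sum(s[ix]) / (2 * W))^2
  }
  q
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# exhaustive best weighted modularity over all partitions
best_partition_q_oracle <- function(w, partitions = all_set_partitions(nrow(w))) {
  W <- sum(w[upper.tri(w)])
  s <- rowSums(w)
  best <- -Inf
  for (m in partitions) {
    q <- 0
    for (c in unique(m)) {
      ix <- which(m == c)
      q <- q + sum(w[ix, ix]) / (2 * W) - (sum(s[ix]) / (2 * W))^2
    }
    if (q > best) best <- q
  }
  best
}

# weighted 8-node graph with two planted blocks
two_block_graph <- function(seed, n = 8) {
  set.seed(seed)
  w <- matrix(0, n, n)
  blocks <- rep(1:2, each = n / 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (blocks[i] == blocks[j]) {
      w[i, j] <- w[j, i] <- runif(1, 0.5, 1)
    } else if (runif(1) < 0.25) {
      w[i, j] <- w[j, i] <- runif(1, 0.02, 0.1)
    }
  }
  dimnames(w) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  list(weights = w, blocks = blocks)
}
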