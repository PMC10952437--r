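#' Resample a visit stream under the 'simple' reference model
#'
#' Builds a synthetic population of `target_n` individuals by sampling
#' `target_n` distinct (individual, location-week) sources from the visit
#' log, without replacement, and giving each synthetic individual the full
#' within-day visit-time sequence of its source, mapped onto a common
#' virtual two-day weekend. Time of day (and the day-1/day-2 structure) is
#' preserved; all social factors — flocking and social preferences — are
#' removed, because the co-occurrence of two synthetic individuals is now
#' only driven by the time of day at which their sources happened to forage.
#' The resampled stream is processed downstream exactly like observed data
#' (event detection, network construction).
#'
#' @param visit_log data.frame with columns tag_id, location_id, timestamp_s,
#'   year, week, day.
#' @param target_n number of synthetic individuals (an observed local
#'   population size).
#' @param seed RNG seed.
#' @param sources optional precomputed [split_visit_sources()] result (used
#'   to avoid re-splitting the log across many replicates).
#' @return a sorted visit stream (tag_id, location_id, timestamp_s, year,
#'   week, day) on the virtual weekend with synthetic tag ids `S001`, ...
#' @export
simple_model_sample <- function(visit_log, target_n, seed = NULL,
                                sources = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sources)) sources <- split_visit_sources(visit_log)
  if (target_n > length(sources)) {
    stop("target_n exceeds the number of available (individual, location-week) sources",
         call. = FALSE)
  }
  chosen <- sample.int(length(sources), target_n)
  rows <- lapply(seq_along(chosen), function(k) {
    v <- sources[[chosen[k]]]
    data.frame(
      tag_id = sprintf("S%03d", k),
      location_id = "virtual",
      timestamp_s = (v$day - 1) * 86400 + v$tod,
      year = 1L, week = 1L, day = v$day,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$timestamp_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a visit log into its (individual, location-week) sources
#'
#' Each element holds one source individual's within-day visit times (`tod`,
#' seconds after midnight) and sampling day, the unit resampled by the
#' simple model.
#' @param visit_log data.frame with tag_id, location_id, year, week, day,
#'   timestamp_s.
#' @return named list of data.frames (day, tod).
#' @export
split_visit_sources <- function(visit_log) {
  key <- interaction(visit_log$tag_id, visit_log$location_id,
                     visit_log$year, visit_log$week, drop = TRUE)
  df <- data.frame(day = visit_log$day, tod = visit_log$timestamp_s %% 86400)
  split(df, key)
}

#' Permute a GBI matrix under the 'social foraging' reference model
#'
#' Applies a chain of checkerboard swaps to the binary group-by-individual
#' matrix: repeatedly find cells `(e1, i1) = (e2, i2) = 1` with
#' `(e1, i2) = (e2, i1) = 0` and flip all four. Every swap preserves all row
#' sums (flock sizes) and column sums (individual visit frequencies), and
#' event times are untouched — only *who* was in which flock is randomized,
#' destroying dyadic social preferences while keeping the propensity to
#' forage in flocks.
#'
#' @param gbi binary event x individual matrix.
#' @param n_swaps number of accepted swaps (default 20 per 1-entry, a
#'   standard burn-in for GBI permutations).
#' @param seed RNG seed.
#' @param max_tries give up after this many attempted draws (guards against
#'   matrices without any checkerboard; default 100 * n_swaps).
#' @return the permuted GBI (same dimnames, same margins). If no checkerboard
#'   exists the input is returned unchanged with a warning.
#' @export
social_foraging_permute <- function(gbi, n_swaps = 20 * sum(gbi), seed = NULL,
                                    max_tries = 100 * n_swaps) {
  if (nrow(gbi) < 2 || ncol(gbi) < 2) {
    stop("GBI permutation requires at least 2 events and 2 individuals",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- gbi
  ones <- which(m == 1)
  n1 <- length(ones)
  if (n1 < 2) {
    warning("no swappable checkerboard exists; returning input unchanged")
    return(gbi)
  }
  er <- ((ones - 1) %% nrow(m)) + 1
  ic <- ((ones - 1) %/% nrow(m)) + 1
  accepted <- 0L
  tries <- 0L
  while (accepted < n_swaps && tries < max_tries) {
    tries <- tries + 1L
    ab <- sample.int(n1, 2)
    a <- ab[1]; b <- ab[2]
    e1 <- er[a]; i1 <- ic[a]; e2 <- er[b]; i2 <- ic[b]
    if (e1 == e2 || i1 == i2) next
    if (m[e1, i2] == 0 && m[e2, i1] == 0) {
      m[e1, i1] <- 0L; m[e2, i2] <- 0L
      m[e1, i2] <- 1L; m[e2, i1] <- 1L
      ic[a] <- i2; ic[b] <- i1
      accepted <- accepted + 1L
    }
  }
  if (accepted == 0L) {
    warning("no swappable checkerboard found; returning input unchanged")
    return(gbi)
  }
  m
}

#' Per-network metrics under the observed data or a reference model
#'
#' @param analysis an [analyze_visit_log()] result (observed location-week
#'   records plus the visit log they came from).
#' @param model one of `"observed"`, `"simple"`, `"social_foraging"`.
#' @param n_replicates replicates per observed network for the reference
#'   models (default 100).
#' @param method,gap_s event-detection settings used when the simple model
#'   re-detects events on resampled streams.
#' @param n_swaps accepted swaps per social-foraging replicate (default 20
#'   per GBI 1-entry).
#' @param seed RNG seed.
#' @return data.frame of [summarize_network()] rows with columns `model` and
#'   `replicate` prepended; population sizes are the observed location-week
#'   sizes, so all three models share the same N support. Replicate failures
#'   are dropped with a message reporting the count.
#' @export
null_model_metrics <- function(analysis,
                               model = c("observed", "simple", "social_foraging"),
                               n_replicates = 100,
                               method = c("gmm", "gap"), gap_s = 300,
                               n_swaps = NULL, seed = 1L) {
  model <- match.arg(model)
  method <- match.arg(method)
  records <- analysis$records
  if (model == "observed") {
    out <- metrics_table(lapply(records, `[[`, "network"))
    out <- cbind(model = "observed", replicate = 1L, out)
    rownames(out) <- NULL
    return(out)
  }
  rows <- list()
  failures <- 0L
  sources <- if (model == "simple") split_visit_sources(analysis$visit_log)
  for (rep_i in seq_len(n_replicates)) {
    for (rec in records) {
      res <- tryCatch({
        if (model == "simple") {
          n <- rec$network$meta$population_size
          stream <- simple_model_sample(
            analysis$visit_log, n,
            seed = child_seed(seed, "simple", rec$key, rep_i),
            sources = sources
          )
          ev <- detect_events(stream, method = method, gap_s = gap_s)
          net <- build_network(build_gbi(ev),
                               location_id = rec$network$meta$location_id,
                               year = rec$network$meta$year,
                               week = rec$network$meta$week)
          summarize_network(net)
        } else {
          gbi <- rec$gbi
          if (nrow(gbi) < 2 || ncol(gbi) < 2) {
            summarize_network(rec$network)
          } else {
            ns <- n_swaps %||% (20 * sum(gbi))
            p <- suppressWarnings(social_foraging_permute(
              gbi, n_swaps = ns,
              seed = child_seed(seed, "swap", rec$key, rep_i)
            ))
            net <- build_network(p,
                                 location_id = rec$network$meta$location_id,
                                 year = rec$network$meta$year,
                                 week = rec$network$meta$week,
                                 long_event_flag = rec$network$meta$long_event_flag)
            summarize_network(net)
          }
        }
      }, error = function(e) NULL)
      if (is.null(res)) {
        failures <- failures + 1L
      } else {
        rows[[length(rows) + 1L]] <- cbind(model = model, replicate = rep_i, res)
      }
    }
  }
  if (failures > 0) message(failures, " replicate network(s) failed and were skipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed-vs-null comparison curves over population size
#'
#' Computes, for the observed data and the requested reference models, the
#' per-population-size-bin mean and standard error of each global network
#' metric — the comparison that separates the contribution of population
#' size alone (simple model), of flocking (social-foraging model), and of
#' dyadic social preferences (observed data) to social structure.
#'
#' @param analysis an [analyze_visit_log()] result.
#' @param models character subset of observed/simple/social_foraging.
#' @param n_replicates replicates per reference model.
#' @param bin_width width of population-size bins (default 5).
#' @param ... passed to [null_model_metrics()].
#' @return data.frame: model, n_bin (bin midpoint), metric, mean, se, n.
#' @export
build_null_curves <- function(analysis,
                              models = c("observed", "simple", "social_foraging"),
                              n_replicates = 100, bin_width = 5, ...) {
  all_rows <- do.call(rbind, lapply(models, function(m) {
    null_model_metrics(analysis, model = m, n_replicates = n_replicates, ...)
  }))
  summarize_null_curves(all_rows, bin_width = bin_width)
}

#' Bin per-network metric rows into mean/SE curves
#' @param rows output of [null_model_metrics()] (possibly row-bound).
#' @param bin_width population-size bin width.
#' @return data.frame: model, n_bin, metric, mean, se, n.
#' @export
summarize_null_curves <- function(rows, bin_width = 5) {
  metrics <- c("edge_density", "global_clustering", "mean_edge_weight",
               "modularity_q")
  bin <- (floor((rows$population_size - 1) / bin_width) + 0.5) * bin_width
  out <- list()
  for (met in metrics) {
    v <- rows[[met]]
    ok <- !is.na(v)
    agg_m <- tapply(v[ok], list(rows$model[ok], bin[ok]), mean)
    agg_s <- tapply(v[ok], list(rows$model[ok], bin[ok]),
                    function(x) stats::sd(x) / sqrt(length(x)))
    agg_n <- tapply(v[ok], list(rows$model[ok], bin[ok]), length)
    for (mod in rownames(agg_m)) {
      for (b in colnames(agg_m)) {
        if (!is.na(agg_m[mod, b])) {
          out[[length(out) + 1L]] <- data.frame(
            model = mod, n_bin = as.numeric(b), metric = met,
            mean = agg_m[mod, b], se = agg_s[mod, b], n = agg_n[mod, b],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
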