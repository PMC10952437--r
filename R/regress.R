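#' Prepare metric tables for the observed-data models
#'
#' Applies the response transformations and exclusion rules, in order:
#'
#' 1. *connectivity*: all networks; response = fully connected yes/no.
#' 2. *density*: fully connected networks excluded; response = squared edge
#'    density.
#' 3. *clustering*, *edge weight*, *modularity*: additionally exclude
#'    networks with fewer than two edges; responses = squared clustering,
#'    log mean edge weight.
#' 4. *modularity (binary)*: zero-vs-positive split at Q <= 0.0001.
#' 5. *modularity (positive)*: only Q > 0.0001; response = log Q.
#'
#' The predictor throughout is log local population size. Rows whose
#' response is undefined (NA metric, non-positive value under a log) are
#' excluded with the reason logged.
#'
#' @param metric_table output of [metrics_table()] (one row per network).
#' @param exclude_long_events drop networks containing a flocking event
#'   longer than 12 min before anything else (the sensitivity re-analysis
#'   path; default FALSE).
#' @param zero_q_threshold "zero" modularity threshold (default 0.0001).
#' @return list of class `flock_model_data`: `tables` (named list of
#'   model-ready data.frames), `counts` (named integer vector of the filter
#'   bookkeeping: n_all, n_not_fully_connected, n_min_edges,
#'   n_modularity_positive), and `exclusion_log`.
#' @export
prepare_responses <- function(metric_table, exclude_long_events = FALSE,
                              zero_q_threshold = 1e-4) {
  m <- metric_table
  log <- character(0)
  if (exclude_long_events) {
    drop <- isTRUE_vec(m$long_event_flag)
    log <- c(log, sprintf("%d networks dropped for containing a >12 min event", sum(drop)))
    m <- m[!drop, , drop = FALSE]
  }
  m$log_popsize <- log(m$population_size)
  m$year_week <- interaction(m$year, m$week, drop = TRUE)

  n_all <- nrow(m)
  connectivity <- m[!is.na(m$fully_connected), , drop = FALSE]

  not_full <- m[!is.na(m$fully_connected) & !m$fully_connected, , drop = FALSE]
  n_not_full <- nrow(not_full)
  density <- not_full[!is.na(not_full$edge_density), , drop = FALSE]
  density$density_sq <- density$edge_density^2

  min_edges <- not_full[not_full$n_edges >= 2, , drop = FALSE]
  n_min_edges <- nrow(min_edges)

  clustering <- min_edges[!is.na(min_edges$global_clustering), , drop = FALSE]
  clustering$clustering_sq <- clustering$global_clustering^2
  if (nrow(clustering) < n_min_edges) {
    log <- c(log, sprintf("%d networks lacked a connected triple (clustering undefined)",
                          n_min_edges - nrow(clustering)))
  }

  edge_weight <- min_edges[!is.na(min_edges$mean_edge_weight) &
                             min_edges$mean_edge_weight > 0, , drop = FALSE]
  edge_weight$log_mean_edge_weight <- log(edge_weight$mean_edge_weight)

  mod_all <- min_edges[!is.na(min_edges$modularity_q), , drop = FALSE]
  mod_all$modularity_zero <- mod_all$modularity_q <= zero_q_threshold
  mod_pos <- mod_all[!mod_all$modularity_zero, , drop = FALSE]
  n_mod_pos <- nrow(mod_pos)
  mod_pos$log_modularity <- log(mod_pos$modularity_q)

  structure(list(
    tables = list(
      connectivity = connectivity,
      density = density,
      clustering = clustering,
      edge_weight = edge_weight,
      modularity_binary = mod_all,
      modularity_positive = mod_pos
    ),
    counts = c(n_all = n_all,
               n_not_fully_connected = n_not_full,
               n_min_edges = n_min_edges,
               n_modularity_positive = n_mod_pos),
    exclusion_log = log
  ), class = "flock_model_data")
}

isTRUE_vec <- function(x) !is.na(x) & x

tidy_fit <- function(fit, model_name) {
  if (is.null(fit)) {
    return(data.frame(model = model_name, term = NA_character_,
                      estimate = NA_real_, se = NA_real_, statistic = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                      note = "did not converge", stringsAsFactors = FALSE))
  }
  co <- if (inherits(fit, "glmmTMB")) {
    summary(fit)$coefficients$cond
  } else {
    stats::coef(summary(fit))
  }
  est <- co[, 1]; se <- co[, 2]; stat <- co[, 3]
  p <- if (ncol(co) >= 4) co[, 4] else 2 * stats::pnorm(-abs(stat))
  data.frame(
    model = model_name, term = rownames(co),
    estimate = est, se = se, statistic = stat,
    ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se, p = p,
    note = "", stringsAsFactors = FALSE, row.names = NULL
  )
}

fit_safely <- function(expr) {
  tryCatch(suppressMessages(expr), error = function(e) NULL,
           warning = function(w) tryCatch(suppressWarnings(suppressMessages(expr)),
                                          error = function(e) NULL))
}

#' Fit the observed-data mixed models
#'
#' Six models link log local population size to network structure (binomial
#' GLMM for connectivity and for the zero/positive modularity split;
#' Gaussian LMMs for squared density, squared clustering, log mean edge
#' weight, and log positive modularity), all with random intercepts for
#' location and for week nested within year. The model fits themselves are
#' delegated to lme4; the bespoke content of this stage is the
#' transformation and filter logic in [prepare_responses()].
#'
#' @param prepared a [prepare_responses()] result.
#' @return data.frame of tidy coefficients (model, term, estimate, se,
#'   statistic, ci_lo, ci_hi, p, note). Non-converging models are reported
#'   with a note and do not halt the pipeline.
#' @export
fit_models <- function(prepared) {
  t <- prepared$tables
  re <- "(1 | location_id) + (1 | year_week)"
  specs <- list(
    connectivity = list(t$connectivity,
                        sprintf("fully_connected ~ log_popsize + %s", re), "binomial"),
    density = list(t$density,
                   sprintf("density_sq ~ log_popsize + %s", re), "gaussian"),
    clustering = list(t$clustering,
                      sprintf("clustering_sq ~ log_popsize + %s", re), "gaussian"),
    edge_weight = list(t$edge_weight,
                       sprintf("log_mean_edge_weight ~ log_popsize + %s", re), "gaussian"),
    modularity_binary = list(t$modularity_binary,
                             sprintf("modularity_zero ~ log_popsize + %s", re), "binomial"),
    modularity_positive = list(t$modularity_positive,
                               sprintf("log_modularity ~ log_popsize + %s", re), "gaussian")
  )
  out <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    d <- s[[1]]
    if (nrow(d) < 10) {
      return(tidy_fit(NULL, nm))
    }
    fit <- if (s[[3]] == "binomial") {
      fit_safely(lme4::glmer(stats::as.formula(s[[2]]), data = d,
                             family = stats::binomial()))
    } else {
      fit_safely(lme4::lmer(stats::as.formula(s[[2]]), data = d, REML = TRUE))
    }
    tidy_fit(fit, nm)
  })
  do.call(rbind, out)
}

#' Zero-truncated negative-binomial model of population size on habitat
#'
#' Weekly local population size (observed only where at least one bird was
#' recorded, hence zero-truncated, NB2 parameterization) on standardized
#' shrub density within a radius and standardized distance to the study-site
#' edge, with random intercepts for location and week-within-year.
#'
#' @param popsizes a [popsize_table()].
#' @param covariates a [location_covariates()] result.
#' @param radius which shrub radius to use, 30 or 100 (default 30).
#' @return tidy coefficient data.frame as in [fit_models()] (model name
#'   `popsize_habitat_<radius>m`).
#' @export
fit_habitat_model <- function(popsizes, covariates, radius = 30) {
  shrub_col <- sprintf("shrub_mean_%gm_z", radius)
  if (!shrub_col %in% names(covariates)) {
    stop("no shrub covariate for radius ", radius, call. = FALSE)
  }
  d <- merge(as.data.frame(popsizes), covariates, by = "location_id")
  d$year_week <- interaction(d$year, d$week, drop = TRUE)
  d$shrub_z <- d[[shrub_col]]
  d$dist_edge_z <- d$dist_to_edge_m_z
  fit <- fit_safely(glmmTMB::glmmTMB(
    size ~ shrub_z + dist_edge_z + (1 | location_id) + (1 | year_week),
    data = d, family = glmmTMB::truncated_nbinom2()
  ))
  tidy_fit(fit, sprintf("popsize_habitat_%gm", radius))
}
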