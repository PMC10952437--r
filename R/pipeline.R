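#' Detect events and build the social network for every location-week
#'
#' The core observed-data pass: splits the visit log into location-week
#' streams, detects flocking events, builds the GBI matrix and the
#' SRI-weighted network, and summarizes metrics.
#'
#' @param visit_log data.frame (tag_id, location_id, timestamp_s, year,
#'   week, day).
#' @param method,gap_s event-detection settings (see [detect_events()]).
#' @param ... further arguments to [detect_events()].
#' @return list of class `flock_analysis`: `records` (per location-week:
#'   key, events, gbi, network), `metrics` (the [metrics_table()]),
#'   `popsizes` (the [popsize_table()]), and the `visit_log`.
#' @export
analyze_visit_log <- function(visit_log, method = c("gmm", "gap"),
                              gap_s = 300, ...) {
  method <- match.arg(method)
  key <- interaction(visit_log$location_id, visit_log$year, visit_log$week,
                     drop = TRUE, sep = "\r")
  records <- list()
  for (k in levels(key)) {
    stream <- visit_log[key == k, , drop = FALSE]
    stream <- stream[order(stream$timestamp_s), , drop = FALSE]
    ev <- detect_events(stream, method = method, gap_s = gap_s, ...)
    gbi <- build_gbi(ev)
    net <- build_network(gbi,
                         location_id = stream$location_id[1],
                         year = stream$year[1], week = stream$week[1],
                         long_event_flag = flag_long_event_networks(ev))
    records[[k]] <- list(key = k, events = ev, gbi = gbi, network = net)
  }
  structure(list(
    records = records,
    metrics = metrics_table(lapply(records, `[[`, "network")),
    popsizes = popsize_table(visit_log),
    visit_log = visit_log
  ), class = "flock_analysis")
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "flocknet_output",
    synthetic = list(),
    event_method = "gap",
    gap_s = 300,
    n_null_replicates = 10L,
    null_models = c("observed", "simple", "social_foraging"),
    n_perm = 200L,
    radii = c(30, 100),
    shrub_n_samples = 164L
  )
}

#' Read a pipeline configuration from YAML (or normalize a list)
#' @param config path to a YAML file or a named list; missing fields take
#'   the package defaults.
#' @return validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$seed)) stop("pipeline config must set a seed")
  if (cfg$n_null_replicates < 1 || cfg$n_perm < 1) {
    stop("replicate and permutation counts must be >= 1")
  }
  if (is.null(cfg$synthetic) && is.null(cfg$visit_log_path)) {
    stop("config needs either a 'synthetic:' block or a 'visit_log_path'")
  }
  cfg
}

#' Run the full pipeline end to end
#'
#' Stages: synthetic data generation (or visit-log loading), event
#' detection, network construction, global metrics, null-model curves,
#' repeatability with permutation test, kriged habitat surface with feeder
#' covariates, and the observed-data mixed models. Writes all stage outputs
#' as plain-text files under `out_dir` plus a JSON run manifest (seeds, row
#' counts per stage, package version).
#'
#' @param config YAML path or config list; see [read_pipeline_config()].
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("flocknet")),
                   seed = cfg$seed, stages = list())

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$visit_log_path)) {
    visit_log <- read_visit_log(cfg$visit_log_path)
    sim <- NULL
    geometry <- NULL
  } else {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$synthetic)
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(scfg)
    visit_log <- sim$visit_log
    geometry <- sim$geometry
    write_sim(sim, cfg$out_dir)
  }
  manifest$stages$visits <- list(n_rows = nrow(visit_log),
                                 n_individuals = length(unique(visit_log$tag_id)))

  # --- events / networks / metrics ---------------------------------------
  analysis <- analyze_visit_log(visit_log, method = cfg$event_method,
                                gap_s = cfg$gap_s)
  utils::write.csv(analysis$metrics, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$popsizes, file.path(cfg$out_dir, "popsizes_observed.csv"),
                   row.names = FALSE)
  write_events_csv(analysis, file.path(cfg$out_dir, "events.csv"))
  manifest$stages$networks <- list(n_networks = nrow(analysis$metrics),
                                   n_events = sum(vapply(analysis$records,
                                                         function(r) nrow(r$events$events),
                                                         integer(1))))

  # --- null models --------------------------------------------------------
  curves <- build_null_curves(analysis, models = cfg$null_models,
                              n_replicates = cfg$n_null_replicates,
                              method = cfg$event_method, gap_s = cfg$gap_s,
                              seed = child_seed(cfg$seed, "null"))
  utils::write.csv(curves, file.path(cfg$out_dir, "null_curves.csv"),
                   row.names = FALSE)
  manifest$stages$null_models <- list(n_replicates = cfg$n_null_replicates,
                                      n_curve_rows = nrow(curves))

  # --- repeatability ------------------------------------------------------
  rpt <- permutation_test(analysis$popsizes, n_perm = cfg$n_perm,
                          seed = child_seed(cfg$seed, "perm"))
  jsonlite::write_json(
    list(R = rpt$R, R_excl_olre = rpt$R_excl_olre, p_value = rpt$p_value,
         var_location = rpt$var_location, var_olre = rpt$var_olre,
         var_dist = rpt$var_dist),
    file.path(cfg$out_dir, "repeatability.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(R_perm = rpt$null_distribution),
                   file.path(cfg$out_dir, "repeatability_null.csv"),
                   row.names = FALSE)
  manifest$stages$repeatability <- list(R = rpt$R, p = rpt$p_value,
                                        n_perm = cfg$n_perm)

  # --- habitat + regression ----------------------------------------------
  coefs <- NULL
  covariates <- NULL
  if (!is.null(geometry)) {
    shrub <- generate_shrub_samples(geometry, n_samples = cfg$shrub_n_samples,
                                    seed = child_seed(cfg$seed, "shrub"))
    vg <- fit_spherical_variogram(shrub)
    surf <- krige_surface(shrub, vg, polygon = geometry$boundary, spacing = 10)
    covariates <- location_covariates(geometry, surf, radii = cfg$radii)
    utils::write.csv(covariates, file.path(cfg$out_dir, "location_covariates.csv"),
                     row.names = FALSE)
    write_surface(surf, file.path(cfg$out_dir, "shrub_surface"))
    manifest$stages$habitat <- list(n_samples = nrow(shrub),
                                    variogram = list(sill = vg$sill, range = vg$range),
                                    n_grid = nrow(surf$grid))
  }
  prepared <- prepare_responses(analysis$metrics)
  coefs <- fit_models(prepared)
  if (!is.null(covariates)) {
    coefs <- rbind(coefs, fit_habitat_model(analysis$popsizes, covariates,
                                            radius = cfg$radii[1]))
  }
  utils::write.csv(coefs, file.path(cfg$out_dir, "model_coefficients.csv"),
                   row.names = FALSE)
  manifest$stages$regress <- list(filter_counts = as.list(prepared$counts),
                                  n_models = length(unique(coefs$model)))

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, analysis = analysis, curves = curves,
                 repeatability = rpt, covariates = covariates,
                 prepared = prepared, coefficients = coefs,
                 manifest = manifest))
}

write_events_csv <- function(analysis, path) {
  rows <- lapply(analysis$records, function(r) {
    ev <- r$events$events
    if (nrow(ev) == 0) return(NULL)
    data.frame(location_id = r$network$meta$location_id,
               year = r$network$meta$year, week = r$network$meta$week,
               ev, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
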