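# One moderately sized simulated dataset with its full observed-data
# analysis, built lazily and shared across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture_analysis <- function() {
  if (is.null(.fixture_env$analysis)) {
    cfg <- sim_config(n_locations = 12, n_years = 1, weeks_per_year = 3,
                      location_effect_sd = 0.6, edge_effect = 0,
                      mean_log_popsize = log(12), seed = 424L)
    sim <- simulate_dataset(cfg)
    .fixture_env$sim <- sim
    .fixture_env$analysis <- analyze_visit_log(sim$visit_log, method = "gmm")
  }
  .fixture_env$analysis
}

fixture_sim <- function() {
  fixture_analysis()
  .fixture_env$sim
}

# metric table with exactly known filter composition (regression-stage
# bookkeeping tests)
planted_metric_table <- function(n_total = 100, n_full = 20, n_one_edge = 10,
                                 n_zero_mod = 30, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    location_id = sprintf("L%02d", sample(1:10, n_total, replace = TRUE)),
    year = sample(1:3, n_total, replace = TRUE),
    week = sample(1:13, n_total, replace = TRUE),
    population_size = sample(3:40, n_total, replace = TRUE),
    long_event_flag = FALSE
  )
  df$fully_connected <- seq_len(n_total) <= n_full
  df$n_edges <- ifelse(df$fully_connected, 10L, 5L)
  df$n_edges[n_full + seq_len(n_one_edge)] <- 1L
  df$edge_density <- runif(n_total, 0.2, 0.99)
  df$edge_density[df$fully_connected] <- 1
  df$edge_density[n_full + n_one_edge + 1L] <- 0.8
  df$global_clustering <- runif(n_total, 0.1, 1)
  df$mean_edge_weight <- runif(n_total, 0.05, 0.9)
  df$modularity_q <- runif(n_total, 0.001, 0.3)
  not_full <- which(!df$fully_connected & df$n_edges >= 2)
  df$modularity_q[not_full[seq_len(n_zero_mod)]] <- 5e-5
  df$usable_for_metrics <- df$n_edges >= 2
  df$zero_modularity_flag <- df$modularity_q <= 1e-4
  df$notes <- ""
  df
}
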