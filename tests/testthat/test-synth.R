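test_that("feeder grid geometry is evenly spaced inside the boundary", {
  cfg1 <- sim_config(n_locations = 1, seed = 1)
  g1 <- generate_geometry(cfg1)
  expect_equal(nrow(g1$feeders), 1)
  expect_gt(distance_to_edge(c(g1$feeders$x, g1$feeders$y), g1$boundary), 0)

  cfg <- sim_config(n_locations = 65, grid_spacing_m = 250, seed = 1)
  g <- generate_geometry(cfg)
  expect_equal(nrow(g$feeders), 65)
  d <- as.matrix(dist(g$feeders[, c("x", "y")]))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(nn >= 200 & nn <= 300))
  inside <- vapply(seq_len(65), function(i) {
    point_in_polygon(c(g$feeders$x[i], g$feeders$y[i]), g$boundary)
  }, logical(1))
  expect_true(all(inside))
})

test_that("degenerate or too-small boundary polygons are rejected", {
  cfg <- sim_config(n_locations = 4, seed = 1)
  flat <- cbind(c(0, 1000, 2000), c(0, 0, 0))
  expect_error(generate_geometry(cfg, boundary = flat), "zero area")
  tiny <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_error(generate_geometry(cfg, boundary = tiny), "too small")
})

test_that("population-size draws follow the latent location model", {
  cfg0 <- sim_config(n_locations = 20, location_effect_sd = 0, edge_effect = 0,
                     seed = 3)
  g <- generate_geometry(cfg0)
  p0 <- draw_location_week_popsizes(cfg0, g)
  expect_true(all(p0$size >= 1))
  lam <- attr(p0, "lambda")
  expect_lt(diff(range(lam)), 1e-9)  # no heterogeneity: all means equal

  # a negative edge effect means larger populations near the study edge
  cfg_e <- sim_config(n_locations = 65, location_effect_sd = 0.05,
                      edge_effect = -0.8, seed = 3)
  ge <- generate_geometry(cfg_e)
  pe <- draw_location_week_popsizes(cfg_e, ge)
  means <- tapply(pe$size, pe$location_id, mean)
  dedge <- attr(pe, "dist_to_edge")[names(means)]
  expect_lt(cor(dedge, means, method = "spearman"), 0)
})

test_that("draws are reproducible from the config seed", {
  cfg <- sim_config(n_locations = 6, n_years = 1, weeks_per_year = 2, seed = 11)
  g <- generate_geometry(cfg)
  a <- draw_location_week_popsizes(cfg, g)
  b <- draw_location_week_popsizes(cfg, g)
  expect_identical(a$size, b$size)
})

test_that("target latent repeatability is invertible from the location SD", {
  cfg <- sim_config(seed = 1, edge_effect = 0)
  for (r in c(0.3, 0.66)) {
    cfg$location_effect_sd <- location_sd_for_repeatability(r, cfg)
    expect_equal(implied_repeatability(cfg), r, tolerance = 1e-6)
  }
})

test_that("visit streams are sorted, clustered, and roster-consistent", {
  cfg <- sim_config(seed = 5)
  roster <- sprintf("B%02d", 1:12)
  s <- simulate_visit_stream(roster, cfg, seed = 9)
  expect_false(is.unsorted(s$timestamp_s))
  expect_true(all(s$tag_id %in% roster))
  truth <- attr(s, "truth")
  expect_equal(length(truth$assignment), nrow(s))
  # every visit belongs to exactly one generated event
  expect_true(all(truth$assignment %in% truth$events$event))
  # time of day within the daylight window
  tod <- s$timestamp_s %% 86400
  expect_true(all(tod >= cfg$daylight_window_s[1] - 1e-6 &
                    tod <= cfg$daylight_window_s[2] + 3600))
})

test_that("a lone bird forms singleton events and empty rosters warn", {
  cfg <- sim_config(seed = 2)
  s1 <- simulate_visit_stream("B01", cfg, seed = 3)
  expect_true(all(attr(s1, "truth")$events$n_members == 1))
  expect_warning(s0 <- simulate_visit_stream(character(0), cfg, seed = 3),
                 "empty roster")
  expect_equal(nrow(s0), 0)
})

test_that("fully cohesive bonded dyads always forage together", {
  cfg <- sim_config(seed = 7, bond_cohesion = 1, unit_time_window_h = NULL)
  roster <- c("A", "B")
  s <- simulate_visit_stream(roster, cfg, units = cbind("A", "B"), seed = 13)
  ev <- detect_events(s, method = "gap")
  gbi <- build_gbi(ev)
  expect_equal(sri(gbi, "A", "B"), 1)
})

test_that("generated event counts match the ~87 per weekend regime", {
  cfg <- sim_config(seed = 31)
  counts <- vapply(1:20, function(i) {
    s <- simulate_visit_stream(sprintf("B%02d", 1:15), cfg, seed = 100 + i)
    nrow(attr(s, "truth")$events)
  }, numeric(1))
  expect_gt(mean(counts), 87 * 0.8)
  expect_lt(mean(counts), 87 * 1.2)
})

test_that("simulated datasets are reproducible and internally consistent", {
  cfg <- sim_config(n_locations = 4, n_years = 1, weeks_per_year = 2,
                    mean_log_popsize = log(8), seed = 21)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$visit_log, s2$visit_log)
  # no visit from a bird outside its location-week roster
  key <- sprintf("%s_y%d_w%02d", s1$visit_log$location_id,
                 s1$visit_log$year, s1$visit_log$week)
  ok <- vapply(unique(key), function(k) {
    all(s1$visit_log$tag_id[key == k] %in% s1$truth$rosters[[k]])
  }, logical(1))
  expect_true(all(ok))
})

test_that("shrub quadrat sampling honours count, constancy and exactness", {
  cfg <- sim_config(seed = 3)
  g <- generate_geometry(cfg)
  sh <- generate_shrub_samples(g, n_samples = 164, seed = 4)
  expect_equal(nrow(sh), 164)
  expect_true(all(sh$density >= 0))
  const <- generate_shrub_samples(g, n_samples = 30, surface = "constant",
                                  mean_density = 3, seed = 4)
  expect_true(all(const$density == 3))
  # noiseless samples equal the latent surface at the sample points
  fn <- attr(sh, "surface_fn")
  expect_equal(sh$density, pmax(0, fn(sh$x, sh$y)), tolerance = 1e-12)
})

test_that("visit logs round-trip through CSV", {
  sim <- fixture_sim()
  dir <- withr::local_tempdir()
  files <- write_sim(sim, dir)
  v <- read_visit_log(files["visit_log"])
  expect_equal(nrow(v), nrow(sim$visit_log))
  expect_equal(sort(unique(v$tag_id)), sort(unique(sim$visit_log$tag_id)))
  expect_true(startsWith(readLines(files["boundary"]), "POLYGON"))
})
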