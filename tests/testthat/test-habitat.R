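square <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))

test_that("distance to the study-site edge is the minimum boundary distance", {
  expect_equal(distance_to_edge(c(500, 500), square), 500)
  expect_equal(distance_to_edge(c(0, 500), square), 0)
  expect_error(distance_to_edge(c(2000, 500), square), "outside")

  # brute force over densely sampled boundary segments, random polygons
  set.seed(3)
  for (i in 1:5) {
    ang <- sort(runif(6, 0, 2 * pi))
    rad <- runif(6, 200, 500)
    poly <- cbind(500 + rad * cos(ang), 500 + rad * sin(ang))
    cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
    pt <- c(cx, cy)
    dense <- do.call(rbind, lapply(seq_len(nrow(poly)), function(k) {
      k2 <- if (k == nrow(poly)) 1 else k + 1
      t <- seq(0, 1, length.out = 3000)
      cbind(poly[k, 1] + t * (poly[k2, 1] - poly[k, 1]),
            poly[k, 2] + t * (poly[k2, 2] - poly[k, 2]))
    }))
    brute <- min(sqrt((dense[, 1] - pt[1])^2 + (dense[, 2] - pt[2])^2))
    expect_equal(distance_to_edge(pt, poly), brute, tolerance = 1e-3)
  }
})

test_that("the spherical variogram fit recovers field structure", {
  cfg <- sim_config(n_locations = 16, grid_spacing_m = 250, seed = 2)
  geo <- generate_geometry(cfg)

  # constant field: sill ~ 0
  const <- generate_shrub_samples(geo, n_samples = 40, surface = "constant",
                                  seed = 5)
  vg0 <- fit_spherical_variogram(const)
  expect_lt(vg0$sill, 1e-8)

  # Gaussian-process field with known range 200 m: recovered within +-50%
  ranges <- vapply(1:3, function(i) {
    gp <- generate_shrub_samples(geo, n_samples = 164, surface = "gp",
                                 gp_range = 200, gp_sill = 1, seed = 10 + i)
    fit_spherical_variogram(gp)$range
  }, numeric(1))
  expect_gt(mean(ranges), 100)
  expect_lt(mean(ranges), 300)

  # pure-nugget white noise: range collapses and the fit is flagged
  set.seed(1)
  wn <- data.frame(x = runif(120, 0, 1000), y = runif(120, 0, 1000),
                   density = rnorm(120))
  vgn <- fit_spherical_variogram(wn)
  expect_lt(vgn$range / 1000, 0.2)

  expect_error(fit_spherical_variogram(wn[rep(1, 20), ]), "distinct")
})

test_that("ordinary kriging interpolates exactly with weights summing to one", {
  cfg <- sim_config(n_locations = 9, grid_spacing_m = 200, seed = 4)
  geo <- generate_geometry(cfg)
  sh <- generate_shrub_samples(geo, n_samples = 60, seed = 6)
  vg <- fit_spherical_variogram(sh)
  # predict at the sample points themselves
  surf_at_samples <- krige_surface(sh, vg, grid = sh[, c("x", "y")])
  expect_equal(surf_at_samples$grid$pred, sh$density, tolerance = 1e-6)
  expect_lt(surf_at_samples$max_weight_sum_error, 1e-8)

  const <- sh; const$density <- 4.2
  vgc <- list(model = "spherical", sill = 1, range = 300, nugget = 0)
  sc <- krige_surface(const, vgc, polygon = geo$boundary, spacing = 100)
  expect_equal(sc$grid$pred, rep(4.2, nrow(sc$grid)), tolerance = 1e-8)
})

test_that("a smooth surface is recovered well from 164 quadrats", {
  cfg <- sim_config(n_locations = 16, grid_spacing_m = 250, seed = 9)
  geo <- generate_geometry(cfg)
  sh <- generate_shrub_samples(geo, n_samples = 164, seed = 12)
  fn <- attr(sh, "surface_fn")
  vg <- fit_spherical_variogram(sh)
  surf <- krige_surface(sh, vg, polygon = geo$boundary, spacing = 50)
  truth <- pmax(0, fn(surf$grid$x, surf$grid$y))
  rmse <- sqrt(mean((surf$grid$pred - truth)^2))
  expect_lt(rmse, 0.2 * sd(truth))
})

test_that("radius means use the expected number of 10 m grid cells", {
  grid <- expand.grid(x = seq(5, 995, by = 10), y = seq(5, 995, by = 10))
  surf <- structure(list(grid = data.frame(grid, pred = 7), spacing = 10),
                    class = "habitat_surface")
  m30 <- mean_within_radius(surf, c(505, 505), 30)
  expect_equal(as.numeric(m30), 7)
  expect_true(abs(attr(m30, "n_cells") - pi * 30^2 / 100) < 5)
  m100 <- mean_within_radius(surf, c(505, 505), 100)
  expect_true(abs(attr(m100, "n_cells") - pi * 100^2 / 100) < 12)
  expect_error(mean_within_radius(surf, c(500, 500), 2), "no grid cells")
})

test_that("location covariates are standardized across feeders", {
  cfg <- sim_config(n_locations = 9, grid_spacing_m = 200, seed = 4)
  geo <- generate_geometry(cfg)
  sh <- generate_shrub_samples(geo, n_samples = 60, seed = 6)
  vg <- fit_spherical_variogram(sh)
  surf <- krige_surface(sh, vg, polygon = geo$boundary, spacing = 20)
  cov <- location_covariates(geo, surf, radii = c(30, 100))
  expect_equal(mean(cov$shrub_mean_30m_z), 0, tolerance = 1e-12)
  expect_equal(sd(cov$shrub_mean_30m_z), 1, tolerance = 1e-12)
  expect_true(all(cov$shrub_mean_30m >= 0))
  # standardizing twice changes nothing
  expect_equal(standardize(standardize(cov$dist_to_edge_m)),
               standardize(cov$dist_to_edge_m))
})
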