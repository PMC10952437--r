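#' Signed area of a simple polygon (shoelace formula)
#' @param polygon two-column matrix of vertices (not closed).
#' @return signed area.
#' @export
polygon_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Point-in-polygon test (ray casting, even-odd rule)
#' @param point numeric length-2 (x, y).
#' @param polygon two-column vertex matrix (not closed).
#' @return logical; points on the boundary count as inside.
#' @export
point_in_polygon <- function(point, polygon) {
  x <- point[1]; y <- point[2]
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # boundary points: treat as inside
    if (dist_point_segment(point, c(px[j], py[j]), c(px[i], py[i])) < 1e-9) {
      return(TRUE)
    }
    if ((py[i] > y) != (py[j] > y)) {
      xint <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - a - t * ab)^2))
}

#' Distance from a point inside the study site to its edge
#'
#' Minimum Euclidean distance from the point to the boundary polygon.
#'
#' @param point numeric length-2 (x, y); must lie inside the polygon.
#' @param polygon two-column vertex matrix (not closed).
#' @return metres.
#' @export
distance_to_edge <- function(point, polygon) {
  if (!point_in_polygon(point, polygon)) {
    stop("point lies outside the polygon", call. = FALSE)
  }
  n <- nrow(polygon)
  d <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    dist_point_segment(point, polygon[i, ], polygon[j, ])
  }, numeric(1))
  min(d)
}

#' Spherical semivariogram model (zero nugget)
#' @param h distances.
#' @param sill,range model parameters.
#' @return semivariance at each distance.
#' @export
spherical_gamma <- function(h, sill, range) {
  g <- ifelse(h <= range,
              sill * (1.5 * h / range - 0.5 * (h / range)^3),
              sill)
  g[h == 0] <- 0
  g
}

#' Empirical semivariogram of quadrat samples
#' @param samples data.frame (x, y, density).
#' @param n_bins number of distance bins (default 15).
#' @param max_dist upper distance cut-off (default half the maximum pairwise
#'   distance, standard practice).
#' @return data.frame: h (bin centre), gamma (mean semivariance), n_pairs.
#' @export
empirical_variogram <- function(samples, n_bins = 15, max_dist = NULL) {
  pts <- as.matrix(samples[, c("x", "y")])
  z <- samples$density
  d <- stats::dist(pts)
  if (max(d) == 0) stop("all samples are collocated", call. = FALSE)
  if (is.null(max_dist)) max_dist <- max(d) / 2
  dv <- as.vector(d)
  sem <- 0.5 * as.vector(stats::dist(z))^2
  keep <- dv > 0 & dv <= max_dist
  brk <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(dv[keep], brk, include.lowest = TRUE, labels = FALSE)
  g <- tapply(sem[keep], bin, mean)
  n <- tapply(sem[keep], bin, length)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  ok <- as.integer(names(g))
  data.frame(h = mid[ok], gamma = as.numeric(g), n_pairs = as.integer(n))
}

#' Fit a spherical variogram model with zero nugget
#'
#' Weighted least squares on the binned empirical semivariogram, with weights
#' `n_pairs / h^2` so short-range structure (which controls kriging weights)
#' dominates the fit. The nugget is fixed at zero: predictions interpolate
#' the samples exactly.
#'
#' @param samples data.frame (x, y, density) of at least 10 spatially
#'   distinct quadrats.
#' @param n_bins distance bins (default 15).
#' @param max_dist see [empirical_variogram()].
#' @return list of class `flock_variogram`: model = "spherical", `sill`,
#'   `range`, `nugget` = 0, the `empirical` variogram, and `poor_fit` (TRUE
#'   when the fitted range collapses below the first bin distance, the
#'   signature of a pure-nugget field).
#' @export
fit_spherical_variogram <- function(samples, n_bins = 15, max_dist = NULL) {
  if (nrow(unique(samples[, c("x", "y")])) < 10) {
    stop("need at least 10 spatially distinct samples", call. = FALSE)
  }
  emp <- empirical_variogram(samples, n_bins = n_bins, max_dist = max_dist)
  w <- emp$n_pairs / emp$h^2
  obj <- function(par) {
    sum(w * (emp$gamma - spherical_gamma(emp$h, par[1], par[2]))^2)
  }
  sill0 <- max(stats::var(samples$density), 1e-12)
  range0 <- max(emp$h) / 2
  fit <- stats::optim(c(sill0, range0), obj, method = "L-BFGS-B",
                      lower = c(1e-12, min(emp$h) / 10),
                      upper = c(Inf, 10 * max(emp$h)))
  structure(list(model = "spherical", sill = fit$par[1], range = fit$par[2],
                 nugget = 0, empirical = emp,
                 poor_fit = fit$par[2] < min(emp$h),
                 objective = fit$value),
            class = "flock_variogram")
}

#' Regular prediction grid over the study polygon
#' @param polygon two-column vertex matrix.
#' @param spacing grid spacing in metres (default 10).
#' @return data.frame (x, y) of node centres inside the polygon.
#' @export
make_prediction_grid <- function(polygon, spacing = 10) {
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  xs <- seq(xr[1] + spacing / 2, xr[2], by = spacing)
  ys <- seq(yr[1] + spacing / 2, yr[2], by = spacing)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  keep <- vapply(seq_len(nrow(g)), function(i) {
    point_in_polygon(c(g$x[i], g$y[i]), polygon)
  }, logical(1))
  g[keep, , drop = FALSE]
}

#' Ordinary kriging of the shrub-cover surface
#'
#' Predicts the density at every grid node by ordinary kriging (weights
#' constrained to sum to 1) under the fitted zero-nugget spherical
#' variogram, using the nearest `n_neighbors` samples per node. With zero
#' nugget the predictor interpolates: at a sampled point the prediction
#' equals the sample value. Far beyond the variogram range the prediction
#' reverts towards the local neighbourhood mean — extrapolation there is
#' reported, not trustworthy.
#'
#' @param samples data.frame (x, y, density).
#' @param variogram a [fit_spherical_variogram()] result.
#' @param grid data.frame (x, y) of prediction nodes; built from `polygon`
#'   at `spacing` when omitted.
#' @param polygon study boundary (needed when `grid` is NULL).
#' @param spacing grid spacing in metres (default 10).
#' @param n_neighbors local kriging neighbourhood size (default 32).
#' @return object of class `habitat_surface`: list with `grid` (x, y, pred),
#'   `variogram`, `spacing`, and `max_weight_sum_error` (largest deviation of
#'   any node's kriging-weight sum from 1).
#' @export
krige_surface <- function(samples, variogram, grid = NULL, polygon = NULL,
                          spacing = 10, n_neighbors = 32) {
  if (is.null(grid)) {
    if (is.null(polygon)) stop("need either a grid or a polygon")
    grid <- make_prediction_grid(polygon, spacing)
  }
  pts <- as.matrix(samples[, c("x", "y")])
  z <- samples$density
  ns <- nrow(pts)
  k <- min(n_neighbors, ns)
  sill <- variogram$sill; rng <- variogram$range
  covfun <- function(h) sill - spherical_gamma(h, sill, rng)

  pred <- numeric(nrow(grid))
  werr <- 0
  warned <- FALSE
  gx <- grid$x; gy <- grid$y
  for (i in seq_len(nrow(grid))) {
    d0 <- sqrt((pts[, 1] - gx[i])^2 + (pts[, 2] - gy[i])^2)
    nn <- order(d0)[seq_len(k)]
    C <- covfun(as.matrix(stats::dist(pts[nn, , drop = FALSE])))
    A <- rbind(cbind(C, 1), c(rep(1, k), 0))
    b <- c(covfun(d0[nn]), 1)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) {
      if (!warned) {
        warning("singular kriging system: using a regularized solve")
        warned <- TRUE
      }
      A[seq_len(k), seq_len(k)] <- C + diag(1e-8 * max(sill, 1), k)
      sol <- solve(A, b)
    }
    wgt <- sol[seq_len(k)]
    werr <- max(werr, abs(sum(wgt) - 1))
    pred[i] <- sum(wgt * z[nn])
  }
  structure(list(grid = data.frame(x = gx, y = gy, pred = pred),
                 variogram = variogram, spacing = spacing,
                 max_weight_sum_error = werr),
            class = "habitat_surface")
}

#' Mean predicted density within a radius of a point
#'
#' Arithmetic mean over grid nodes whose centre lies within `radius` of the
#' point. On a 10 m grid a 30 m radius captures about 28 cells
#' (`pi * 30^2 / 100`).
#'
#' @param surface a [krige_surface()] result.
#' @param point numeric length-2 (x, y).
#' @param radius metres.
#' @return the mean density, with attribute `n_cells` (contributing cells).
#' @export
mean_within_radius <- function(surface, point, radius) {
  g <- surface$grid
  d2 <- (g$x - point[1])^2 + (g$y - point[2])^2
  sel <- d2 <= radius^2
  if (!any(sel)) stop("no grid cells within the radius", call. = FALSE)
  structure(mean(g$pred[sel]), n_cells = sum(sel))
}

#' Habitat covariates for every feeder location
#'
#' Mean kriged shrub density within each radius of the feeder, plus the
#' distance to the study-site edge, and standardized (z-score) versions of
#' all three as used in the population-size model.
#'
#' @param geometry a [generate_geometry()] result.
#' @param surface a [krige_surface()] result.
#' @param radii radii in metres (default `c(30, 100)`).
#' @return data.frame keyed by location_id with `shrub_mean_<r>m`,
#'   `dist_to_edge_m`, and `*_z` columns (mean 0, SD 1 across locations).
#' @export
location_covariates <- function(geometry, surface, radii = c(30, 100)) {
  f <- geometry$feeders
  out <- data.frame(location_id = f$location_id, stringsAsFactors = FALSE)
  for (r in radii) {
    vals <- vapply(seq_len(nrow(f)), function(i) {
      as.numeric(mean_within_radius(surface, c(f$x[i], f$y[i]), r))
    }, numeric(1))
    out[[sprintf("shrub_mean_%gm", r)]] <- vals
  }
  out$dist_to_edge_m <- vapply(seq_len(nrow(f)), function(i) {
    distance_to_edge(c(f$x[i], f$y[i]), geometry$boundary)
  }, numeric(1))
  for (col in setdiff(names(out), "location_id")) {
    out[[paste0(col, "_z")]] <- standardize(out[[col]])
  }
  out
}

#' Standardize to mean 0, SD 1 (idempotent on already-standardized input)
#' @param x numeric vector.
#' @return z-scores; a constant vector maps to zeros.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Write a kriged surface as an ESRI-ASCII-style text raster plus CSV
#' @param surface a [krige_surface()] result.
#' @param path_prefix output files are `<prefix>.asc` and `<prefix>.csv`.
#' @return invisibly, the file paths.
#' @export
write_surface <- function(surface, path_prefix) {
  g <- surface$grid
  utils::write.csv(g, paste0(path_prefix, ".csv"), row.names = FALSE)
  xs <- sort(unique(g$x)); ys <- sort(unique(g$y), decreasing = TRUE)
  m <- matrix(-9999, nrow = length(ys), ncol = length(xs))
  m[cbind(match(g$y, ys), match(g$x, xs))] <- g$pred
  hdr <- c(
    sprintf("ncols %d", length(xs)),
    sprintf("nrows %d", length(ys)),
    sprintf("xllcorner %g", min(xs) - surface$spacing / 2),
    sprintf("yllcorner %g", min(ys) - surface$spacing / 2),
    sprintf("cellsize %g", surface$spacing),
    "NODATA_value -9999"
  )
  con <- file(paste0(path_prefix, ".asc"), "w")
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(paste0(path_prefix, c(".asc", ".csv")))
}
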