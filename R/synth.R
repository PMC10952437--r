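#' Configuration for the synthetic visit-log generator
#'
#' Defines the study conditions the generator emulates: a grid of RFID
#' feeders sampled on two weekend days per week over 13 weeks in each of
#' three winters, with location-consistent local population sizes, burst
#' (flock) structured visits, dyadic social preferences (pair bonds) and a
#' habitat gradient (larger populations near the study-site edge).
#'
#' Population sizes follow a latent log-normal / zero-truncated Poisson
#' model: \eqn{\log \lambda_l = \mu + \beta_e z_l + a_l} with
#' \eqn{a_l \sim N(0, \sigma_l^2)} a location effect shared across all weeks
#' and years, and \eqn{z_l} the standardized distance to the study-site
#' edge. The weekly count is a zero-truncated Poisson draw from
#' \eqn{\lambda_l} (plus optional week/year trends). This matches the
#' Poisson mixed model used downstream to estimate repeatability, so
#' parameter recovery is well-posed; see [implied_repeatability()].
#'
#' @param n_locations number of feeder locations (default 65).
#' @param grid_spacing_m feeder grid spacing in metres (default 250).
#' @param n_years number of winters (default 3).
#' @param weeks_per_year weekly samples per winter (default 13).
#' @param sample_days_per_week sampling days per weekend (default 2).
#' @param location_effect_sd SD of the latent (log-scale) location effect.
#'   The default, together with `edge_effect`, implies a latent
#'   repeatability of about 0.66 at the default mean population size.
#' @param edge_effect slope of log population size on the standardized
#'   distance to the study-site edge; negative means larger populations near
#'   the edge (default -0.19).
#' @param mean_log_popsize latent mean of log weekly population size
#'   (default `log(15.35)`).
#' @param week_trend linear fixed effect of week (1..13) on log size.
#' @param year_effects additive log-scale offsets, one per year.
#' @param flock_rate_per_day expected flocking events per sampling day at a
#'   location hosting the mean population size (default 43.5, i.e. about 87
#'   per weekend on average across locations).
#' @param event_rate_size_exp exponent of the event-rate scaling with local
#'   population size: the effective daily rate is
#'   `flock_rate_per_day * (n / exp(mean_log_popsize))^event_rate_size_exp`.
#'   The default 1.3 makes busy locations host more foraging bouts — the
#'   mechanism that keeps large populations well mixed (without it,
#'   per-pair association opportunities would collapse as 1/n^2 and large
#'   networks would fragment, which is not what feeder data show). Note
#'   the pairwise association index is unaffected by the event rate (it
#'   depends only on the joining probability), so this controls mixing,
#'   not edge weights. Set 0 for a size-independent rate.
#' @param flock_duration_mean_s mean event duration in seconds (default 240).
#' @param visit_rate_in_event mean number of antenna visits an individual
#'   makes during one event it attends (Poisson, minimum 1; default 1.5 —
#'   a bird typically lands on the antenna a couple of times per
#'   gathering).
#' @param flock_size_max,flock_size_halfsat parameters of the saturating
#'   flock-size curve: the expected flock size in a population of `n` birds
#'   is `flock_size_max * n / (n + flock_size_halfsat)`, so flocks grow with
#'   local population size but saturate (defaults 16.5 and 40: flocks of
#'   ~4.5 at the mean population size of ~15, approaching 10+ only in the
#'   largest populations). The per-event joining probability is this flock
#'   size divided by `n`, hence decreases with population size — which is
#'   what makes the mean edge weight fall as populations grow.
#' @param join_prob optional fixed mean joining probability overriding the
#'   flock-size curve (default `NULL`: derive from the curve).
#' @param join_concentration concentration of the Beta distribution from
#'   which each individual's event-joining propensity is drawn
#'   (`Beta(join_prob * k, (1 - join_prob) * k)`). Small values give strong
#'   attendance heterogeneity — some birds attend most events, others one or
#'   two — which is what keeps larger networks from being trivially fully
#'   connected; `Inf` gives every bird the same propensity. Because the
#'   propensity depends only on the individual (column), event membership is
#'   exchangeable given the GBI margins, which the swap-permutation null
#'   model preserves. Default 3.
#' @param pair_bond_fraction proportion of individuals in bonded social
#'   units (default 0.85; wintering great tits travel in small fission-
#'   fusion units built around mated pairs).
#' @param bond_cohesion probability that a bonded unit decides jointly
#'   (all members join or none) rather than independently (default 0.95),
#'   in a population of up to 10 birds. In larger populations the
#'   effective cohesion is scaled by `(10 / n)^2`: at crowded feeders the
#'   constant turnover of arriving birds erodes unit cohesion, which is
#'   what lets large networks mix. At 0 every decision is independent and
#'   event membership is exchangeable given the GBI margins.
#' @param unit_size_mean mean size of bonded social units (default 4:
#'   small roving sub-flocks with sizes 2 + Poisson; 2 makes every unit a
#'   mated pair).
#' @param unit_time_window_h optional activity-window width in hours for
#'   bonded units *in a population of 10 birds*: when a unit decides
#'   jointly it only joins gatherings inside its own window of the day
#'   (joining probability rescaled so marginal attendance is unchanged).
#'   The effective width widens back to the full day away from populations
#'   of about 10 birds (a Gaussian bump in population size): a handful of
#'   birds form one flock sharing the feeder all day, a population of
#'   around 10 splits into sub-flocks visiting at distinct times, and at
#'   crowded feeders continuous visitation dissolves the sub-flock
#'   boundaries again. This is the mechanism behind the fragmentation
#'   (modularity) peak at intermediate population sizes seen in feeder
#'   networks. Default 2 h; `NULL` disables the window.
#' @param multi_feeder_prob probability that a bird recorded at its home
#'   location in a week also contributes records to a neighbouring feeder
#'   that week; realized as a visitor fraction of each weekly roster so the
#'   drawn population size is preserved exactly (default 0.3, giving about
#'   1.3 feeders per bird-week).
#' @param daylight_window_s start/end of the daily activity window in
#'   seconds after midnight (default 07:00-17:00).
#' @param seed master RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_locations = 65,
                       grid_spacing_m = 250,
                       n_years = 3,
                       weeks_per_year = 13,
                       sample_days_per_week = 2,
                       location_effect_sd = 0.28,
                       edge_effect = -0.19,
                       mean_log_popsize = log(15.35),
                       week_trend = 0,
                       year_effects = NULL,
                       flock_rate_per_day = 43.5,
                       event_rate_size_exp = 1.3,
                       flock_duration_mean_s = 240,
                       visit_rate_in_event = 1.5,
                       flock_size_max = 16.5,
                       flock_size_halfsat = 40,
                       join_prob = NULL,
                       join_concentration = 3,
                       pair_bond_fraction = 0.85,
                       bond_cohesion = 0.95,
                       unit_size_mean = 4,
                       unit_time_window_h = 2,
                       multi_feeder_prob = 0.3,
                       daylight_window_s = c(7, 17) * 3600,
                       seed = 1L) {
  stop_if_not_scalar_num(n_locations, "n_locations", lower = 1)
  stop_if_not_scalar_num(grid_spacing_m, "grid_spacing_m", lower = 1e-6)
  stop_if_not_scalar_num(n_years, "n_years", lower = 1)
  stop_if_not_scalar_num(weeks_per_year, "weeks_per_year", lower = 1)
  stop_if_not_scalar_num(sample_days_per_week, "sample_days_per_week", lower = 1)
  stop_if_not_scalar_num(location_effect_sd, "location_effect_sd", lower = 0)
  stop_if_not_scalar_num(mean_log_popsize, "mean_log_popsize")
  stop_if_not_scalar_num(edge_effect, "edge_effect")
  stop_if_not_scalar_num(flock_rate_per_day, "flock_rate_per_day", lower = 0)
  stop_if_not_scalar_num(event_rate_size_exp, "event_rate_size_exp")
  stop_if_not_scalar_num(flock_duration_mean_s, "flock_duration_mean_s", lower = 0)
  stop_if_not_scalar_num(visit_rate_in_event, "visit_rate_in_event", lower = 0)
  if (!is.null(join_prob)) stop_if_not_scalar_num(join_prob, "join_prob", 0, 1)
  stop_if_not_scalar_num(flock_size_max, "flock_size_max", lower = 1e-6)
  stop_if_not_scalar_num(flock_size_halfsat, "flock_size_halfsat", lower = 0)
  stop_if_not_scalar_num(join_concentration, "join_concentration", lower = 1e-6)
  stop_if_not_scalar_num(pair_bond_fraction, "pair_bond_fraction", 0, 1)
  stop_if_not_scalar_num(bond_cohesion, "bond_cohesion", 0, 1)
  stop_if_not_scalar_num(unit_size_mean, "unit_size_mean", lower = 2)
  if (!is.null(unit_time_window_h)) {
    stop_if_not_scalar_num(unit_time_window_h, "unit_time_window_h", lower = 0.1)
  }
  stop_if_not_scalar_num(multi_feeder_prob, "multi_feeder_prob", 0, 1)
  if (is.null(year_effects)) year_effects <- rep(0, n_years)
  if (length(year_effects) != n_years) {
    stop("'year_effects' must have one entry per year", call. = FALSE)
  }
  cfg <- list(
    n_locations = as.integer(n_locations),
    grid_spacing_m = grid_spacing_m,
    n_years = as.integer(n_years),
    weeks_per_year = as.integer(weeks_per_year),
    sample_days_per_week = as.integer(sample_days_per_week),
    location_effect_sd = location_effect_sd,
    edge_effect = edge_effect,
    mean_log_popsize = mean_log_popsize,
    week_trend = week_trend,
    year_effects = year_effects,
    flock_rate_per_day = flock_rate_per_day,
    event_rate_size_exp = event_rate_size_exp,
    flock_duration_mean_s = flock_duration_mean_s,
    visit_rate_in_event = visit_rate_in_event,
    flock_size_max = flock_size_max,
    flock_size_halfsat = flock_size_halfsat,
    join_prob = join_prob,
    join_concentration = join_concentration,
    pair_bond_fraction = pair_bond_fraction,
    bond_cohesion = bond_cohesion,
    unit_size_mean = unit_size_mean,
    unit_time_window_h = unit_time_window_h,
    multi_feeder_prob = multi_feeder_prob,
    daylight_window_s = daylight_window_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Feeder grid and study-site boundary
#'
#' Places `n_locations` feeders on an evenly spaced rectangular grid and
#' surrounds them with a rectangular boundary polygon at half a grid spacing,
#' so every feeder lies strictly inside the study site and distance to the
#' edge varies from the margin up to the site half-width.
#'
#' @param config a [sim_config()].
#' @param boundary optional polygon (two-column matrix of x, y vertices, not
#'   closed) to use instead of the default rectangle; all feeders must fall
#'   strictly inside it.
#' @return an object of class `flock_geometry`: a list with `feeders`
#'   (data.frame: location_id, x, y), `boundary` (vertex matrix) and
#'   `spacing`.
#' @export
generate_geometry <- function(config, boundary = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_locations
  sp <- config$grid_spacing_m
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  idx <- seq_len(n) - 1L
  col <- idx %% ncol_
  row <- idx %/% ncol_
  margin <- sp / 2
  x <- margin + col * sp
  y <- margin + row * sp
  feeders <- data.frame(
    location_id = sprintf("L%02d", seq_len(n)),
    x = x, y = y,
    stringsAsFactors = FALSE
  )
  if (is.null(boundary)) {
    w <- margin + (ncol_ - 1) * sp + margin
    h <- margin + (nrow_ - 1) * sp + margin
    boundary <- cbind(x = c(0, w, w, 0), y = c(0, 0, h, h))
  } else {
    boundary <- as.matrix(boundary)
  }
  if (abs(polygon_area(boundary)) < 1e-9) {
    stop("boundary polygon has zero area", call. = FALSE)
  }
  inside <- vapply(seq_len(n), function(i) {
    point_in_polygon(c(feeders$x[i], feeders$y[i]), boundary)
  }, logical(1))
  if (!all(inside)) {
    stop("boundary polygon too small: some feeders fall outside it",
         call. = FALSE)
  }
  structure(list(feeders = feeders, boundary = boundary, spacing = sp),
            class = "flock_geometry")
}

#' Latent repeatability implied by a generator configuration
#'
#' The between-location variance on the log scale is the sum of the random
#' location-effect variance and the variance contributed by the edge-distance
#' gradient (the covariate is standardized across locations, so the gradient
#' contributes `edge_effect^2`). The within-location (distribution-specific)
#' variance of the log-link Poisson model is \eqn{\ln(1/\lambda + 1)}
#' evaluated at the marginal mean. Repeatability on the latent scale is the
#' between-location share of their sum.
#'
#' @param config a [sim_config()].
#' @return a number in (0, 1).
#' @export
implied_repeatability <- function(config) {
  v_b <- config$location_effect_sd^2 + config$edge_effect^2
  mu <- config$mean_log_popsize + mean(config$year_effects) +
    config$week_trend * (config$weeks_per_year + 1) / 2
  lambda <- exp(mu + v_b / 2)
  v_d <- log(1 / lambda + 1)
  v_b / (v_b + v_d)
}

#' Location-effect SD needed for a target latent repeatability
#'
#' Inverts [implied_repeatability()] by fixed-point iteration: the
#' distribution-specific variance depends on the marginal mean, which in turn
#' depends on the between-location variance being solved for.
#'
#' @param R target latent repeatability in \[0, 1).
#' @param config a [sim_config()]; its `edge_effect` and `mean_log_popsize`
#'   are held fixed.
#' @return the `location_effect_sd` giving latent repeatability `R`.
#' @export
location_sd_for_repeatability <- function(R, config) {
  stop_if_not_scalar_num(R, "R", 0, 1 - 1e-9)
  mu <- config$mean_log_popsize + mean(config$year_effects) +
    config$week_trend * (config$weeks_per_year + 1) / 2
  v_b <- 0.1
  for (i in 1:50) {
    lambda <- exp(mu + v_b / 2)
    v_d <- log(1 / lambda + 1)
    v_b <- R / (1 - R) * v_d
  }
  v_loc <- v_b - config$edge_effect^2
  if (v_loc < 0) {
    stop("edge_effect alone already exceeds the between-location variance ",
         "needed for the requested repeatability", call. = FALSE)
  }
  sqrt(v_loc)
}

#' Draw weekly local population sizes for every location
#'
#' @param config a [sim_config()].
#' @param geometry a [generate_geometry()] result.
#' @param seed RNG seed (default derived from the config seed).
#' @return a data.frame (class `popsize_table`) with columns location_id,
#'   year, week, size, plus attributes `location_effects` and `lambda`.
#' @export
draw_location_week_popsizes <- function(config, geometry,
                                        seed = child_seed(config$seed, "popsizes")) {
  stopifnot(inherits(config, "sim_config"), inherits(geometry, "flock_geometry"))
  set.seed(seed)
  f <- geometry$feeders
  d_edge <- vapply(seq_len(nrow(f)), function(i) {
    distance_to_edge(c(f$x[i], f$y[i]), geometry$boundary)
  }, numeric(1))
  z <- if (stats::sd(d_edge) > 0) (d_edge - mean(d_edge)) / stats::sd(d_edge) else d_edge * 0
  a <- stats::rnorm(nrow(f), 0, config$location_effect_sd)
  log_lambda_loc <- config$mean_log_popsize + config$edge_effect * z + a

  grid <- expand.grid(
    week = seq_len(config$weeks_per_year),
    year = seq_len(config$n_years),
    location = seq_len(nrow(f)),
    KEEP.OUT.ATTRS = FALSE
  )
  log_lambda <- log_lambda_loc[grid$location] +
    config$week_trend * grid$week + config$year_effects[grid$year]
  size <- rztpois(nrow(grid), exp(log_lambda))
  out <- data.frame(
    location_id = f$location_id[grid$location],
    year = grid$year,
    week = grid$week,
    size = as.integer(size),
    stringsAsFactors = FALSE
  )
  attr(out, "location_effects") <- stats::setNames(a, f$location_id)
  attr(out, "dist_to_edge") <- stats::setNames(d_edge, f$location_id)
  attr(out, "lambda") <- exp(log_lambda)
  class(out) <- c("popsize_table", "data.frame")
  out
}

# Partition a fraction of a pool into bonded social units. With
# size_mean = 2 every unit is a pair bond; larger means give small roving
# sub-flocks (sizes 2 + Poisson).
make_social_units <- function(tags, fraction, size_mean = 2) {
  n_bonded <- floor(length(tags) * fraction)
  if (n_bonded < 2) return(list())
  chosen <- sample(tags, n_bonded)
  units <- list()
  i <- 1L
  while (i <= n_bonded - 1L) {
    sz <- if (size_mean <= 2) 2L else 2L + stats::rpois(1, size_mean - 2)
    sz <- min(sz, n_bonded - i + 1L)
    if (sz < 2) break
    units[[length(units) + 1L]] <- chosen[i:(i + sz - 1L)]
    i <- i + sz
  }
  units
}

# All within-unit dyads as a two-column matrix
units_to_dyads <- function(units) {
  rows <- lapply(units, function(u) {
    if (length(u) < 2) return(NULL)
    t(utils::combn(sort(u), 2))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) matrix(character(0), ncol = 2) else out
}

#' Simulate one location-week visit stream
#'
#' Event start times form a homogeneous Poisson process within the daylight
#' window of each sampling day (rate scaled by population size, see
#' [sim_config()]); each roster individual joins an event with its
#' Beta-drawn propensity, except that bonded social units decide jointly
#' (all members or none) with probability `bond_cohesion`. When the
#' configuration sets a unit activity window, a unit deciding jointly only
#' joins events inside its own window of the day (with the joining
#' probability rescaled so marginal attendance is unchanged) — this is what
#' lets a small population fall apart into sub-flocks that rarely meet.
#' Each attending individual makes a Poisson (minimum 1) number of antenna
#' visits concentrated around the middle of the event interval. Events that
#' attract no individual leave no trace and are dropped.
#'
#' @param roster character vector of tag ids present this location-week.
#' @param config a [sim_config()].
#' @param location_id,year,week identifiers stamped on the output rows.
#' @param units bonded social units: a list of tag-id character vectors, or
#'   a two-column matrix of bonded dyads (each row one pair). Members absent
#'   from the roster are ignored; units with fewer than 2 present members
#'   are inactive.
#' @param seed RNG seed.
#' @return a data.frame with columns tag_id, location_id, timestamp_s, year,
#'   week, day, sorted by timestamp, with attribute `truth` (a list with the
#'   generated event table and the per-visit event assignment). An empty
#'   roster yields an empty stream with a warning.
#' @export
simulate_visit_stream <- function(roster, config, location_id = "L01",
                                  year = 1L, week = 1L, units = NULL,
                                  seed = child_seed(config$seed, "stream",
                                                    location_id, year, week)) {
  stopifnot(inherits(config, "sim_config"))
  empty <- data.frame(tag_id = character(0), location_id = character(0),
                      timestamp_s = numeric(0), year = integer(0),
                      week = integer(0), day = integer(0),
                      stringsAsFactors = FALSE)
  if (length(roster) == 0) {
    warning("empty roster: returning empty visit stream")
    attr(empty, "truth") <- list(events = data.frame(), assignment = integer(0))
    return(empty)
  }
  set.seed(seed)
  n <- length(roster)
  if (is.matrix(units)) units <- split(units, row(units))
  units <- lapply(units, function(u) u[u %in% roster])
  units <- units[vapply(units, length, integer(1)) >= 2]
  # a very small population is one loosely connected flock: below 7 birds
  # the whole roster forages as a single unit
  if (length(roster) >= 2 && length(roster) < 7 && config$bond_cohesion > 0) {
    units <- list(roster)
  }
  week_origin <- ((year - 1) * config$weeks_per_year + (week - 1)) * 7 * 86400
  dw <- config$daylight_window_s

  # per-bird event-joining propensity for this location-week; the mean
  # follows the saturating flock-size curve unless a fixed join_prob is set
  p_bar <- config$join_prob %||%
    min(0.95, config$flock_size_max / (n + config$flock_size_halfsat))
  p_join <- if (is.finite(config$join_concentration) && p_bar > 0 && p_bar < 1) {
    stats::rbeta(n, p_bar * config$join_concentration,
                 (1 - p_bar) * config$join_concentration)
  } else {
    rep(p_bar, n)
  }
  names(p_join) <- roster

  # per-unit mean propensity, optional activity window (center drawn per
  # location-week), and the window-rescaled joint joining probability
  n_units <- length(units)
  day_len <- dw[2] - dw[1]
  win_frac <- 1
  win_lo <- win_hi <- NULL
  if (n_units > 0) {
    p_unit <- vapply(units, function(u) mean(p_join[u]), numeric(1))
    # a lone sub-flock has nothing to segregate from: windows only apply
    # when at least two units share the location; the width relaxes to the
    # full day away from populations of ~10 birds
    w <- if (is.null(config$unit_time_window_h) || n_units < 2) Inf else {
      w10 <- config$unit_time_window_h * 3600
      day_len - (day_len - w10) * exp(-((n - 10) / 9)^2)
    }
    if (w < day_len) {
      win_frac <- w / day_len
      centre_u <- stats::runif(n_units, dw[1] + w / 2, dw[2] - w / 2)
      win_lo <- centre_u - w / 2
      win_hi <- centre_u + w / 2
      p_unit <- pmin(0.95, p_unit / win_frac)
    }
  }

  rows <- list()
  ev_rows <- list()
  ev_id <- 0L
  rate <- config$flock_rate_per_day *
    (n / exp(config$mean_log_popsize))^config$event_rate_size_exp
  for (day in seq_len(config$sample_days_per_week)) {
    k <- stats::rpois(1, rate)
    if (k == 0) next
    starts <- sort(stats::runif(k, dw[1], dw[2]))
    durs <- stats::rexp(k, 1 / config$flock_duration_mean_s)
    # keep consecutive events temporally distinct: an event ends before 80%
    # of the gap to the next start has elapsed
    gap_next <- c(diff(starts), Inf)
    durs <- pmin(durs, 0.8 * gap_next)
    for (e in seq_len(k)) {
      join <- stats::runif(n) < p_join
      names(join) <- roster
      if (n_units > 0) {
        cohesion_eff <- config$bond_cohesion * min(1, (10 / n)^2)
        for (b in seq_len(n_units)) {
          if (stats::runif(1) < cohesion_eff) {
            in_window <- is.null(win_lo) ||
              (starts[e] >= win_lo[b] && starts[e] <= win_hi[b])
            shared <- in_window && stats::runif(1) < p_unit[b]
            join[units[[b]]] <- shared
          }
        }
      }
      members <- roster[join]
      if (length(members) == 0) next
      ev_id <- ev_id + 1L
      n_visits <- pmax(1L, stats::rpois(length(members), config$visit_rate_in_event))
      # visit activity peaks mid-event: Gaussian around the event centre,
      # clipped to the event interval
      centre <- starts[e] + durs[e] / 2
      tod <- stats::rnorm(sum(n_visits), centre, durs[e] / 4)
      tod <- pmin(pmax(tod, starts[e]), starts[e] + durs[e])
      ts <- week_origin + (day - 1) * 86400 + tod
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = rep(members, n_visits),
        location_id = location_id,
        timestamp_s = ts,
        year = year, week = week, day = day,
        event = ev_id,
        stringsAsFactors = FALSE
      )
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        event = ev_id, day = day,
        start_s = week_origin + (day - 1) * 86400 + starts[e],
        duration_s = durs[e],
        n_members = length(members),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    attr(empty, "truth") <- list(events = data.frame(), assignment = integer(0))
    return(empty)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$timestamp_s)
  out <- out[ord, , drop = FALSE]
  truth_assignment <- out$event
  out$event <- NULL
  rownames(out) <- NULL
  attr(out, "truth") <- list(events = do.call(rbind, ev_rows),
                             assignment = truth_assignment,
                             units = units)
  out
}

#' Plant perfectly separated flocking events (testing utility)
#'
#' Builds a stream of `n_events` events with centres on a regular grid
#' `gap_s` seconds apart and visit times Gaussian around each centre with SD
#' `spread_s`. Used to verify event-detection recovery when clusters are
#' unambiguous (gap much larger than spread).
#'
#' @param n_events number of events.
#' @param gap_s distance between consecutive event centres (seconds).
#' @param spread_s within-event SD of visit times (seconds).
#' @param tags pool of tag ids.
#' @param members_per_event individuals per event (sampled from `tags`).
#' @param visits_per_member visits each member makes.
#' @param seed RNG seed.
#' @return data.frame (tag_id, timestamp_s, day) sorted by time, with a
#'   `truth` attribute holding the planted event index per visit.
#' @export
plant_events <- function(n_events, gap_s, spread_s, tags = sprintf("B%02d", 1:10),
                         members_per_event = 4, visits_per_member = 3,
                         seed = 1L) {
  set.seed(seed)
  centres <- gap_s * seq_len(n_events)
  rows <- lapply(seq_len(n_events), function(e) {
    members <- sample(tags, min(members_per_event, length(tags)))
    ts <- stats::rnorm(length(members) * visits_per_member, centres[e], spread_s)
    data.frame(tag_id = rep(members, each = visits_per_member),
               timestamp_s = ts, day = 1L, event = e,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$timestamp_s), , drop = FALSE]
  truth <- out$event
  out$event <- NULL
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Simulate a full multi-location, multi-week dataset
#'
#' Each location hosts a disjoint pool of resident birds (with pair bonds
#' formed within pools); a weekly roster of the drawn population size is
#' composed of residents plus a visitor fraction drawn from the pools of the
#' nearest neighbouring feeders, so that birds use on average slightly more
#' than one feeder per week while the drawn population size is preserved
#' exactly.
#'
#' @param config a [sim_config()].
#' @param geometry optional pre-built [generate_geometry()] result.
#' @return a list of class `flock_sim`: `visit_log` (one data.frame across
#'   all location-weeks), `popsizes` (the drawn [draw_location_week_popsizes()]
#'   table), `geometry`, `config`, and `truth` (location effects, bonds,
#'   rosters, per-stream event assignments, implied latent repeatability).
#' @export
simulate_dataset <- function(config, geometry = generate_geometry(config)) {
  stopifnot(inherits(config, "sim_config"))
  pops <- draw_location_week_popsizes(config, geometry)
  f <- geometry$feeders
  n_loc <- nrow(f)

  set.seed(child_seed(config$seed, "pools"))
  max_size <- tapply(pops$size, pops$location_id, max)
  pool_size <- pmax(4L, ceiling(2 * max_size[f$location_id]))
  pools <- lapply(seq_len(n_loc), function(i) {
    sprintf("%s_B%03d", f$location_id[i], seq_len(pool_size[i]))
  })
  names(pools) <- f$location_id
  social_units <- lapply(pools, make_social_units,
                         fraction = config$pair_bond_fraction,
                         size_mean = config$unit_size_mean)
  all_units <- do.call(c, unname(social_units))
  bonds <- units_to_dyads(all_units)

  dmat <- as.matrix(stats::dist(f[, c("x", "y")]))
  diag(dmat) <- Inf
  neighbours <- lapply(seq_len(n_loc), function(i) {
    order(dmat[i, ])[seq_len(min(4L, n_loc - 1L))]
  })

  visitor_frac <- config$multi_feeder_prob / (1 + config$multi_feeder_prob)

  # roster sampling units per pool: bonded units stay together, so bonded
  # dyads co-occur in weekly rosters and social preferences are expressed
  pool_units <- lapply(names(pools), function(loc) {
    p <- pools[[loc]]
    in_unit <- unlist(social_units[[loc]], use.names = FALSE)
    c(social_units[[loc]], as.list(setdiff(p, in_unit)))
  })
  names(pool_units) <- names(pools)

  sample_units <- function(units, n_target) {
    if (n_target <= 0 || length(units) == 0) return(character(0))
    picked <- character(0)
    for (u in sample(length(units))) {
      picked <- c(picked, units[[u]])
      if (length(picked) >= n_target) break
    }
    picked[seq_len(min(n_target, length(picked)))]
  }

  streams <- vector("list", nrow(pops))
  rosters <- vector("list", nrow(pops))
  for (r in seq_len(nrow(pops))) {
    loc <- pops$location_id[r]
    i <- match(loc, f$location_id)
    n_target <- pops$size[r]
    set.seed(child_seed(config$seed, "roster", loc, pops$year[r], pops$week[r]))
    n_vis <- if (n_loc > 1) round(visitor_frac * n_target) else 0L
    n_home <- n_target - n_vis
    n_home <- min(n_home, length(pools[[i]]))
    roster <- sample_units(pool_units[[i]], n_home)
    if (n_vis > 0) {
      visitor_pool <- unlist(pools[neighbours[[i]]], use.names = FALSE)
      roster <- c(roster, sample(visitor_pool, min(n_vis, length(visitor_pool))))
    }
    rosters[[r]] <- roster
    streams[[r]] <- simulate_visit_stream(
      roster, config, location_id = loc,
      year = pops$year[r], week = pops$week[r], units = all_units
    )
  }
  truth_events <- lapply(streams, attr, "truth")
  visit_log <- do.call(rbind, streams)
  rownames(visit_log) <- NULL
  names(truth_events) <- names(rosters) <-
    sprintf("%s_y%d_w%02d", pops$location_id, pops$year, pops$week)
  structure(list(
    visit_log = visit_log,
    popsizes = pops,
    geometry = geometry,
    config = config,
    truth = list(
      location_effects = attr(pops, "location_effects"),
      dist_to_edge = attr(pops, "dist_to_edge"),
      bonds = bonds,
      units = all_units,
      rosters = rosters,
      events = truth_events,
      implied_R = implied_repeatability(config)
    )
  ), class = "flock_sim")
}

#' Sample shrub-cover quadrat densities over the study site
#'
#' Draws quadrat centre points uniformly in the boundary polygon and
#' evaluates a latent density surface at them. Three surface families are
#' available: a smooth low-order cosine field (default; its true surface
#' function is returned for recovery tests), a Gaussian-process draw with a
#' spherical covariance of known range (for variogram recovery), and a
#' constant field.
#'
#' @param geometry a [generate_geometry()] result.
#' @param n_samples number of quadrats (default 164).
#' @param surface one of "cosine", "gp", "constant".
#' @param mean_density,amplitude mean level and fluctuation scale of the
#'   density field.
#' @param gp_range,gp_sill spherical-covariance parameters for
#'   `surface = "gp"`.
#' @param noise_sd independent measurement noise SD (default 0: noiseless).
#' @param seed RNG seed.
#' @return data.frame (x, y, density); for "cosine" and "constant" an
#'   attribute `surface_fn(x, y)` gives the noiseless latent surface.
#' @export
generate_shrub_samples <- function(geometry, n_samples = 164,
                                   surface = c("cosine", "gp", "constant"),
                                   mean_density = 5, amplitude = 2,
                                   gp_range = 200, gp_sill = 1,
                                   noise_sd = 0, seed = 1L) {
  surface <- match.arg(surface)
  set.seed(seed)
  b <- geometry$boundary
  xr <- range(b[, 1]); yr <- range(b[, 2])
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n_samples) {
    cand <- cbind(stats::runif(2 * n_samples, xr[1], xr[2]),
                  stats::runif(2 * n_samples, yr[1], yr[2]))
    keep <- apply(cand, 1, point_in_polygon, polygon = b)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n_samples), , drop = FALSE]

  if (surface == "constant") {
    fn <- function(x, y) rep(mean_density, length(x))
  } else if (surface == "cosine") {
    lx <- diff(xr); ly <- diff(yr)
    ph <- stats::runif(3, 0, 2 * pi)
    fn <- function(x, y) {
      mean_density + amplitude * (
        cos(2 * pi * x / lx + ph[1]) +
          cos(2 * pi * y / ly + ph[2]) +
          0.5 * cos(2 * pi * (x + y) / (lx + ly) + ph[3])
      ) / 2.5
    }
  } else {
    fn <- NULL
  }

  if (surface == "gp") {
    h <- as.matrix(stats::dist(pts))
    C <- gp_sill - spherical_gamma(h, gp_sill, gp_range)
    L <- chol(C + diag(1e-8, n_samples))
    z <- mean_density + drop(t(L) %*% stats::rnorm(n_samples))
  } else {
    z <- fn(pts[, 1], pts[, 2])
  }
  if (noise_sd > 0) z <- z + stats::rnorm(n_samples, 0, noise_sd)
  out <- data.frame(x = pts[, 1], y = pts[, 2], density = pmax(0, z))
  if (!is.null(fn)) attr(out, "surface_fn") <- fn
  out
}

#' Write the generator outputs as plain-text files
#'
#' Visit log and shrub samples as CSV, feeders as CSV, the boundary as a WKT
#' POLYGON, and the ground truth as JSON.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param shrub optional [generate_shrub_samples()] result.
#' @return invisibly, the vector of files written.
#' @export
write_sim <- function(sim, dir, shrub = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    visit_log = file.path(dir, "visit_log.csv"),
    feeders = file.path(dir, "feeders.csv"),
    boundary = file.path(dir, "boundary.wkt"),
    popsizes = file.path(dir, "popsizes.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  utils::write.csv(sim$visit_log, files["visit_log"], row.names = FALSE)
  utils::write.csv(sim$geometry$feeders, files["feeders"], row.names = FALSE)
  writeLines(polygon_to_wkt(sim$geometry$boundary), files["boundary"])
  utils::write.csv(as.data.frame(sim$popsizes), files["popsizes"], row.names = FALSE)
  truth <- list(
    location_effects = as.list(sim$truth$location_effects),
    implied_R = sim$truth$implied_R,
    bonds = apply(sim$truth$bonds, 1, paste, collapse = "--")
  )
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(shrub)) {
    f <- file.path(dir, "shrub_samples.csv")
    utils::write.csv(shrub, f, row.names = FALSE)
    files <- c(files, shrub = f)
  }
  invisible(files)
}

polygon_to_wkt <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%g %g", ring[, 1], ring[, 2]), collapse = ", "))
}

#' Read a visit log written by [write_sim()] (or of the same schema)
#' @param path CSV path with columns tag_id, location_id, timestamp_s, year,
#'   week, day.
#' @return the visit-log data.frame.
#' @export
read_visit_log <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "location_id", "timestamp_s", "year", "week", "day")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("visit log is missing columns: ", paste(miss, collapse = ", "))
  v
}
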