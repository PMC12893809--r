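# Synthetic data with known ground truth: movement tracks, landscapes,
# breeding sites and TFA-model tables.  Every generator is a pure function of
# its scenario plus seed, and its outputs pass the corresponding analysis
# module's input validation unchanged.

#' Movement-track scenario
#'
#' Describes the stated world for a simulated juvenile: a stationary OU (or
#' OUF) process centred on the nest, an abrupt emigration to a displaced
#' centre on `onset_day`, irregular diurnal sampling (5 min to 4 h), a winter
#' data gap, and ~5% of fixes violating the HDOP/satellite QC rule.
#'
#' @param sigma2 Per-axis stationary variance, m^2 (default 300 m sd, a
#'   territory-scale pre-dispersal range).
#' @param tau_pos Position autocorrelation time, seconds (default 6 h).
#' @param tau_vel Velocity autocorrelation time, seconds; 0 for plain OU.
#' @param nest Nest `(x, y)` in the working projection, metres.
#' @param onset_day Integer day index (0-based from `start_date`) of
#'   emigration.
#' @param displacement Post-onset shift of the process centre, metres.
#' @param schedule Sampling intervals (seconds) drawn uniformly per step.
#' @param day_window UTC hours within which fixes are attempted.
#' @param gap_windows List of `c(first_day, last_day)` 0-based day ranges with
#'   no fixes (default: a 60-day winter block when the track is long enough).
#' @param n_days Scenario length in days.
#' @param start_date First tracking date.
#' @param hatch_date Hatch date (ages are measured from it).
#' @param qc_violation_rate Fraction of fixes given failing HDOP/satellites.
#' @param proj Working projection for lon/lat back-conversion.
#' @param seed Integer seed.
#' @return List of class `track_scenario`.
#' @export
track_scenario <- function(sigma2 = 300^2, tau_pos = 6 * 3600, tau_vel = 0,
                           nest = c(0, 0), onset_day = 40,
                           displacement = 6000,
                           schedule = c(300, 900, 1800, 3600, 7200, 14400),
                           day_window = c(6, 18),
                           gap_windows = NULL, n_days = 365,
                           start_date = as.Date("2023-06-15"),
                           hatch_date = as.Date("2023-04-20"),
                           qc_violation_rate = 0.05,
                           proj = tm_projection(52.5, 13.4), seed = 1) {
  stopifnot(onset_day < n_days, all(schedule > 0), sigma2 > 0, tau_pos >= 0)
  if (is.null(gap_windows) && n_days >= 240)
    gap_windows <- list(c(170, 229)) # 60-day winter block
  structure(as.list(environment()), class = "track_scenario")
}

#' Simulate a GPS track from a scenario
#'
#' Positions are drawn from the exact transition distributions of the
#' stationary OU/OUF process at the irregular sample times (no
#' discretisation error); the process centre jumps from the nest to
#' `nest + displacement` (random direction) at `onset_day`.
#'
#' @param s A [track_scenario()].
#' @return A `raptor_track`; the ground truth (onset date, displaced centre,
#'   generating parameters) is attached as attribute `truth`.
#' @export
simulate_track <- function(s) {
  stopifnot(inherits(s, "track_scenario"))
  set.seed(s$seed)
  # sampling times
  gap_days <- unlist(lapply(s$gap_windows, function(w) w[1]:w[2]))
  tt <- numeric(0)
  for (d in 0:(s$n_days - 1)) {
    if (d %in% gap_days) next
    t0 <- d * 86400 + s$day_window[1] * 3600
    t1 <- d * 86400 + s$day_window[2] * 3600
    t <- t0
    while (t < t1) {
      tt <- c(tt, t)
      t <- t + sample(s$schedule, 1)
    }
  }
  n <- length(tt)
  th <- stats::runif(1, 0, 2 * pi)
  shift <- s$displacement * c(cos(th), sin(th))
  # exact zero-mean process
  z <- matrix(0, n, 2)
  if (s$tau_vel > 0) {
    st <- cbind(stats::rnorm(2, 0, sqrt(s$sigma2)),
                stats::rnorm(2, 0, sqrt(s$sigma2 / (s$tau_pos * s$tau_vel))))
    z[1, ] <- st[, 1]
    for (k in 2:n) {
      d <- ouf_disc(tt[k] - tt[k - 1], s$tau_pos, s$tau_vel)
      ev <- eigen(d$Q * s$sigma2, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
      st <- d$Phi %*% st + L %*% matrix(stats::rnorm(4), 2)
      z[k, ] <- st[1, ]
    }
  } else if (s$tau_pos > 0) {
    z[1, ] <- stats::rnorm(2, 0, sqrt(s$sigma2))
    for (k in 2:n) {
      r <- exp(-(tt[k] - tt[k - 1]) / s$tau_pos)
      z[k, ] <- r * z[k - 1, ] +
        stats::rnorm(2, 0, sqrt(s$sigma2 * (1 - r^2)))
    }
  } else {
    z[] <- stats::rnorm(2 * n, 0, sqrt(s$sigma2))
  }
  day <- floor(tt / 86400)
  ctr <- matrix(rep(s$nest, each = n), n)
  post <- day >= s$onset_day
  ctr[post, 1] <- ctr[post, 1] + shift[1]
  ctr[post, 2] <- ctr[post, 2] + shift[2]
  xy <- z + ctr
  bad <- stats::runif(n) < s$qc_violation_rate
  hdop <- ifelse(bad & stats::runif(n) < 0.5, stats::runif(n, 4.5, 9),
                 stats::runif(n, 0.6, 3.5))
  sats <- ifelse(bad & hdop <= 4, sample(3:4, n, replace = TRUE),
                 sample(5:12, n, replace = TRUE))
  ll <- unproject_xy(xy[, 1], xy[, 2], s$proj)
  fixes <- data.table::data.table(
    timestamp = as.POSIXct(s$start_date, tz = "UTC") + tt,
    lon = ll[, 1], lat = ll[, 2], x = xy[, 1], y = xy[, 2],
    hdop = hdop, n_satellites = as.integer(sats))
  tr <- new_track(sprintf("sim%03d", s$seed), fixes, s$proj,
                  nest = s$nest, hatch_date = s$hatch_date)
  attr(tr, "truth") <- list(onset_date = s$start_date + s$onset_day,
                            centre_post = s$nest + shift,
                            sigma2 = s$sigma2, tau_pos = s$tau_pos,
                            tau_vel = s$tau_vel)
  tr
}

# seeded Gaussian random field on an nr x nc grid via separable Gaussian
# smoothing of white noise, standardised to the requested sill (variance)
gaussian_field <- function(nr, nc, range_cells, sill = 1) {
  wn <- matrix(stats::rnorm((nr + 4 * range_cells) * (nc + 4 * range_cells)),
               nr + 4 * range_cells)
  kx <- stats::dnorm(seq(-2 * range_cells, 2 * range_cells), sd = range_cells)
  sm <- apply(wn, 2, function(col) stats::filter(col, kx, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, kx, sides = 2)))
  core <- sm[(2 * range_cells + 1):(2 * range_cells + nr),
             (2 * range_cells + 1):(2 * range_cells + nc)]
  core <- (core - mean(core, na.rm = TRUE)) / stats::sd(core, na.rm = TRUE)
  core * sqrt(sill)
}

#' Landscape scenario
#'
#' @param extent Square landscape side length, metres.
#' @param cell Cell size, metres.
#' @param field_range Spatial correlation range of the random fields, metres.
#' @param sills Named per-layer marginal variances (on the natural scale of
#'   each layer).
#' @param n_habitat_seeds Seed patches per habitat class (6 classes:
#'   1 residential, 2 urban mixed, 3 natural mixed, 4 city parks,
#'   5 cemeteries, 6 others).
#' @param water_fraction Approximate fraction of the landscape that is water.
#' @param proj Working projection.
#' @param seed Integer seed.
#' @return List of class `landscape_scenario`.
#' @export
landscape_scenario <- function(extent = 10000, cell = 50, field_range = 500,
                               sills = c(tree_cover = 400, imperviousness = 625,
                                         pop_density = 900, human_footprint = 25),
                               n_habitat_seeds = 5, water_fraction = 0.05,
                               centre = c(0, 0),
                               proj = tm_projection(52.5, 13.4), seed = 1) {
  stopifnot(extent %% cell == 0)
  structure(as.list(environment()), class = "landscape_scenario")
}

#' Simulate a predictor landscape
#'
#' Continuous layers are seeded Gaussian random fields scaled to plausible
#' ranges (tree cover and imperviousness clamped to [0, 100] %, population
#' density non-negative); the 6-class habitat layer grows from random seed
#' patches (nearest-seed assignment with a jittered distance); water is the
#' lowest fraction of an independent smooth field, polygonised along its
#' contour.
#'
#' @param s A [landscape_scenario()].
#' @return List of class `synthetic_landscape`: `layers` (named `uraster`s),
#'   `habitat` (categorical `uraster`), `water` (polygon list), `region`
#'   (boundary ring), `proj`, `scenario`.
#' @export
simulate_landscape <- function(s) {
  stopifnot(inherits(s, "landscape_scenario"))
  set.seed(s$seed)
  n <- s$extent / s$cell
  rc <- max(2, round(s$field_range / s$cell))
  x0 <- s$centre[1] - s$extent / 2; y1 <- s$centre[2] + s$extent / 2
  origin <- c(x0, y1) # NW corner
  mk <- function(sill, centre, lo, hi) {
    f <- gaussian_field(n, n, rc, sill) + centre
    pmin(pmax(f, lo), hi) # matrix first: pmin/pmax keep dims of arg 1
  }
  layers <- list(
    tree_cover = mk(s$sills[["tree_cover"]], 35, 0, 100),
    imperviousness = mk(s$sills[["imperviousness"]], 45, 0, 100),
    pop_density = mk(s$sills[["pop_density"]], 40, 0, Inf),
    human_footprint = mk(s$sills[["human_footprint"]], 25, 0, 50))
  layers <- lapply(layers, new_raster, origin = origin, cell = s$cell,
                   kind = "continuous")
  # habitat: nearest (jittered) seed over 6 classes
  ns <- 6 * s$n_habitat_seeds
  sx <- stats::runif(ns, x0, x0 + s$extent)
  sy <- stats::runif(ns, y1 - s$extent, y1)
  scls <- rep(1:6, each = s$n_habitat_seeds)
  cx <- x0 + (seq_len(n) - 0.5) * s$cell
  cy <- y1 - (seq_len(n) - 0.5) * s$cell
  gx <- matrix(cx, n, n, byrow = TRUE); gy <- matrix(cy, n, n)
  best_d <- matrix(Inf, n, n); hab <- matrix(1, n, n)
  jit <- gaussian_field(n, n, rc, (s$extent / 20)^2)
  for (k in seq_len(ns)) {
    d <- sqrt((gx - sx[k])^2 + (gy - sy[k])^2) + jit * (k %% 3 - 1) / 2
    sel <- d < best_d
    hab[sel] <- scls[k]; best_d[sel] <- d[sel]
  }
  habitat <- new_raster(hab, origin, s$cell, kind = "categorical")
  # water: lowest `water_fraction` of an independent smooth field
  wf <- gaussian_field(n, n, 2 * rc, 1)
  thr <- stats::quantile(wf, s$water_fraction)
  cl <- grDevices::contourLines(x = cx, y = rev(cy), z = t(wf[n:1, ]),
                                levels = thr)
  water <- lapply(cl, function(p) cbind(x = p$x, y = p$y))
  water <- Filter(function(w) nrow(w) >= 4, water)
  y0 <- y1 - s$extent
  region <- rbind(c(x0, y0), c(x0 + s$extent, y0),
                  c(x0 + s$extent, y1), c(x0, y1), c(x0, y0))
  colnames(region) <- c("x", "y")
  structure(list(layers = layers, habitat = habitat, water = water,
                 region = region, proj = s$proj, scenario = s),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("<synthetic_landscape> %g m extent @ %g m, layers: %s\n",
              x$scenario$extent, x$scenario$cell,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Sample breeding sites from a known suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' `exp(linear predictor)`; coefficient names refer to continuous layers
#' (per natural unit) or habitat indicators written as `"habitat=k"`.
#'
#' @param landscape A `synthetic_landscape`.
#' @param coefficients Named numeric vector, e.g.
#'   `c(tree_cover = 0.05, "habitat=4" = 1.5)`.
#' @param n_presence Number of sites.
#' @param seed Integer seed.
#' @return List: `points` (matrix `x`, `y`, cell centres), `truth`
#'   (suitability `uraster`, normalised to sum 1), `eta` (linear-predictor
#'   raster values).
#' @export
simulate_breeding_sites <- function(landscape, coefficients, n_presence, seed = 1) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  hab <- landscape$habitat$values
  eta <- matrix(0, nrow(hab), ncol(hab))
  for (nm in names(coefficients)) {
    if (grepl("^habitat=", nm)) {
      code <- as.numeric(sub("^habitat=", "", nm))
      eta <- eta + coefficients[[nm]] * (hab == code)
    } else {
      if (!nm %in% names(landscape$layers))
        stop("coefficient references unknown layer: ", nm)
      eta <- eta + coefficients[[nm]] * landscape$layers[[nm]]$values
    }
  }
  p <- exp(eta - max(eta))
  if (all(p == 0)) stop("all-zero sampling probabilities")
  set.seed(seed)
  idx <- sample(length(p), n_presence, prob = as.vector(p))
  r <- landscape$habitat
  row <- (idx - 1) %% nrow(hab) + 1
  col <- (idx - 1) %/% nrow(hab) + 1
  cc <- cell_centres(r)
  pts <- cbind(x = cc$x[col], y = cc$y[row])
  truth <- new_raster(p / sum(p), r$origin, r$cell, kind = "continuous")
  list(points = pts, truth = truth, eta = eta)
}

#' Simulate a TFA table from a known GLMM
#'
#' Population densities are log-uniform on [1, 300] inhabitants/ha; responses
#' are drawn from the stated random-intercept GLMM.
#'
#' @param n_individuals,tfa_per_ind Grouping structure.
#' @param beta Fixed effects `(intercept, slope)` on the model scale
#'   (poisson: log days vs raw density; gaussian: log ha vs log density).
#' @param sigma2_u Random-intercept variance.
#' @param sigma2_e Residual variance (gaussian only).
#' @param family `"poisson"` or `"gaussian"`.
#' @param seed Integer seed.
#' @return data.table: `individual_id`, `mean_pop_density`, `response`
#'   (days for poisson, ha for gaussian), plus the true `u` per row.
#' @export
simulate_tfa_table <- function(n_individuals = 22, tfa_per_ind = 4,
                               beta = NULL, sigma2_u = 0.25, sigma2_e = 0.5,
                               family = c("poisson", "gaussian"), seed = 1) {
  family <- match.arg(family)
  if (is.null(beta))
    beta <- if (family == "poisson") c(5.6, -0.02) else c(3.5, -0.3)
  set.seed(seed)
  J <- n_individuals
  n <- J * tfa_per_ind
  g <- rep(seq_len(J), each = tfa_per_ind)
  x <- exp(stats::runif(n, log(1), log(300)))
  u <- stats::rnorm(J, 0, sqrt(sigma2_u))
  if (family == "poisson") {
    eta <- beta[1] + beta[2] * x + u[g]
    y <- stats::rpois(n, exp(eta))
  } else {
    eta <- beta[1] + beta[2] * log(x) + u[g]
    y <- exp(eta + stats::rnorm(n, 0, sqrt(sigma2_e)))
  }
  data.table::data.table(individual_id = sprintf("ind%02d", g),
                         mean_pop_density = x, response = y, u = u[g])
}
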