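test_that("empirical variogram matches closed forms", {
  # IID: flat at sigma^2
  tr <- iid_track(400, sigma = 2, seed = 3)
  v <- empirical_variogram(tr, n_lags = 10)
  expect_true(all(abs(v$semivariance - 4) / 4 < 0.25))
  expect_true(v$resident)
  # OU: gamma(dt) = sigma2 (1 - exp(-dt/tau)); bins kept narrow relative to
  # tau so the theory at the bin centre represents the bin
  # track spans ~500 tau so single-realisation noise stays small
  tau <- 3600; s2 <- 100
  tro <- ou_track(2000, s2, tau, dt = 900, seed = 4)
  vo <- empirical_variogram(tro, n_lags = 30, max_lag = 5 * tau)
  thy <- s2 * (1 - exp(-vo$lag_centres / tau))
  expect_lt(max(abs(vo$semivariance - thy) / s2), 0.15)
  # two-fix track: one populated lag with a single pair
  t2 <- make_track(c(0, 3), c(0, 4), ts_utc(c(0, 3600)))
  v2 <- empirical_variogram(t2, n_lags = 1, max_lag = 7200)
  expect_equal(v2$pairs_per_lag, 1L)
  expect_equal(v2$semivariance, (9 + 16) / 4)
})

test_that("IID fit is the closed-form sample variance", {
  tr <- iid_track(300, sigma = 1.7, seed = 5)
  m <- fit_movement_model(tr, "IID")
  s2 <- (var(tr$fixes$x) + var(tr$fixes$y)) / 2
  expect_equal(m$sigma2, s2, tolerance = 1e-9)
  expect_equal(m$mu, c(mean(tr$fixes$x), mean(tr$fixes$y)))
  # AICc definition
  expect_equal(m$aicc, 2 * 3 - 2 * m$loglik + 2 * 3 * 4 / (m$n - 4))
})

test_that("OU likelihood approaches the IID likelihood as tau -> 0", {
  tr <- iid_track(200, seed = 6)
  tt <- as.numeric(tr$fixes$timestamp)
  pr <- urbanraptor:::profile_nll(
    urbanraptor:::ou_innovations(tr$fixes$x, tt, 1e-6),
    urbanraptor:::ou_innovations(tr$fixes$y, tt, 1e-6))
  iid <- fit_movement_model(tr, "IID")
  expect_equal(pr$loglik, iid$loglik, tolerance = 1e-6)
})

test_that("compiled OUF filter agrees with the plain-R reference filter", {
  tr <- ou_track(150, 50, 4 * 3600, dt = 1800, seed = 7)
  z <- tr$fixes$x; tt <- as.numeric(tr$fixes$timestamp)
  a <- urbanraptor:::ouf_innovations_r(z, tt, 3 * 3600, 900)
  b <- urbanraptor:::ouf_innovations_cpp(z, tt, 3 * 3600, 900)
  expect_equal(a$ed, b$ed, tolerance = 1e-10)
  expect_equal(a$ec, b$ec, tolerance = 1e-10)
  expect_equal(a$S, b$S, tolerance = 1e-10)
})

test_that("OU parameters are recovered from exact simulations", {
  # scaled down from the 20-seed criterion run (in test-acceptance.R)
  errs <- sapply(1:8, function(seed) {
    tr <- ou_track(1000, 250000, 86400, dt = 3600, seed = seed)
    m <- fit_movement_model(tr, "OU")
    c(abs(m$sigma2 / 250000 - 1), abs(m$tau_pos / 86400 - 1))
  })
  expect_lt(median(errs[1, ]), 0.25)
  expect_lt(median(errs[2, ]), 0.25)
})

test_that("AICc model selection identifies the generating class", {
  sel_iid <- sapply(1:10, function(seed) {
    tr <- iid_track(300, seed = seed)
    select_model(list(fit_movement_model(tr, "IID"),
                      fit_movement_model(tr, "OU")))$kind
  })
  expect_gte(mean(sel_iid == "IID"), 0.8)
  sel_ouf <- sapply(1:6, function(seed) {
    s <- track_scenario(sigma2 = 250000, tau_pos = 86400, tau_vel = 3 * 3600,
                        n_days = 40, onset_day = 39, displacement = 0,
                        schedule = 1800, gap_windows = list(),
                        qc_violation_rate = 0, seed = seed)
    tr <- simulate_track(s)
    select_model(list(fit_movement_model(tr, "IID"),
                      fit_movement_model(tr, "OU"),
                      fit_movement_model(tr, "OUF")))$kind
  })
  expect_gt(mean(sel_ouf == "OUF"), 0.5)
  # single candidate passes through; ties break to fewer parameters
  one <- fit_movement_model(iid_track(50), "IID")
  expect_identical(select_model(list(one)), one)
})

test_that("akde produces a unit-mass grid with the documented bandwidth", {
  tr <- iid_track(500, seed = 8)
  m <- fit_movement_model(tr, "IID")
  est <- akde(tr, m, weighted = TRUE, corrected = TRUE)
  expect_equal(sum(est$grid$values), 1, tolerance = 1e-6)
  expect_equal(est$bandwidth, m$sigma2 * 500^(-1 / 3))
  # regular sampling: temporal-Voronoi weights equal for interior fixes
  # (the end fixes carry half a cell by the clamped-end convention)
  expect_equal(est$weights[2:499], rep(1 / 499, 498))
  expect_equal(est$weights[c(1, 500)], rep(1 / 998, 2))
  expect_equal(est$n_area, 500)
})

test_that("IID akde equals the direct kernel-sum oracle", {
  tr <- iid_track(200, seed = 9)
  m <- fit_movement_model(tr, "IID")
  est <- akde(tr, m, weighted = FALSE, corrected = FALSE)
  g <- est$grid
  cc <- cell_centres(g)
  set.seed(1)
  rows <- sample(g$n_rows, 10); cols <- sample(g$n_cols, 10)
  H <- est$bandwidth
  for (k in 1:10) {
    direct <- mean(dnorm(cc$x[cols[k]], tr$fixes$x, sqrt(H)) *
                   dnorm(cc$y[rows[k]], tr$fixes$y, sqrt(H)))
    expect_equal(g$values[rows[k], cols[k]] / g$cell^2, direct,
                 tolerance = 1e-8)
  }
})

test_that("near-duplicate fixes leave the weighted density unchanged", {
  tr <- ou_track(200, 250000, 86400, dt = 3600, seed = 10)
  m <- fit_movement_model(tr, "OU")
  est1 <- akde(tr, m, weighted = TRUE, cell = 100)
  f2 <- rbind(tr$fixes, tr$fixes)
  f2$timestamp <- f2$timestamp + rep(c(0, 0.001), each = nrow(tr$fixes))
  tr2 <- new_track("dup", f2, tr$proj)
  est2 <- akde(tr2, m, weighted = TRUE, cell = 100)
  expect_lt(max(abs(est2$grid$values - est1$grid$values)) /
              max(est1$grid$values), 1e-6)
})

test_that("contours have correct mass geometry", {
  tr <- iid_track(2000, seed = 11)
  m <- fit_movement_model(tr, "IID")
  est <- akde(tr, m, weighted = FALSE, corrected = TRUE)
  c50 <- range_contour(est, 0.5)
  c95 <- range_contour(est, 0.95)
  expect_gte(c95$area, c50$area)                 # nesting
  expect_lt(abs(c50$area / (2 * pi * log(2) * m$sigma2) - 1), 0.12)
  expect_true(c50$ci_low < c50$area && c50$area < c50$ci_high)
  # uniform density on a rectangle: area = level x rectangle area (+/- cells)
  uni <- structure(list(
    grid = new_raster(matrix(1 / 200, 10, 20), c(0, 10), 1),
    n_area = 100, correction = 1), class = "range_estimate")
  cu <- range_contour(uni, 0.5)
  expect_lt(abs(cu$area - 0.5 * 200) / 200, 1 / 200 + 1e-9)
})

test_that("analytic Gaussian grid isopleth matches the closed form", {
  # density evaluated analytically on a fine grid, no sampling noise
  s2 <- 1
  cell <- 0.04
  ax <- seq(-4, 4, by = cell)
  d <- outer(dnorm(ax, 0, 1), dnorm(ax, 0, 1)) * cell^2
  est <- structure(list(grid = new_raster(d / sum(d), c(-4, 4), cell),
                        n_area = 1e6, correction = 1),
                   class = "range_estimate")
  ct <- range_contour(est, 0.5)
  expect_lt(abs(ct$area / (2 * pi * log(2) * s2) - 1), 0.05)
})
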