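# Independent oracle implementations used across the suite.  Each one is a
# deliberately naive algorithm, distinct from the package's code paths.

# winding-number point-in-polygon (vs the package's ray casting)
oracle_point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  vapply(seq_along(px), function(i) {
    dx <- poly[, 1] - px[i]; dy <- poly[, 2] - py[i]
    if (any(dx == 0 & dy == 0)) return(TRUE)
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > 1e-6
  }, logical(1))
}

# gift-wrapping (Jarvis march) convex hull, CCW
oracle_hull <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (length(hull) == 1) setdiff(seq_len(n), cur) else seq_len(n)[-cur]
    nxt <- cand[1]
    for (k in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
            (pts[nxt, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cr < 0 || (cr == 0 && d_k > d_nxt)) nxt <- k
    }
    cur <- nxt
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# shoelace on an arbitrary ring (re-derived here, not the package function)
oracle_area <- function(poly) {
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# build a minimal valid track from coordinates and times
make_track <- function(x, y, times, id = "t1", hdop = 1, sats = 8,
                       nest = NULL, hatch = NULL,
                       proj = tm_projection(52.5, 13.4)) {
  ll <- unproject_xy(x, y, proj)
  f <- data.table::data.table(timestamp = times, lon = ll[, 1], lat = ll[, 2],
                              x = x, y = y, hdop = hdop,
                              n_satellites = as.integer(sats))
  new_track(id, f, proj, nest = nest, hatch_date = hatch)
}

ts_utc <- function(s) as.POSIXct("2023-07-01 00:00:00", tz = "UTC") + s

# IID Gaussian track at hourly sampling
iid_track <- function(n, sigma = 1, seed = 1) {
  set.seed(seed)
  make_track(rnorm(n, 0, sigma), rnorm(n, 0, sigma), ts_utc(3600 * seq_len(n)))
}

# exact OU track at regular sampling (independent of the synthetic module)
ou_track <- function(n, sigma2, tau, dt = 3600, seed = 1) {
  set.seed(seed)
  r <- exp(-dt / tau)
  mk <- function() {
    z <- numeric(n)
    z[1] <- rnorm(1, 0, sqrt(sigma2))
    for (k in 2:n) z[k] <- r * z[k - 1] + rnorm(1, 0, sqrt(sigma2 * (1 - r^2)))
    z
  }
  make_track(mk(), mk(), ts_utc(dt * seq_len(n)))
}

fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  data.table::fwrite(df, path)
  path
}

basic_fix_df <- function(n = 3, id = "b1") {
  data.frame(individual_id = id,
             timestamp = format(ts_utc(3600 * seq_len(n)), "%Y-%m-%dT%H:%M:%S"),
             lon = 13.4 + (seq_len(n)) * 1e-4, lat = 52.5, hdop = 1.2,
             n_satellites = 8L)
}
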