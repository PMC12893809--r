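test_that("cluster_fixes separates well-spaced blobs and flags noise", {
  set.seed(21)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 40), rnorm(n, cy, 40))
  pts <- rbind(blob(0, 0, 200), blob(2000, 0, 200))
  df <- data.frame(x = pts[, 1], y = pts[, 2])
  lab <- cluster_fixes(df, eps = 150, min_pts = 10)
  expect_equal(length(unique(lab[lab > 0])), 2)
  # blobs map to distinct labels
  expect_equal(length(unique(lab[1:200][lab[1:200] > 0])), 1)
  expect_false(any(lab[1:200][lab[1:200] > 0] %in% lab[201:400]))
  # single blob: one cluster holding nearly all fixes
  lab1 <- cluster_fixes(df[1:200, ], eps = 150, min_pts = 10)
  expect_equal(max(lab1), 1)
  expect_gte(mean(lab1 == 1), 0.95)
  # permutation invariance (as a partition)
  perm <- sample(400)
  lab_p <- cluster_fixes(df[perm, ], eps = 150, min_pts = 10)
  expect_equal(lab_p[order(perm)] > 0, lab > 0)
  tab <- table(lab[lab > 0], lab_p[order(perm)][lab > 0])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("cluster_fixes equals a brute-force connectivity oracle", {
  set.seed(22)
  df <- data.frame(x = runif(120, 0, 600), y = runif(120, 0, 600))
  eps <- 80; minp <- 4
  lab <- cluster_fixes(df, eps = eps, min_pts = minp)
  # oracle: transitive closure over core-point adjacency
  d <- as.matrix(dist(df)) <= eps
  core <- rowSums(d) >= minp
  adj <- d & outer(core, core) # core-core edges
  reach <- adj | diag(nrow(df))
  for (k in seq_len(nrow(df)))
    reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  comp <- unname(apply(reach[, core, drop = FALSE], 1, function(r) which(r)[1]))
  # every pair of core points: same package cluster iff connected in oracle
  ci <- which(core)
  same_pkg <- outer(lab[ci], lab[ci], `==`)
  same_orc <- outer(comp[ci], comp[ci], `==`)
  expect_equal(same_pkg, same_orc)
})

test_that("habitat polygons split straddling clusters", {
  set.seed(23)
  pts <- data.frame(x = runif(300, -100, 100), y = runif(300, -50, 50))
  left <- rbind(c(-200, -100), c(0, -100), c(0, 100), c(-200, 100))
  right <- rbind(c(0, -100), c(200, -100), c(200, 100), c(0, 100))
  lab0 <- cluster_fixes(pts, eps = 60, min_pts = 5)
  expect_equal(max(lab0), 1)
  lab <- cluster_fixes(pts, eps = 60, min_pts = 5,
                       habitat = list(park = left, yard = right))
  expect_equal(length(unique(lab[lab > 0])), 2)
})

test_that("mcp95 drops the farthest 5% and matches the hull oracle", {
  set.seed(24)
  g <- expand.grid(x = seq(0, 1, length.out = 10), y = seq(0, 1, length.out = 10))
  out5 <- data.frame(x = c(5, -4, 6, 7, -8), y = c(5, 6, -7, 8, 9))
  pts <- rbind(g, out5)
  m <- mcp95(pts)
  expect_equal(sum(!m$kept), ceiling(0.05 * 105))
  expect_true(all(!m$kept[101:105])) # all five outliers removed
  expect_equal(m$area, 1, tolerance = 0.02)
  # monotone: mcp95 area <= full-hull area
  full <- oracle_area(oracle_hull(as.matrix(pts)))
  expect_lte(m$area, full)
  # area equals shoelace on the gift-wrapping oracle hull of kept points
  for (seed in 1:5) {
    set.seed(seed)
    p <- matrix(rnorm(80), ncol = 2)
    mm <- mcp95(p)
    expect_equal(mm$area, oracle_area(oracle_hull(p[mm$kept, ])),
                 tolerance = 1e-12)
  }
  # translation/rotation leave the area unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p <- matrix(rnorm(60), ncol = 2)
  p2 <- sweep(p %*% R, 2, c(100, -50), `+`)
  expect_equal(mcp95(p2)$area, mcp95(p)$area, tolerance = 1e-9)
  expect_error(mcp95(matrix(1:8, ncol = 2)), ">= 5")
  colin <- cbind(seq(0, 1, length.out = 30), seq(0, 2, length.out = 30))
  expect_error(mcp95(colin), "degenerate|collinear")
})

test_that("qualification thresholds behave exactly at the boundary", {
  day <- 86400
  mk <- function(n, days) ts_utc(seq(0, (days - 1) * day, length.out = n))
  expect_false(qualify_tfa(mk(29, 15))$accept) # fix count
  expect_match(qualify_tfa(mk(29, 15))$reasons, "fixes")
  expect_false(qualify_tfa(mk(40, 9))$accept)  # period
  expect_match(qualify_tfa(mk(40, 9))$reasons, "period")
  expect_true(qualify_tfa(mk(30, 10))$accept)  # both at the boundary
  # accepted clusters satisfy both predicates on re-check
  q <- qualify_tfa(mk(35, 12))
  expect_true(q$n_fixes >= 30 && q$period_days >= 10)
})

test_that("occupancy span is the central 95% interquantile range in days", {
  set.seed(25)
  tt <- ts_utc(sort(runif(1000, 0, 100 * 86400)))
  expect_equal(occupancy_timespan(tt), 95, tolerance = 2 / 95)
  expect_equal(occupancy_timespan(rep(ts_utc(0), 5)), 0)
  # equals brute-force sorted-array quantiles
  tt2 <- ts_utc(c(0, 5, 20, 40, 80, 1000) * 3600)
  s <- sort(as.numeric(tt2))
  expect_equal(occupancy_timespan(tt2),
               (quantile(s, 0.975, names = FALSE) -
                quantile(s, 0.025, names = FALSE)) / 86400)
  # alternative convention: 0.95 quantile of time since first fix
  expect_equal(occupancy_timespan(tt2, convention = "upper"),
               quantile(s - s[1], 0.95, names = FALSE) / 86400)
})

test_that("mean_covariate averages cell centres inside the polygon", {
  const <- new_raster(matrix(7, 10, 10), c(0, 100), 10)
  sq <- rbind(c(5, 5), c(95, 5), c(95, 95), c(5, 95))
  expect_equal(mean_covariate(sq, const), 7)
  # checkerboard over a large square: close to 0.5
  ch <- new_raster(outer(1:40, 1:40, function(i, j) (i + j) %% 2), c(0, 400), 10)
  big <- rbind(c(0, 0), c(400, 0), c(400, 400), c(0, 400))
  expect_equal(mean_covariate(big, ch), 0.5, tolerance = 0.01)
  # equals the brute-force centre-in-polygon scan on an odd polygon
  set.seed(26)
  r <- new_raster(matrix(runif(400), 20, 20), c(0, 200), 10)
  # vertices off the cell-centre lattice so no centre sits on an edge
  poly <- rbind(c(10.31, 15.77), c(180.13, 40.41), c(150.59, 190.23),
                c(40.87, 120.11))
  cc <- cell_centres(r)
  acc <- c()
  for (i in 1:20) for (j in 1:20)
    if (oracle_point_in_polygon(cc$x[j], cc$y[i], poly))
      acc <- c(acc, r$values[i, j])
  expect_equal(mean_covariate(poly, r), mean(acc))
  expect_error(mean_covariate(rbind(c(1e5, 1e5), c(1e5 + 1, 1e5),
                                    c(1e5, 1e5 + 1)), r), "overlap|inside")
})

test_that("extract_tfas finds exactly the planted attractor clusters", {
  set.seed(27)
  day <- 86400
  mkblob <- function(cx, cy, n, t0)
    data.frame(x = rnorm(n, cx, 50), y = rnorm(n, cy, 50),
               t = t0 + sort(runif(n, 0, 40 * day)))
  b1 <- mkblob(0, 0, 60, 0); b2 <- mkblob(3000, 0, 60, 10 * day)
  noise <- data.frame(x = runif(6, -500, 3500), y = runif(6, 1500, 2500),
                      t = runif(6, 0, 50 * day))
  all <- rbind(b1, b2, noise)
  ord <- order(all$t)
  tr <- make_track(all$x[ord], all$y[ord], ts_utc(all$t[ord]))
  tfas <- extract_tfas(tr, eps = 150, min_pts = 10)
  expect_equal(nrow(tfas), 2)
  expect_true(all(tfas$n_fixes >= 30))
})
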