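# L-BFGS-B oracle for the penalised Gibbs objective: split lambda = a - b
# with a, b >= 0 so the L1 term becomes linear and smooth methods apply
oracle_maxent <- function(Fp, Fb, beta) {
  p <- ncol(Fp)
  obj <- function(par) {
    lam <- par[1:p] - par[p + 1:p]
    -(mean(Fp %*% lam) - log(sum(exp(Fb %*% lam))) -
        sum(beta * (par[1:p] + par[p + 1:p])))
  }
  o <- optim(rep(0, 2 * p), obj, method = "L-BFGS-B", lower = 0,
             control = list(maxit = 2000, factr = 1e4))
  list(lambda = o$par[1:p] - o$par[p + 1:p], objective = -o$value)
}

toy_data <- function(seed = 1, np = 50, nb = 500) {
  set.seed(seed)
  list(p = data.frame(u = rbeta(np, 4, 2), v = rnorm(np, 0.7, 0.2)),
       b = data.frame(u = runif(nb), v = runif(nb)))
}

test_that("feature construction follows the documented formulas", {
  d <- data.frame(u = c(0, 0.25, 0.5, 0.75, 1), v = 1:5,
                  hab = c("a", "b", "a", "a", "b"))
  spec <- make_feature_spec(d, c("linear", "quadratic", "product", "hinge"),
                            hinge_knots = 3)
  Fm <- build_features(d, spec)
  # knots at 0.25, 0.5, 0.75; forward hinge (x - k)/(1 - k)
  expect_equal(unname(Fm[4, "h+(u,0.500)"]), 0.5)
  expect_equal(unname(Fm[2, "h-(u,0.500)"]), 0.5)
  # at the covariate minimum: linear, quadratic and forward hinges all zero
  uc <- grep("^(u|u\\^2|h\\+\\(u)", colnames(Fm))
  expect_true(all(Fm[1, uc] == 0))
  # product features count C(p, 2); one-hot passes through
  expect_true("u*v" %in% colnames(Fm))
  expect_equal(sum(grepl("\\*", colnames(Fm))), choose(2, 2))
  expect_equal(unname(Fm[, "hab=a"]), c(1, 0, 1, 1, 0))
  # unseen category code errors
  expect_error(build_features(transform(d, hab = "zz"), spec), "unseen")
  # zero-variance covariate dropped with a message
  expect_message(make_feature_spec(data.frame(u = 1:5 / 5, w = 2),
                                   "linear"), "zero-variance")
})

test_that("a feature with identical presence/background means gets zero weight", {
  set.seed(51)
  Fp <- matrix(rep(c(0, 1), 25), ncol = 1)
  Fb <- matrix(rep(c(0, 1), 250), ncol = 1)
  m <- fit_maxent(Fp, Fb, beta_multiplier = 1)
  expect_equal(unname(m$lambda), 0)
})

test_that("the proximal fit matches a generic convex-solver oracle", {
  d <- toy_data(52)
  spec <- make_feature_spec(rbind(d$p, d$b), c("linear", "quadratic"))
  Fp <- build_features(d$p, spec); Fb <- build_features(d$b, spec)
  m <- fit_maxent(Fp, Fb, beta_multiplier = 1, tol = 1e-10)
  orc <- oracle_maxent(Fp, Fb, m$beta)
  expect_lt(abs(m$objective - orc$objective), 1e-4)
  expect_gte(m$objective, orc$objective - 1e-4) # ours is the (weak) winner
  # concavity: fitted objective never below the origin value
  expect_gte(m$objective,
             urbanraptor:::.maxent_objective(0 * m$lambda, Fp, Fb, m$beta))
})

test_that("the L1 path shrinks with the regularisation multiplier", {
  d <- toy_data(53)
  spec <- make_feature_spec(rbind(d$p, d$b), c("linear", "quadratic", "hinge"),
                            hinge_knots = 6)
  Fp <- build_features(d$p, spec); Fb <- build_features(d$b, spec)
  fits <- lapply(1:5, function(m) fit_maxent(Fp, Fb, beta_multiplier = m))
  l1 <- sapply(fits, function(f) sum(abs(f$lambda)))
  expect_true(all(diff(l1) <= 1e-8))
  # training gain (unpenalised part) is non-increasing in the multiplier
  gain <- sapply(fits, function(f)
    urbanraptor:::.maxent_objective(f$lambda, Fp, Fb, 0 * f$beta))
  expect_true(all(diff(gain) <= 1e-6))
})

test_that("raw predictions normalise over the background; logistic is monotone", {
  d <- toy_data(54)
  spec <- make_feature_spec(rbind(d$p, d$b), "hinge", hinge_knots = 5)
  Fp <- build_features(d$p, spec); Fb <- build_features(d$b, spec)
  m <- fit_maxent(Fp, Fb, spec = spec)
  raw_b <- predict(m, d$b)
  expect_equal(sum(raw_b), 1, tolerance = 1e-6)
  # lambda = 0: uniform raw over background
  m0 <- m; m0$lambda[] <- 0
  s <- as.vector(Fb %*% m0$lambda)
  m0$log_Z <- log(sum(exp(s)))
  expect_equal(predict(m0, d$b), rep(1 / 500, 500))
  raw <- predict(m, rbind(d$p, d$b))
  lg <- predict(m, rbind(d$p, d$b), type = "logistic")
  expect_true(all(diff(lg[order(raw)]) >= 0))
  expect_true(all(lg > 0 & lg < 1))
})

test_that("AUC equals the brute-force pairwise probability", {
  set.seed(55)
  pp <- runif(12); bb <- runif(18)
  wins <- 0
  for (a in pp) for (b in bb)
    wins <- wins + (a > b) + 0.5 * (a == b)
  expect_equal(auc_mw(pp, bb), wins / (12 * 18))
  # ties get half credit
  expect_equal(auc_mw(c(1, 1), c(1, 0)), 0.75)
  # invariance under strictly monotone transforms
  expect_equal(auc_mw(exp(3 * pp), exp(3 * bb)), auc_mw(pp, bb))
})

test_that("max_sss equals an exhaustive scan and honours tie rules", {
  set.seed(56)
  pp <- round(runif(10), 2); bb <- round(runif(10), 2)
  got <- max_sss_threshold(pp, bb)
  cand <- sort(unique(c(pp, bb)))
  sums <- sapply(cand, function(t) mean(pp >= t) + mean(bb < t))
  expect_equal(got$sensitivity + got$specificity, max(sums))
  expect_equal(got$threshold, cand[which.max(sums)]) # lowest maximiser
  expect_equal(got$tss, got$sensitivity + got$specificity - 1)
  # perfect separation
  ps <- max_sss_threshold(c(5, 6, 7), c(1, 2, 3))
  expect_equal(ps$tss, 1)
  expect_equal(ps$sensitivity, 1)
  # degenerate: all predictions identical
  expect_equal(max_sss_threshold(rep(2, 5), rep(2, 7))$tss, 0)
})

test_that("background sampling respects region, water, ratio and seed", {
  region <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  water <- list(rbind(c(400, 400), c(600, 400), c(600, 600), c(400, 600)))
  pts <- sample_background(region, water, n_presence = 20, ratio = 10, seed = 9)
  expect_equal(nrow(pts), 200)
  expect_true(all(point_in_polygon(pts[, 1], pts[, 2], region)))
  expect_false(any(point_in_any(pts[, 1], pts[, 2], water)))
  expect_equal(sample_background(region, water, 20, 10, seed = 9), pts)
  expect_error(sample_background(region, list(region), 5, 10, seed = 1),
               "empty")
})

test_that("cross-validation ranks an informative model above chance and
           shuffled labels near it", {
  set.seed(57)
  ls <- simulate_landscape(landscape_scenario(extent = 4000, seed = 57))
  sites <- simulate_breeding_sites(ls, c(tree_cover = 0.08), 60, seed = 57)
  bg <- sample_background(ls$region, ls$water, 60, ratio = 10, seed = 57)
  tc <- function(p) vapply(seq_len(nrow(p)), function(i)
    focal_mean(ls$layers$tree_cover, p[i, ], 200), numeric(1))
  pres <- data.frame(tree_cover = tc(sites$points))
  back <- data.frame(tree_cover = tc(bg))
  cv <- cross_validate_maxent(pres, back, feature_sets = list("hinge"),
                              multipliers = c(1, 3), k = 5, seed = 1,
                              hinge_knots = 8, max_iter = 400)
  expect_gt(cv$grid$mean_auc[1], 0.65)
  expect_s3_class(cv$best_model, "maxent_model")
  # shuffled presences: no signal left
  all_tc <- rbind(pres, back)
  set.seed(58)
  idx <- sample(nrow(all_tc), nrow(pres))
  cv0 <- cross_validate_maxent(all_tc[idx, , drop = FALSE],
                               all_tc[-idx, , drop = FALSE],
                               feature_sets = list("hinge"),
                               multipliers = 1, k = 5, seed = 1,
                               hinge_knots = 8, max_iter = 400)
  expect_lt(abs(cv0$grid$mean_auc[1] - 0.5), 0.07)
})

test_that("binarisation and area accounting follow the masking rules", {
  n <- 60 # 3 km x 3 km at 50 m
  suit <- new_raster(matrix(0.9, n, n), c(0, 3000), 50)
  hab <- new_raster(matrix(rep(1:4, each = n * n / 4), n, n), c(0, 3000), 50,
                    kind = "categorical")
  # one isolated nest buffer on a fully suitable grid removes ~pi km^2
  rep1 <- binarize_and_account(suit, 0.5, habitat = hab,
                               occupied_nests = cbind(1500, 1500),
                               buffer_radius = 1000)
  excluded <- rep1$total_suitable_km2 - rep1$unoccupied_suitable_km2
  expect_lt(abs(excluded - pi) / pi, 0.01)
  expect_equal(rep1$total_suitable_km2, 9)
  expect_equal(sum(rep1$by_habitat_class_km2), rep1$total_suitable_km2)
  # threshold above the maximum: nothing suitable
  rep2 <- binarize_and_account(suit, 0.95)
  expect_equal(rep2$total_suitable_km2, 0)
  # per-class areas equal brute-force cell enumeration under a random surface
  set.seed(59)
  sv <- new_raster(matrix(runif(n * n), n, n), c(0, 3000), 50)
  rep3 <- binarize_and_account(sv, 0.6, habitat = hab)
  for (cl in 1:4) {
    manual <- sum(sv$values >= 0.6 & hab$values == cl) * 0.0025
    expect_equal(unname(rep3$by_habitat_class_km2[as.character(cl)]), manual)
  }
  # masked polygons are forced unsuitable
  msk <- list(rbind(c(0, 0), c(3000, 0), c(3000, 3000), c(0, 3000)))
  rep4 <- binarize_and_account(suit, 0.5, mask = msk)
  expect_equal(rep4$total_suitable_km2, 0)
  expect_error(binarize_and_account(suit, 0.5,
                                    habitat = new_raster(matrix(1, 5, 5),
                                                         c(0, 3000), 50,
                                                         "categorical")),
               "mismatch")
})
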