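# exact multivariate-normal ML oracle for the Gaussian LMM: generic optimiser
# over (beta, log sigma2_u, log sigma2_e) with a dense covariance matrix
oracle_lmm <- function(y, x, g) {
  g <- as.factor(g)
  Z <- outer(as.integer(g), seq_len(nlevels(g)), `==`) + 0
  X <- cbind(1, x)
  nll <- function(par) {
    beta <- par[1:2]; s2u <- exp(par[3]); s2e <- exp(par[4])
    V <- s2u * tcrossprod(Z) + s2e * diag(length(y))
    r <- y - X %*% beta
    as.numeric(determinant(V)$modulus + t(r) %*% solve(V, r)) / 2 +
      length(y) / 2 * log(2 * pi)
  }
  o <- optim(c(mean(y), 0, 0, 0), nll, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  o <- optim(o$par, nll, method = "BFGS", control = list(reltol = 1e-14))
  list(beta = o$par[1:2], loglik = -o$value)
}

test_that("gaussian fit matches the exact GLS oracle on a small dataset", {
  set.seed(31)
  g <- rep(c("a", "b", "c"), each = 5)
  x <- exp(runif(15, 0, 3))
  y <- exp(1.5 - 0.4 * log(x) + rep(rnorm(3, 0, 0.5), each = 5) + rnorm(15, 0, 0.3))
  fit <- fit_glmm(data.frame(response = y, predictor = x, individual_id = g),
                  family = "gaussian")
  orc <- oracle_lmm(log(y), log(x), g)
  expect_equal(fit$beta, orc$beta, tolerance = 1e-6)
  expect_equal(fit$loglik, orc$loglik, tolerance = 1e-8)
})

test_that("with no group variance the slope collapses to the ordinary GLM", {
  set.seed(32)
  tab <- simulate_tfa_table(n_individuals = 30, tfa_per_ind = 4,
                            beta = c(4, -0.01), sigma2_u = 0, family = "poisson",
                            seed = 32)
  fit <- fit_glmm(tab, "poisson", response = "response",
                  predictor = "mean_pop_density")
  glm_fit <- glm(round(response) ~ mean_pop_density, poisson(), data = tab)
  expect_equal(fit$beta[2], unname(coef(glm_fit)[2]), tolerance = 1e-4)
  expect_true(fit$singular || fit$sigma2_u < 1e-3)
})

test_that("poisson slope is recovered across simulations", {
  slopes <- sapply(1:10, function(seed) {
    tab <- simulate_tfa_table(n_individuals = 40, tfa_per_ind = 3,
                              beta = c(5.6, -0.02), sigma2_u = 0.25,
                              family = "poisson", seed = seed)
    fit_glmm(tab, "poisson", response = "response",
             predictor = "mean_pop_density")$beta[2]
  })
  expect_lt(abs(median(slopes) / -0.02 - 1), 0.15)
})

test_that("noiseless log-linear data give an exact gaussian fit", {
  x <- exp(seq(0, 3, length.out = 12))
  y <- exp(2 - 0.5 * log(x))
  tab <- data.frame(response = y, predictor = x,
                    individual_id = rep(c("a", "b", "c"), 4))
  fit <- fit_glmm(tab, "gaussian")
  expect_equal(fit$beta, c(2, -0.5), tolerance = 1e-6)
  expect_lt(fit$sigma2_e, 1e-10)
  expect_equal(unname(fit$fitted), log(y), tolerance = 1e-5)
})

test_that("our Laplace Poisson fit agrees with lme4 glmer", {
  skip_if_not_installed("lme4")
  tab <- simulate_tfa_table(n_individuals = 25, tfa_per_ind = 4,
                            family = "poisson", seed = 33)
  fit <- fit_glmm(tab, "poisson", response = "response",
                  predictor = "mean_pop_density")
  gm <- suppressMessages(suppressWarnings(lme4::glmer(
    round(response) ~ mean_pop_density + (1 | individual_id),
    data = tab, family = stats::poisson())))
  expect_equal(fit$beta, unname(lme4::fixef(gm)), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(gm)), tolerance = 1e-4)
})

test_that("alternative loglik dominates the null (nesting)", {
  for (seed in 1:5) {
    tab <- simulate_tfa_table(family = "poisson", seed = seed)
    a <- fit_glmm(tab, "poisson", response = "response",
                  predictor = "mean_pop_density")
    n <- fit_glmm(tab, "poisson", response = "response",
                  predictor = "mean_pop_density", slope = FALSE)
    expect_gte(a$loglik, n$loglik - 1e-6)
  }
})

test_that("bootstrap LRT hits the floor under a strong effect and stays near
           1 when there is nothing to find", {
  tab <- simulate_tfa_table(n_individuals = 20, tfa_per_ind = 4,
                            beta = c(5.6, -0.02), sigma2_u = 0.1,
                            family = "poisson", seed = 34)
  a <- fit_glmm(tab, "poisson", response = "response",
                predictor = "mean_pop_density")
  n0 <- fit_glmm(tab, "poisson", response = "response",
                 predictor = "mean_pop_density", slope = FALSE)
  lrt <- bootstrap_lrt(n0, a, n_boot = 49, seed = 7)
  expect_equal(lrt$p_boot, 1 / 50)            # p floor = 1/(n_boot + 1)
  expect_gt(lrt$statistic, 0)
  # null-true data: large p, small statistic
  tabn <- simulate_tfa_table(n_individuals = 20, tfa_per_ind = 4,
                             beta = c(4.5, 0), sigma2_u = 0.1,
                             family = "poisson", seed = 35)
  an <- fit_glmm(tabn, "poisson", response = "response",
                 predictor = "mean_pop_density")
  nn <- fit_glmm(tabn, "poisson", response = "response",
                 predictor = "mean_pop_density", slope = FALSE)
  lrt0 <- bootstrap_lrt(nn, an, n_boot = 49, seed = 8)
  expect_gt(lrt0$p_boot, 0.1)
  # reproducible under the same seed
  lrt0b <- bootstrap_lrt(nn, an, n_boot = 49, seed = 8)
  expect_equal(lrt0$p_boot, lrt0b$p_boot)
  expect_equal(lrt0$boot_stats, lrt0b$boot_stats)
})

test_that("probable-error predictions have the documented geometry", {
  tab <- simulate_tfa_table(n_individuals = 30, tfa_per_ind = 3,
                            beta = c(5.6, -0.02), family = "poisson", seed = 36)
  fit <- fit_glmm(tab, "poisson", response = "response",
                  predictor = "mean_pop_density")
  grid <- seq(5, 250, length.out = 20)
  pe <- predict_with_pe(fit, grid, level = 0.6745)
  # half-width on the link scale = z * SE with z = qnorm(0.5 + 0.6745/2)
  z <- qnorm(0.5 + 0.6745 / 2)
  expect_equal(z, 0.9832, tolerance = 1e-3)
  expect_equal(log(pe$upper) - pe$eta, z * pe$se, tolerance = 1e-10)
  # level -> 0 collapses the interval onto the mean
  pe0 <- predict_with_pe(fit, grid, level = 1e-12)
  expect_equal(pe0$lower, pe0$fit, tolerance = 1e-6)
  # negative fitted slope gives monotone decreasing predictions
  expect_true(all(diff(pe$fit) < 0))
})
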