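# Random-intercept GLMMs for the TFA analyses, plus parametric-bootstrap
# likelihood-ratio tests.
#
# Two families are supported, matching the two TFA models:
#   * poisson  - log link, response = occupancy span rounded to whole days;
#   * gaussian - identity link on log-transformed response and predictor.
# Both have a single fixed slope and a random intercept per individual.
#
# The Gaussian linear mixed model is fitted by exact profiled maximum
# likelihood (the marginal covariance is block-compound-symmetric, so GLS and
# the profile over the variance ratio are closed-form; only the ratio is
# optimised in 1-D).  The Poisson model uses a Laplace approximation to the
# marginal likelihood with the inner random-effect modes found by a Newton
# iteration vectorised over groups.  Everything is plain ML so that nested
# log-likelihoods are directly comparable in the bootstrap LRT - a documented
# deviation from PQL-style fitting, whose quasi-likelihoods are not suited to
# likelihood-ratio calibration.

#' Fit a random-intercept GLMM
#'
#' @param data data.frame with the response, predictor and grouping columns.
#' @param family `"poisson"` (log link, integer response) or `"gaussian"`.
#' @param response,predictor,group Column names.
#' @param log_response,log_predictor Apply natural-log transforms before
#'   fitting (defaults follow the two TFA models: both `TRUE` for gaussian,
#'   both `FALSE` for poisson).
#' @param slope Include the fixed slope?  `FALSE` fits the intercept-only
#'   null model used by [bootstrap_lrt()].
#' @return Object of class `glmm_fit`: `beta`, `sigma2_u`, `sigma2_e`
#'   (gaussian), `loglik`, `fitted` (conditional means on the model scale),
#'   `vcov_beta`, `converged`, plus the model frame for refitting.
#' @export
fit_glmm <- function(data, family = c("poisson", "gaussian"),
                     response = "response", predictor = "predictor",
                     group = "individual_id",
                     log_response = NULL, log_predictor = NULL, slope = TRUE) {
  family <- match.arg(family)
  if (is.null(log_response)) log_response <- family == "gaussian"
  if (is.null(log_predictor)) log_predictor <- family == "gaussian"
  y <- data[[response]]; x <- data[[predictor]]
  g <- as.factor(data[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups for a random intercept")
  if (log_predictor) {
    if (any(x <= 0)) stop("predictor must be positive for log transform")
    x <- log(x)
  }
  if (family == "poisson") {
    y <- round(y)
    if (any(y < 0)) stop("negative counts")
    if (log_response) stop("poisson family models counts; no log transform")
    fit <- .fit_pois_laplace(y, x, g, slope)
  } else {
    if (log_response) {
      if (any(y <= 0)) stop("response must be positive for log transform")
      y <- log(y)
    }
    fit <- .fit_lmm_ml(y, x, g, slope)
  }
  fit$family <- family
  fit$transforms <- c(response = if (log_response) "log" else "none",
                      predictor = if (log_predictor) "log" else "none")
  fit$frame <- data.frame(y = y, x = x, g = g)
  fit$slope <- slope
  class(fit) <- "glmm_fit"
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit %s> beta = (%s), sigma2_u = %.4g%s, loglik = %.3f\n",
              x$family, paste(signif(x$beta, 5), collapse = ", "),
              x$sigma2_u,
              if (!is.null(x$sigma2_e)) sprintf(", sigma2_e = %.4g", x$sigma2_e)
              else "", x$loglik))
  invisible(x)
}

# exact profiled ML for the Gaussian random-intercept LMM
.fit_lmm_ml <- function(y, x, g, slope) {
  X <- if (slope) cbind(1, x) else cbind(rep(1, length(y)))
  N <- length(y); gi <- as.integer(g); J <- nlevels(g)
  nj <- tabulate(gi, J)
  nll2 <- function(loglam, want_fit = FALSE) {
    lam <- exp(loglam)
    cj <- lam / (1 + nj * lam)           # per group
    # XtWX = XtX - sum_j c_j (Xt 1_j)(1_j^t X)
    Sx <- rowsum(X, gi)                  # J x p group sums
    Sy <- rowsum(y, gi)
    XtWX <- crossprod(X) - crossprod(Sx * sqrt(cj))
    XtWy <- crossprod(X, y) - crossprod(Sx, cj * Sy)
    beta <- solve(XtWX, XtWy)
    r <- y - X %*% beta
    Sr <- rowsum(as.vector(r), gi)
    quad <- sum(r^2) - sum(cj * Sr^2)
    s2e <- quad / N
    val <- N * log(2 * pi * s2e) + sum(log(1 + nj * lam)) + N
    if (!want_fit) return(val)
    list(nll2 = val, beta = as.vector(beta), sigma2_e = s2e,
         sigma2_u = lam * s2e, lambda = lam,
         vcov_beta = s2e * solve(XtWX),
         u = (nj * lam / (1 + nj * lam)) * (Sr / nj),
         resid = as.vector(r))
  }
  o <- stats::optimize(nll2, interval = c(-15, 15))
  # boundary check: effectively zero random-effect variance
  if (nll2(-15) <= o$objective + 1e-10) o$minimum <- -15
  f <- nll2(o$minimum, want_fit = TRUE)
  singular <- f$lambda <= exp(-15) * 1.01
  fitted <- as.vector(X %*% f$beta) + f$u[as.integer(g)]
  list(beta = f$beta, sigma2_u = if (singular) 0 else f$sigma2_u,
       sigma2_e = f$sigma2_e, loglik = -f$nll2 / 2, fitted = fitted,
       vcov_beta = f$vcov_beta, u = f$u, singular = singular, converged = TRUE)
}

# Laplace marginal negative log-likelihood for the Poisson random-intercept
# GLMM; inner Newton vectorised over groups.
.pois_laplace_nll <- function(par, y, x, gi, J, slope, want_u = FALSE) {
  p <- if (slope) 2L else 1L
  beta <- par[1:p]
  s2 <- exp(2 * par[p + 1])
  c_i <- if (slope) beta[1] + beta[2] * x else rep(beta[1], length(y))
  if (max(c_i) > 50) return(1e10)
  ec <- exp(c_i)
  A <- rowsum(ec, gi)[, 1]
  S <- rowsum(y, gi)[, 1]
  B <- sum(y * c_i)
  u <- log((S + 0.5) / A) * s2 / (s2 + 1 / pmax(A, 1e-12)) # shrunken start
  u[!is.finite(u)] <- 0
  for (it in 1:60) {
    eu <- exp(pmin(u, 50))
    gr <- S - eu * A - u / s2
    he <- eu * A + 1 / s2
    step <- gr / he
    step <- pmax(pmin(step, 4), -4)
    u <- u + step
    if (max(abs(gr)) < 1e-9) break
  }
  eu <- exp(pmin(u, 50))
  H <- eu * A + 1 / s2
  ll <- B + sum(S * u) - sum(eu * A) - sum(lgamma(y + 1)) -
    sum(u^2) / (2 * s2) - J * log(s2) / 2 - sum(log(H)) / 2
  if (!is.finite(ll)) return(1e10)
  if (want_u) return(list(nll = -ll, u = u))
  -ll
}

.fit_pois_laplace <- function(y, x, g, slope, want_vcov = TRUE) {
  gi <- as.integer(g); J <- nlevels(g)
  p <- if (slope) 2L else 1L
  start <- c(log(mean(y) + 0.1), if (slope) 0, log(0.5))
  if (slope && stats::sd(x) > 0) {
    # crude moment start for the slope on the log scale
    z <- log(y + 0.5)
    b1 <- stats::cov(z, x) / stats::var(x)
    start[1:2] <- c(mean(z) - b1 * mean(x), b1)
  }
  obj <- function(par) .pois_laplace_nll(par, y, x, gi, J, slope)
  o <- stats::nlminb(start, obj, control = list(rel.tol = 1e-10))
  if (want_vcov) { # refine once from the optimum (helps flat sigma_u directions)
    o2 <- stats::nlminb(o$par, obj, control = list(rel.tol = 1e-10))
    if (o2$objective < o$objective) o <- o2
  }
  par <- o$par
  res <- .pois_laplace_nll(par, y, x, gi, J, slope, want_u = TRUE)
  vcov_beta <- matrix(NA_real_, p, p)
  if (want_vcov) {
    # observed-information vcov for beta by central finite differences
    hpar <- par[1:p]
    hfun <- function(b) .pois_laplace_nll(c(b, par[p + 1]), y, x, gi, J, slope)
    Hm <- matrix(0, p, p)
    eps <- 1e-4 * pmax(abs(hpar), 1)
    for (i in 1:p) for (j in i:p) {
      ei <- ej <- rep(0, p); ei[i] <- eps[i]; ej[j] <- eps[j]
      Hm[i, j] <- Hm[j, i] <-
        (hfun(hpar + ei + ej) - hfun(hpar + ei - ej) -
         hfun(hpar - ei + ej) + hfun(hpar - ei - ej)) / (4 * eps[i] * eps[j])
    }
    vcov_beta <- tryCatch(solve(Hm), error = function(e) matrix(NA, p, p))
  }
  c_i <- if (slope) par[1] + par[2] * x else rep(par[1], length(y))
  s2u <- exp(2 * par[p + 1])
  list(beta = par[1:p], sigma2_u = if (s2u < 1e-8) 0 else s2u,
       sigma2_e = NULL, loglik = -o$objective,
       fitted = exp(c_i + res$u[gi]), vcov_beta = vcov_beta, u = res$u,
       singular = s2u < 1e-8, converged = o$convergence == 0)
}

#' Parametric-bootstrap likelihood-ratio test for the fixed slope
#'
#' Simulates `n_boot` datasets from the fitted null (intercept-only) model -
#' drawing new random intercepts each time - refits both models to each
#' replicate, and compares the observed statistic `2 * (loglik_alt -
#' loglik_null)` with the simulated null distribution.
#'
#' @param null_fit,alt_fit `glmm_fit` objects on the same rows; `null_fit`
#'   must be `alt_fit` without the slope.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed (single RNG stream; replicates drawn in order).
#' @return List of class `lrt_result`: `statistic`, `df`, `p_boot`,
#'   `n_boot`, `n_failed`, `boot_stats`.
#' @export
bootstrap_lrt <- function(null_fit, alt_fit, n_boot = 1000, seed = 1) {
  stopifnot(inherits(null_fit, "glmm_fit"), inherits(alt_fit, "glmm_fit"),
            !null_fit$slope, alt_fit$slope,
            null_fit$family == alt_fit$family,
            nrow(null_fit$frame) == nrow(alt_fit$frame))
  fam <- null_fit$family
  fr <- null_fit$frame
  gi <- as.integer(fr$g); J <- nlevels(fr$g)
  t_obs <- 2 * (alt_fit$loglik - null_fit$loglik)
  set.seed(seed)
  stats_b <- rep(NA_real_, n_boot)
  su <- sqrt(null_fit$sigma2_u)
  for (b in seq_len(n_boot)) {
    u <- stats::rnorm(J, 0, su)
    eta <- null_fit$beta[1] + u[gi]
    yb <- if (fam == "poisson") stats::rpois(length(eta), exp(eta))
          else eta + stats::rnorm(length(eta), 0, sqrt(null_fit$sigma2_e))
    fb <- data.frame(y = yb, x = fr$x, g = fr$g)
    f0 <- try(if (fam == "poisson")
                .fit_pois_laplace(fb$y, fb$x, fb$g, FALSE, want_vcov = FALSE)
              else .fit_lmm_ml(fb$y, fb$x, fb$g, FALSE), silent = TRUE)
    f1 <- try(if (fam == "poisson")
                .fit_pois_laplace(fb$y, fb$x, fb$g, TRUE, want_vcov = FALSE)
              else .fit_lmm_ml(fb$y, fb$x, fb$g, TRUE), silent = TRUE)
    if (inherits(f0, "try-error") || inherits(f1, "try-error")) next
    stats_b[b] <- 2 * (f1$loglik - f0$loglik)
  }
  failed <- sum(is.na(stats_b))
  if (failed > 0.1 * n_boot)
    stop("more than 10% of bootstrap replicates failed to refit")
  if (failed > 0)
    message(failed, " bootstrap replicate(s) dropped (non-convergence)")
  ok <- stats_b[!is.na(stats_b)]
  p <- (1 + sum(ok >= t_obs - 1e-10)) / (length(ok) + 1)
  structure(list(statistic = t_obs, df = 1L, p_boot = p,
                 n_boot = length(ok), n_failed = failed, boot_stats = ok),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> LRT = %.3f, df = %d, p_boot = %.4g (%d replicates)\n",
              x$statistic, x$df, x$p_boot, x$n_boot))
  invisible(x)
}

#' Population-level predictions with a probable-error band
#'
#' Predicts the population-level (random effect at zero) response over a grid
#' of predictor values, with a symmetric normal-quantile interval computed
#' from the fixed-effect prediction variance.  The default level 0.6745
#' yields the "probable error" band expected to contain half the values
#' (half-width 0.9995 standard errors).
#'
#' @param fit A `glmm_fit` with slope.
#' @param grid Numeric vector of predictor values on the original scale.
#' @param level Central interval mass in (0, 1).
#' @return data.frame: `predictor`, `fit`, `lower`, `upper` (response scale),
#'   and the link-scale columns `eta`, `se`.
#' @export
predict_with_pe <- function(fit, grid, level = 0.6745) {
  stopifnot(inherits(fit, "glmm_fit"), fit$slope, level >= 0, level < 1)
  xg <- if (fit$transforms[["predictor"]] == "log") log(grid) else grid
  X <- cbind(1, xg)
  eta <- as.vector(X %*% fit$beta)
  se <- sqrt(pmax(0, rowSums((X %*% fit$vcov_beta) * X)))
  z <- stats::qnorm(0.5 + level / 2)
  inv <- if (fit$family == "poisson" ||
             fit$transforms[["response"]] == "log") exp else identity
  data.frame(predictor = grid, fit = inv(eta),
             lower = inv(eta - z * se), upper = inv(eta + z * se),
             eta = eta, se = se)
}
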