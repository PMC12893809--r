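# Continuous-time movement models fitted by exact Gaussian maximum likelihood.
#
# Three stationary, isotropic candidate processes are supported:
#   IID  - uncorrelated positions (no autocorrelation timescale),
#   OU   - Ornstein-Uhlenbeck position process, ACF exp(-dt/tau_p),
#   OUF  - position + correlated velocity, ACF
#          (tau_p exp(-dt/tau_p) - tau_v exp(-dt/tau_v)) / (tau_p - tau_v).
#
# OU and OUF are Markovian in a (position[, velocity]) state, so the exact
# likelihood is evaluated by sequential conditioning (a Kalman filter with
# exact discretisation at the observed, irregular time steps) in O(n).  The
# long-run mean and the variance scale sigma2 are profiled out analytically;
# only the timescales are optimised numerically.  This is plain ML (with AICc
# model selection), deliberately not a small-sample REML refinement.

.MODEL_DF <- c(IID = 3, OU = 4, OUF = 5) # mu_x, mu_y, sigma2 [, tau_p [, tau_v]]

# Exact discretisation of the OUF state (x, v) over a step dt, in sigma2 = 1
# units: returns the 2x2 transition matrix Phi and innovation covariance Q.
ouf_disc <- function(dt, tau_p, tau_v) {
  f1 <- 1 / tau_p; f2 <- 1 / tau_v
  A <- matrix(c(0, -f1 * f2, 1, -(f1 + f2)), 2, 2)
  e1 <- exp(-f1 * dt); e2 <- exp(-f2 * dt)
  Phi <- (e1 * (A + f2 * diag(2)) - e2 * (A + f1 * diag(2))) / (f2 - f1)
  Pinf <- diag(c(1, f1 * f2))
  Q <- Pinf - Phi %*% Pinf %*% t(Phi)
  list(Phi = Phi, Q = (Q + t(Q)) / 2, Pinf = Pinf)
}

# Innovation decomposition for one axis under OU dynamics (sigma2 = 1 units).
# Returns per-step innovations of the data (ed), of the all-ones mean
# regressor (ec) and innovation variances S.
ou_innovations <- function(z, tt, tau) {
  n <- length(z)
  r <- exp(-diff(tt) / tau)
  ed <- c(z[1], z[-1] - r * z[-n])
  ec <- c(1, 1 - r)
  S <- c(1, 1 - r^2)
  list(ed = ed, ec = ec, S = S)
}

# Same decomposition under OUF dynamics via a 2-state Kalman filter run
# jointly on the data series and the constant-1 mean regressor.  The
# compiled version (src/ouf_filter.cpp) is used in fitting; this plain-R
# twin is retained as the independent reference implementation for tests.
ouf_innovations_r <- function(z, tt, tau_p, tau_v) {
  n <- length(z)
  f1 <- 1 / tau_p; f2 <- 1 / tau_v
  Pinf <- diag(c(1, f1 * f2))
  m <- matrix(0, 2, 2)      # state means for (data, regressor)
  P <- Pinf
  ed <- ec <- S <- numeric(n)
  dts <- diff(tt)
  prev_dt <- -1; Phi <- NULL; Q <- NULL
  for (i in seq_len(n)) {
    if (i > 1) {
      dt <- dts[i - 1]
      if (dt != prev_dt) {
        d <- ouf_disc(dt, tau_p, tau_v)
        Phi <- d$Phi; Q <- d$Q; prev_dt <- dt
      }
      m <- Phi %*% m
      P <- Phi %*% P %*% t(Phi) + Q
    }
    # observe position component; measurement H = (1, 0), R = 0
    Si <- P[1, 1]
    ed[i] <- z[i] - m[1, 1]
    ec[i] <- 1 - m[1, 2]
    S[i] <- Si
    K <- P[, 1] / Si
    m <- m + K %*% rbind(c(ed[i], ec[i]))
    P <- P - tcrossprod(K) * Si
    P <- (P + t(P)) / 2
  }
  list(ed = ed, ec = ec, S = S)
}

# Profiled -2 log likelihood for both axes given innovation decompositions.
# mu and sigma2 are profiled analytically; returns the components needed to
# build the fitted model.
profile_nll <- function(inn_x, inn_y) {
  n <- length(inn_x$ed)
  if (any(!is.finite(inn_x$S)) || any(inn_x$S <= 0))
    return(list(nll2 = Inf, mu = c(NA, NA), sigma2 = NA, loglik = -Inf))
  prof <- function(inn) {
    w <- 1 / inn$S
    mu <- sum(inn$ed * inn$ec * w) / sum(inn$ec^2 * w)
    e <- inn$ed - mu * inn$ec
    list(mu = mu, quad = sum(e^2 * w))
  }
  px <- prof(inn_x); py <- prof(inn_y)
  sigma2 <- (px$quad + py$quad) / (2 * n)
  if (!is.finite(sigma2) || sigma2 <= 0)
    return(list(nll2 = Inf, mu = c(NA, NA), sigma2 = NA, loglik = -Inf))
  logdet <- 2 * sum(log(inn_x$S)) # S identical across axes
  nll2 <- 2 * n * log(2 * pi * sigma2) + logdet + 2 * n
  list(nll2 = nll2, mu = c(px$mu, py$mu), sigma2 = sigma2,
       loglik = -nll2 / 2)
}

#' Fit a continuous-time movement model to a track
#'
#' Fits one of the candidate stationary processes (`"IID"`, `"OU"`, `"OUF"`)
#' to the projected fix coordinates by exact maximum likelihood, profiling the
#' mean and variance and optimising autocorrelation timescales numerically.
#' A single isotropic variance `sigma2` per axis is assumed.
#'
#' For IID data the reported `sigma2` is the bias-corrected sample variance
#' averaged over axes; the log-likelihood is always the maximised Gaussian
#' likelihood so that AICc values are comparable across kinds.
#'
#' @param track A `raptor_track` with at least 20 fixes.
#' @param kind One of `"IID"`, `"OU"`, `"OUF"`.
#' @return Object of class `movement_model` with fields `kind`, `mu`,
#'   `sigma2` (m^2), `tau_pos`, `tau_vel` (seconds), `loglik`, `k_params`,
#'   `aicc`, `n`, `converged`.
#' @export
fit_movement_model <- function(track, kind = c("IID", "OU", "OUF")) {
  kind <- match.arg(kind)
  stopifnot(inherits(track, "raptor_track"))
  f <- track$fixes
  n <- nrow(f)
  if (n < 20) stop("need >= 20 fixes, got ", n)
  tt <- as.numeric(f$timestamp)
  if (any(diff(tt) <= 0)) stop("timestamps must be strictly increasing")
  x <- f$x; y <- f$y
  T_total <- tt[n] - tt[1]
  converged <- TRUE
  if (kind == "IID") {
    mu <- c(mean(x), mean(y))
    ssq <- sum((x - mu[1])^2) + sum((y - mu[2])^2)
    sigma2_ml <- ssq / (2 * n)
    loglik <- -(2 * n) / 2 * log(2 * pi * sigma2_ml) - ssq / (2 * sigma2_ml)
    sigma2 <- ssq / (2 * (n - 1)) # bias-corrected, reported
    tau_p <- 0; tau_v <- 0
  } else if (kind == "OU") {
    obj <- function(ltau) {
      tau <- exp(ltau)
      profile_nll(ou_innovations(x, tt, tau), ou_innovations(y, tt, tau))$nll2
    }
    med_dt <- stats::median(diff(tt))
    o <- stats::optimize(obj, interval = log(c(med_dt / 50, T_total * 10)))
    tau_p <- exp(o$minimum); tau_v <- 0
    pr <- profile_nll(ou_innovations(x, tt, tau_p), ou_innovations(y, tt, tau_p))
    mu <- pr$mu; sigma2 <- pr$sigma2; loglik <- pr$loglik
  } else {
    obj <- function(par) {
      tau_p <- exp(par[1]); ratio <- stats::plogis(par[2])
      tau_v <- tau_p * ratio
      if (!is.finite(tau_p) || ratio > 0.99) return(1e12)
      pr <- try(profile_nll(ouf_innovations_cpp(x, tt, tau_p, tau_v),
                            ouf_innovations_cpp(y, tt, tau_p, tau_v)), silent = TRUE)
      if (inherits(pr, "try-error") || !is.finite(pr$nll2)) return(1e12)
      pr$nll2
    }
    # warm start from the OU fit
    ou <- fit_movement_model(track, "OU")
    best <- NULL
    for (start in list(c(log(ou$tau_pos), stats::qlogis(0.2)),
                       c(log(ou$tau_pos), stats::qlogis(0.6)))) {
      o <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
      if (is.null(best) || o$value < best$value) best <- o
    }
    converged <- best$convergence == 0 && best$value < 1e11
    tau_p <- exp(best$par[1]); tau_v <- tau_p * stats::plogis(best$par[2])
    pr <- profile_nll(ouf_innovations_cpp(x, tt, tau_p, tau_v),
                      ouf_innovations_cpp(y, tt, tau_p, tau_v))
    mu <- pr$mu; sigma2 <- pr$sigma2; loglik <- pr$loglik
  }
  k <- .MODEL_DF[[kind]]
  aicc <- 2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
  structure(list(kind = kind, mu = mu, sigma2 = sigma2, tau_pos = tau_p,
                 tau_vel = tau_v, loglik = loglik, k_params = k, aicc = aicc,
                 n = n, T_total = T_total, converged = converged),
            class = "movement_model")
}

#' @export
print.movement_model <- function(x, ...) {
  cat(sprintf("<movement_model %s> sigma2 = %.4g m^2", x$kind, x$sigma2))
  if (x$kind != "IID") cat(sprintf(", tau_pos = %.4g s", x$tau_pos))
  if (x$kind == "OUF") cat(sprintf(", tau_vel = %.4g s", x$tau_vel))
  cat(sprintf("\n  loglik = %.2f, AICc = %.2f (n = %d)\n", x$loglik, x$aicc, x$n))
  invisible(x)
}

#' Select the best-supported movement model by AICc
#'
#' Returns the converged candidate with the smallest AICc; ties (within
#' `tol`) are broken towards fewer parameters.
#'
#' @param candidates List of `movement_model` objects.
#' @param tol AICc tie tolerance.
#' @return The selected `movement_model`.
#' @export
select_model <- function(candidates, tol = 1e-8) {
  ok <- Filter(function(m) isTRUE(m$converged) && is.finite(m$aicc), candidates)
  if (!length(ok)) stop("no converged candidate models")
  aicc <- vapply(ok, `[[`, numeric(1), "aicc")
  k <- vapply(ok, `[[`, numeric(1), "k_params")
  best <- which(aicc <= min(aicc) + tol)
  ok[[best[which.min(k[best])]]]
}

#' Empirical semi-variance function of a track
#'
#' Computes the per-axis semivariance `E[(z(t+dt) - z(t))^2] / 2`, averaged
#' over the two coordinate axes, for all fix pairs binned into `n_lags`
#' equal-width time-lag bins.  A range-residency flag is derived from the
#' final quartile of lags: the variogram is considered flat (resident) when a
#' pair-count-weighted linear regression of semivariance on lag over those
#' bins has a slope not significantly different from zero (t-test, alpha
#' 0.05).
#'
#' @param track A `raptor_track` with at least 20 fixes.
#' @param n_lags Number of lag bins.
#' @param max_lag Largest lag considered, seconds; defaults to half the track
#'   span (longer lags have few, highly dependent pairs).
#' @return Object of class `variogram`: `lag_centres`, `semivariance`,
#'   `pairs_per_lag`, `resident`, `slope_p`.
#' @export
empirical_variogram <- function(track, n_lags = 20, max_lag = NULL) {
  stopifnot(inherits(track, "raptor_track"))
  f <- track$fixes
  n <- nrow(f)
  if (n < 20 && n != 2) stop("need >= 20 fixes, got ", n)
  tt <- as.numeric(f$timestamp)
  if (is.null(max_lag)) max_lag <- (tt[n] - tt[1]) / 2
  ii <- utils::combn(n, 2)
  dt <- tt[ii[2, ]] - tt[ii[1, ]]
  keep <- dt <= max_lag & dt > 0
  if (!any(keep)) { keep <- dt > 0; max_lag <- max(dt) }
  dt <- dt[keep]
  sv <- ((f$x[ii[2, ]] - f$x[ii[1, ]])^2 +
         (f$y[ii[2, ]] - f$y[ii[1, ]])^2)[keep] / 4
  brk <- seq(0, max_lag, length.out = n_lags + 1)
  bin <- pmin(n_lags, pmax(1, findInterval(dt, brk, rightmost.closed = TRUE)))
  cnt <- tabulate(bin, n_lags)
  sem <- rep(NA_real_, n_lags)
  agg <- tapply(sv, bin, mean)
  sem[as.integer(names(agg))] <- agg
  centres <- (brk[-1] + brk[-length(brk)]) / 2
  keep_bins <- cnt >= 1
  centres <- centres[keep_bins]; sem <- sem[keep_bins]; cnt <- cnt[keep_bins]
  # residency: flat final quartile?  Two criteria, either suffices: the
  # slope is statistically indistinguishable from zero, or the fitted change
  # across the quartile is below 10% of its mean semivariance (statistical
  # significance of an ecologically negligible trend is not expansion).
  q <- centres >= stats::quantile(centres, 0.75) - 1e-9
  resident <- NA; slope_p <- NA_real_
  if (sum(q) >= 3) {
    fit <- stats::lm(sem[q] ~ centres[q], weights = cnt[q])
    slope_p <- summary(fit)$coefficients[2, 4]
    rel_change <- abs(stats::coef(fit)[2]) * diff(range(centres[q])) /
      mean(sem[q])
    resident <- slope_p > 0.05 || rel_change < 0.1
  }
  structure(list(lag_centres = centres, semivariance = sem,
                 pairs_per_lag = cnt, resident = resident, slope_p = slope_p),
            class = "variogram")
}

#' @export
print.variogram <- function(x, ...) {
  cat(sprintf("<variogram> %d lag bins, asymptote ~%.4g m^2, resident: %s\n",
              length(x$lag_centres), mean(utils::tail(x$semivariance, 3)),
              format(x$resident)))
  invisible(x)
}
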