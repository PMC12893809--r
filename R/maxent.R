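# Presence/background maximum-entropy habitat-suitability modelling.
#
# Maxent is fitted directly as an L1-penalised Gibbs (exponential-family)
# density over the background: maximise
#     mean_presence(lambda . f) - log sum_background exp(lambda . f)
#       - sum_j beta_j |lambda_j|
# by cyclic coordinate-wise proximal Newton updates.  Per-feature penalties
# are beta_j = multiplier * s_j / sqrt(m) with s_j the feature standard
# deviation over the m presences - a single smoothness dial equivalent in
# role to the classical regularization multiplier.

#' Define a Maxent feature specification from training covariates
#'
#' Continuous covariates are min-max normalised to [0, 1] using the training
#' range; factors/characters become one-hot indicator columns that enter as
#' linear features.  Hinge features use `hinge_knots` interior knots per
#' covariate, forward `max(0, (x - k) / (1 - k))` and reverse
#' `max(0, (k - x) / k)`.
#'
#' @param data Training covariate data.frame (presences + background).
#' @param classes Subset of `c("linear", "quadratic", "product", "hinge")`.
#' @param hinge_knots Interior knots per continuous covariate.
#' @return Object of class `feature_spec` (stores classes, knots and the
#'   per-variable normalisation).
#' @export
make_feature_spec <- function(data, classes = c("linear", "quadratic", "product", "hinge"),
                              hinge_knots = 20) {
  classes <- match.arg(classes, several.ok = TRUE)
  stopifnot(!"hinge" %in% classes || hinge_knots >= 2)
  data <- as.data.frame(data)
  cont <- names(data)[vapply(data, is.numeric, logical(1))]
  cats <- setdiff(names(data), cont)
  norm <- lapply(data[cont], function(v) c(min = min(v), max = max(v)))
  dropped <- cont[vapply(norm, function(n) n["max"] <= n["min"], logical(1))]
  if (length(dropped))
    message("dropping zero-variance covariate(s): ",
            paste(dropped, collapse = ", "))
  cont <- setdiff(cont, dropped)
  levels <- lapply(data[cats], function(v) sort(unique(as.character(v))))
  structure(list(classes = classes, hinge_knots = hinge_knots,
                 continuous = cont, categorical = cats,
                 norm = norm[cont], levels = levels),
            class = "feature_spec")
}

#' Build the Maxent feature matrix
#'
#' @param data Covariate data.frame with the spec's variables.
#' @param spec A [make_feature_spec()] object (training normalisation).
#' @return Numeric matrix, one column per feature.
#' @export
build_features <- function(data, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  data <- as.data.frame(data)
  n <- nrow(data)
  Z <- list()
  U <- lapply(spec$continuous, function(v) {
    r <- spec$norm[[v]]
    pmin(1, pmax(0, (data[[v]] - r["min"]) / (r["max"] - r["min"])))
  })
  names(U) <- spec$continuous
  if ("linear" %in% spec$classes)
    for (v in spec$continuous) Z[[v]] <- U[[v]]
  if ("quadratic" %in% spec$classes)
    for (v in spec$continuous) Z[[paste0(v, "^2")]] <- U[[v]]^2
  if ("product" %in% spec$classes && length(spec$continuous) >= 2) {
    cmb <- utils::combn(spec$continuous, 2)
    for (k in seq_len(ncol(cmb)))
      Z[[paste0(cmb[1, k], "*", cmb[2, k])]] <- U[[cmb[1, k]]] * U[[cmb[2, k]]]
  }
  if ("hinge" %in% spec$classes) {
    knots <- seq(0, 1, length.out = spec$hinge_knots + 2)
    knots <- knots[-c(1, length(knots))]
    for (v in spec$continuous) for (k in knots) {
      Z[[sprintf("h+(%s,%.3f)", v, k)]] <- pmax(0, (U[[v]] - k) / (1 - k))
      Z[[sprintf("h-(%s,%.3f)", v, k)]] <- pmax(0, (k - U[[v]]) / k)
    }
  }
  for (v in spec$categorical) {
    vals <- as.character(data[[v]])
    unseen <- setdiff(unique(vals), spec$levels[[v]])
    if (length(unseen))
      stop("unseen category code(s) in '", v, "': ",
           paste(unseen, collapse = ", "))
    for (lv in spec$levels[[v]])
      Z[[paste0(v, "=", lv)]] <- as.numeric(vals == lv)
  }
  out <- do.call(cbind, Z)
  rownames(out) <- NULL
  out
}

soft_threshold <- function(z, t) sign(z) * pmax(0, abs(z) - t)

# penalised Gibbs objective (to be maximised)
.maxent_objective <- function(lambda, Fp, Fb, beta) {
  s <- Fb %*% lambda
  mx <- max(s)
  mean(Fp %*% lambda) - (mx + log(sum(exp(s - mx)))) - sum(beta * abs(lambda))
}

#' Fit a Maxent model by coordinate-wise proximal updates
#'
#' @param features_presence,features_background Feature matrices from
#'   [build_features()] (same columns).
#' @param beta_multiplier Regularisation multiplier (the analysis grid is
#'   1-5); scales every per-feature L1 penalty.
#' @param max_iter Maximum number of full coordinate sweeps.
#' @param tol Convergence tolerance on the objective change per sweep.
#' @param spec Optional `feature_spec` to store for prediction on raw
#'   covariates.
#' @return Object of class `maxent_model`: `lambda`, `beta`, `log_Z`
#'   (log normaliser, sum convention over the training background),
#'   `entropy`, `objective`, `iterations`, `converged`.
#' @export
fit_maxent <- function(features_presence, features_background,
                       beta_multiplier = 1, max_iter = 2500, tol = 1e-5,
                       spec = NULL) {
  Fp <- as.matrix(features_presence); Fb <- as.matrix(features_background)
  stopifnot(ncol(Fp) == ncol(Fb), nrow(Fp) >= 5)
  m <- nrow(Fp); nb <- nrow(Fb); p <- ncol(Fp)
  sj <- apply(Fp, 2, stats::sd)
  beta <- beta_multiplier * pmax(sj, 1e-3) / sqrt(m)
  pbar <- colMeans(Fp)
  lambda <- numeric(p)
  eta <- rep(0, nb)
  obj_old <- .maxent_objective(lambda, Fp, Fb, beta)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    for (j in seq_len(p)) {
      w <- exp(eta - max(eta)); w <- w / sum(w)
      ebar <- sum(w * Fb[, j])
      gj <- pbar[j] - ebar
      hj <- max(sum(w * Fb[, j]^2) - ebar^2, 1e-10)
      new_l <- soft_threshold(lambda[j] + gj / hj, beta[j] / hj)
      d <- new_l - lambda[j]
      if (d == 0) next
      d <- max(min(d, 1), -1) # damp large steps
      lambda[j] <- lambda[j] + d
      eta <- eta + d * Fb[, j]
    }
    obj <- .maxent_objective(lambda, Fp, Fb, beta)
    if (is.na(obj)) stop("maxent objective diverged (NaN) at sweep ", it)
    if (abs(obj - obj_old) < tol) { converged <- TRUE; obj_old <- obj; break }
    obj_old <- obj
  }
  s <- as.vector(Fb %*% lambda)
  mx <- max(s)
  log_Z <- mx + log(sum(exp(s - mx)))
  raw_b <- exp(s - log_Z)
  entropy <- -sum(raw_b * log(pmax(raw_b, 1e-300)))
  structure(list(lambda = stats::setNames(lambda, colnames(Fp)), beta = beta,
                 beta_multiplier = beta_multiplier, log_Z = log_Z,
                 entropy = entropy, objective = obj_old, iterations = it,
                 converged = converged, spec = spec),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features (%d active), multiplier %g, obj %.5f (%d sweeps%s)\n",
              length(x$lambda), sum(x$lambda != 0), x$beta_multiplier,
              x$objective, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Predict Maxent suitability
#'
#' @param object A `maxent_model`.
#' @param newdata Covariate data.frame (requires the model to carry its
#'   `feature_spec`) or a prebuilt feature matrix.
#' @param type `"raw"` (sums to 1 over the training background) or
#'   `"logistic"` (the conventional 0-1 output with tau = 0.5).
#' @param ... Unused.
#' @return Numeric vector of suitabilities.
#' @export
predict.maxent_model <- function(object, newdata, type = c("raw", "logistic"), ...) {
  type <- match.arg(type)
  Fm <- if (is.matrix(newdata)) newdata else {
    if (is.null(object$spec)) stop("model carries no feature_spec; pass features")
    build_features(newdata, object$spec)
  }
  raw <- exp(as.vector(Fm %*% object$lambda) - object$log_Z)
  if (type == "raw") return(raw)
  re <- raw * exp(object$entropy)
  re / (1 + re)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' @param pred_presence,pred_background Predicted scores.
#' @return AUC in [0, 1]; ties receive half credit.
#' @export
auc_mw <- function(pred_presence, pred_background) {
  np <- length(pred_presence); nb <- length(pred_background)
  r <- rank(c(pred_presence, pred_background), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Threshold maximising sensitivity plus specificity (max SSS)
#'
#' Scans every unique predicted value as a candidate cut-off (presences
#' scoring at or above the threshold count as predicted suitable) and returns
#' the lowest value attaining the maximum of sensitivity + specificity.
#'
#' @param pred_presence,pred_background Predicted scores.
#' @return List: `threshold`, `sensitivity`, `specificity`, `tss`.
#' @export
max_sss_threshold <- function(pred_presence, pred_background) {
  stopifnot(length(pred_presence) > 0, length(pred_background) > 0)
  cand <- sort(unique(c(pred_presence, pred_background)))
  best <- NULL
  for (t in cand) {
    se <- mean(pred_presence >= t)
    sp <- mean(pred_background < t)
    if (is.null(best) || se + sp > best$sum + 1e-12)
      best <- list(threshold = t, sensitivity = se, specificity = sp,
                   sum = se + sp)
  }
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity, tss = best$sum - 1)
}

#' Sample background points within a region, excluding water
#'
#' Uniform rejection sampling over the region polygon minus the water
#' polygons, reproducible under `seed`; returns `ratio * n_presence` points
#' (the analysis convention is 10 background points per breeding site).
#'
#' @param region Polygon ring, metres.
#' @param water List of water polygon rings (may be empty).
#' @param n_presence Number of presence sites.
#' @param ratio Background-to-presence ratio.
#' @param seed Integer seed.
#' @return Matrix with columns `x`, `y`.
#' @export
sample_background <- function(region, water = list(), n_presence, ratio = 10,
                              seed = 1) {
  region <- as.matrix(region)
  n_target <- ratio * n_presence
  bb <- apply(region[, 1:2], 2, range)
  set.seed(seed)
  out <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(out) < n_target) {
    m <- max(2 * (n_target - nrow(out)), 100)
    px <- stats::runif(m, bb[1, 1], bb[2, 1])
    py <- stats::runif(m, bb[1, 2], bb[2, 2])
    ok <- point_in_polygon(px, py, region) & !point_in_any(px, py, water)
    out <- rbind(out, cbind(px[ok], py[ok]))
    tries <- tries + 1
    if (tries > 1000) stop("region minus water appears empty")
  }
  out <- out[seq_len(n_target), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Cross-validated Maxent model selection
#'
#' Evaluates every (feature combination, regularisation multiplier) pair by
#' k-fold cross-validation with folds stratified over presences and
#' background (the same folds reused across configurations), then refits the
#' winner - highest mean test AUC, ties by higher mean TSS, then by larger
#' multiplier - on all data.  The reported binarisation threshold is the
#' arithmetic mean of the per-fold max-SSS thresholds of the winning
#' configuration.
#'
#' @param presence,background Covariate data.frames.
#' @param feature_sets List of character vectors of feature classes; default
#'   the three analysis sets LQPH, hinge+product, hinge.
#' @param multipliers Numeric vector of regularisation multipliers.
#' @param k Number of folds (each holds out ~1/k of both classes).
#' @param seed Fold-assignment seed.
#' @param hinge_knots,max_iter,tol Passed through to the fitter.
#' @return List of class `maxent_cv`: `best_model`, `best_config`,
#'   `threshold`, `grid` (per-config mean AUC/TSS), `folds`.
#' @export
cross_validate_maxent <- function(presence, background,
                                  feature_sets = list(
                                    c("linear", "quadratic", "product", "hinge"),
                                    c("hinge", "product"),
                                    "hinge"),
                                  multipliers = 1:5, k = 10, seed = 1,
                                  hinge_knots = 20, max_iter = 2500, tol = 1e-5) {
  presence <- as.data.frame(presence); background <- as.data.frame(background)
  np <- nrow(presence); nb <- nrow(background)
  stopifnot(np >= k)
  set.seed(seed)
  fold_p <- sample(rep_len(seq_len(k), np))
  fold_b <- sample(rep_len(seq_len(k), nb))
  grid <- list()
  for (fs in feature_sets) for (mult in multipliers) {
    aucs <- tss <- thr <- numeric(k)
    for (fold in seq_len(k)) {
      trp <- presence[fold_p != fold, , drop = FALSE]
      trb <- background[fold_b != fold, , drop = FALSE]
      tep <- presence[fold_p == fold, , drop = FALSE]
      teb <- background[fold_b == fold, , drop = FALSE]
      spec <- make_feature_spec(rbind(trp, trb), classes = fs,
                                hinge_knots = hinge_knots)
      fit <- fit_maxent(build_features(trp, spec), build_features(trb, spec),
                        beta_multiplier = mult, max_iter = max_iter,
                        tol = tol, spec = spec)
      pp <- predict(fit, tep); pb <- predict(fit, teb)
      aucs[fold] <- auc_mw(pp, pb)
      ms <- max_sss_threshold(pp, pb)
      tss[fold] <- ms$tss; thr[fold] <- ms$threshold
    }
    grid[[length(grid) + 1]] <- data.table::data.table(
      features = paste(fs, collapse = "+"), multiplier = mult,
      mean_auc = mean(aucs), mean_tss = mean(tss), mean_threshold = mean(thr))
  }
  grid <- data.table::rbindlist(grid)
  ord <- order(-grid$mean_auc, -grid$mean_tss, -grid$multiplier)
  best <- grid[ord[1], ]
  fs_best <- strsplit(best$features, "+", fixed = TRUE)[[1]]
  spec <- make_feature_spec(rbind(presence, background), classes = fs_best,
                            hinge_knots = hinge_knots)
  final <- fit_maxent(build_features(presence, spec),
                      build_features(background, spec),
                      beta_multiplier = best$multiplier, max_iter = max_iter,
                      tol = tol, spec = spec)
  structure(list(best_model = final,
                 best_config = list(features = fs_best,
                                    multiplier = best$multiplier),
                 threshold = best$mean_threshold, grid = grid,
                 folds = list(presence = fold_p, background = fold_b)),
            class = "maxent_cv")
}

# 5-fold CV AUC of a single-covariate linear+quadratic model; used as the
# default performance score in the collinearity screen.
univariate_cv_auc <- function(x, is_presence, seed = 1, k = 5) {
  df <- data.frame(v = x)
  p <- df[is_presence, , drop = FALSE]; b <- df[!is_presence, , drop = FALSE]
  if (nrow(p) < k) k <- max(2, nrow(p))
  cv <- cross_validate_maxent(p, b, feature_sets = list(c("linear", "quadratic")),
                              multipliers = 1, k = k, seed = seed,
                              hinge_knots = 2, max_iter = 200, tol = 1e-4)
  cv$grid$mean_auc[1]
}

#' Binarise a suitability raster and account suitable area
#'
#' Cells at or above `threshold` are suitable; cells inside the exclusion
#' mask polygons (peripheral forest / pasture, where the model is not
#' transferable) are forced unsuitable.  Areas are totalled overall and per
#' habitat class, and the suitable area lying outside 1000-m circular
#' territory buffers around occupied nests is reported as unoccupied
#' suitable habitat.
#'
#' @param suitability Continuous `uraster`.
#' @param threshold Binarisation threshold (from [max_sss_threshold()]).
#' @param habitat Optional categorical `uraster` on the same grid.
#' @param mask Optional list of exclusion polygons, metres.
#' @param occupied_nests Optional matrix/data.frame with `x`, `y` of occupied
#'   nests.
#' @param buffer_radius Territory buffer radius, metres.
#' @return List of class `area_report`: `binary` (`uraster`),
#'   `total_suitable_km2`, `by_habitat_class_km2`, `unoccupied_suitable_km2`,
#'   `occupied_buffer_radius`.
#' @export
binarize_and_account <- function(suitability, threshold, habitat = NULL,
                                 mask = NULL, occupied_nests = NULL,
                                 buffer_radius = 1000) {
  stopifnot(inherits(suitability, "uraster"))
  if (!is.null(habitat)) {
    if (!identical(dim(habitat$values), dim(suitability$values)) ||
        habitat$cell != suitability$cell ||
        any(habitat$origin != suitability$origin))
      stop("habitat raster grid mismatch")
  }
  v <- suitability$values
  suit <- !is.na(v) & v >= threshold
  cc <- cell_centres(suitability)
  gx <- matrix(cc$x, suitability$n_rows, suitability$n_cols, byrow = TRUE)
  gy <- matrix(cc$y, suitability$n_rows, suitability$n_cols)
  if (!is.null(mask) && length(mask))
    suit[matrix(point_in_any(as.vector(gx), as.vector(gy), mask),
                suitability$n_rows)] <- FALSE
  cell_km2 <- (suitability$cell / 1000)^2
  total <- sum(suit) * cell_km2
  by_class <- NULL
  if (!is.null(habitat)) {
    cls <- habitat$values[suit]
    tab <- table(cls, useNA = "no")
    by_class <- stats::setNames(as.numeric(tab) * cell_km2, names(tab))
  }
  unocc <- suit
  if (!is.null(occupied_nests) && NROW(occupied_nests)) {
    nst <- as.matrix(occupied_nests)[, 1:2, drop = FALSE]
    occ <- matrix(FALSE, suitability$n_rows, suitability$n_cols)
    for (i in seq_len(nrow(nst)))
      occ <- occ | ((gx - nst[i, 1])^2 + (gy - nst[i, 2])^2 <= buffer_radius^2)
    unocc <- suit & !occ
  }
  binary <- new_raster(suit + 0, suitability$origin, suitability$cell,
                       kind = "categorical")
  structure(list(binary = binary, total_suitable_km2 = total,
                 by_habitat_class_km2 = by_class,
                 unoccupied_suitable_km2 = sum(unocc) * cell_km2,
                 occupied_buffer_radius = buffer_radius),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf("<area_report> suitable %.3f km^2, unoccupied %.3f km^2 (buffer %g m)\n",
              x$total_suitable_km2, x$unoccupied_suitable_km2,
              x$occupied_buffer_radius))
  invisible(x)
}
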