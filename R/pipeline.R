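# End-to-end orchestration: run the analysis stages from a single flat
# configuration with one global seed, uniform logging and a hashed artifact
# manifest.  Per-stage seeds are derived deterministically from the global
# seed and the stage name, so every stochastic stage is a pure function of
# (inputs, parameters, seed).

.PIPELINE_DEFAULTS <- list(
  seed = 1, out_dir = "urbanraptor_out",
  fixes_csv = NA, nests_csv = NA, region_geojson = NA,
  # tracking / dispersal
  hdop_max = 4, min_sats = 5, min_elevation = -12, min_tracking_days = 30,
  territory_radius_m = 1000, return_window_days = 7, max_age_days = 730,
  # ranges
  cfr_level = 0.5,
  # tfa
  tfa_eps_m = 150, tfa_min_pts = 10, tfa_min_fixes = 30, tfa_min_days = 10,
  # glmm
  n_boot = 1000,
  # synthetic stage
  sim_n_individuals = 5, sim_n_days = 200, sim_onset_day = 40,
  sim_extent_m = 6000, sim_cell_m = 50, sim_n_presence = 60,
  # sdm
  background_ratio = 10, cv_folds = 10, hinge_knots = 20, max_iter = 2500)

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Unknown keys are
#' rejected.  Values are parsed as numbers where possible.
#'
#' @param path File path.
#' @return Named list merged over the documented defaults.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", l)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  merge_config(cfg)
}

merge_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(.PIPELINE_DEFAULTS, cfg)
}

stage_seed <- function(global_seed, stage) {
  # stable small-integer hash of the stage name, mixed with the global seed
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

.log <- function(...) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (`simulate` < `qc` <
#' `dispersal` < `ranges` < `tfa` < `glmm`; `simulate` < `predictors` <
#' `sdm`), writing plain-text artifacts (CSV, GeoJSON, ASCII grids, JSON)
#' under `config$out_dir` and returning a manifest of files with MD5 hashes.
#' When no input paths are configured, the `simulate` stage supplies
#' synthetic tracks and a synthetic landscape.
#'
#' @param config Named list (see `read_config()`) or a config file path.
#' @param stages Character vector of stages to run.
#' @return data.frame manifest: `file`, `md5`, `stage`.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "qc", "dispersal", "ranges",
                                    "tfa", "glmm", "predictors", "sdm")) {
  cfg <- if (is.character(config)) read_config(config) else merge_config(config)
  order_all <- c("simulate", "qc", "dispersal", "ranges", "tfa", "glmm",
                 "predictors", "sdm")
  stages <- order_all[order_all %in% stages]
  deps <- list(qc = "simulate", dispersal = "qc", ranges = "dispersal",
               tfa = "ranges", glmm = "tfa", predictors = "simulate",
               sdm = "predictors")
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, ...) {
    for (f in c(...))
      manifest[[length(manifest) + 1]] <<- data.frame(
        file = f, md5 = unname(tools::md5sum(f)), stage = stage)
  }
  artifact <- function(name) file.path(out, name)
  need <- function(stage, file) {
    if (!file.exists(file))
      stop(sprintf("stage '%s' requires missing artifact %s (run stage '%s')",
                   stage, file, deps[[stage]]))
  }

  if ("simulate" %in% stages) {
    .log("stage simulate")
    sseed <- stage_seed(cfg$seed, "simulate")
    tracks <- lapply(seq_len(cfg$sim_n_individuals), function(i)
      simulate_track(track_scenario(n_days = cfg$sim_n_days,
                                    onset_day = cfg$sim_onset_day,
                                    seed = sseed + i)))
    write_fixes(tracks, artifact("fixes.csv"))
    nests <- data.table::data.table(
      individual_id = vapply(tracks, `[[`, "", "individual_id"),
      nest_lon = 13.4, nest_lat = 52.5,
      hatch_date = as.Date("2023-04-20"))
    data.table::fwrite(nests, artifact("nests.csv"))
    ls <- simulate_landscape(landscape_scenario(
      extent = cfg$sim_extent_m, cell = cfg$sim_cell_m, seed = sseed))
    for (nm in names(ls$layers)) write_asc(ls$layers[[nm]], artifact(paste0(nm, ".asc")))
    write_asc(ls$habitat, artifact("habitat.asc"))
    sites <- simulate_breeding_sites(ls, c(tree_cover = 0.05, "habitat=4" = 1.5),
                                     cfg$sim_n_presence, seed = sseed)
    data.table::fwrite(data.table::as.data.table(sites$points), artifact("nest_sites.csv"))
    jsonlite::write_json(list(seed = sseed, onset_day = cfg$sim_onset_day),
                         artifact("truth.json"), auto_unbox = TRUE)
    note("simulate", artifact("fixes.csv"), artifact("nests.csv"),
         artifact("habitat.asc"), artifact("nest_sites.csv"),
         artifact("truth.json"),
         vapply(names(ls$layers), function(nm) artifact(paste0(nm, ".asc")), ""))
  }

  if ("qc" %in% stages) {
    .log("stage qc")
    fx <- if (!is.na(cfg$fixes_csv)) cfg$fixes_csv else artifact("fixes.csv")
    need("qc", fx)
    nst <- if (!is.na(cfg$nests_csv)) cfg$nests_csv else artifact("nests.csv")
    tracks <- read_fixes(fx, nests = if (file.exists(nst)) read_nests(nst))
    tracks <- lapply(tracks, qc_filter, hdop_max = cfg$hdop_max,
                     min_sats = cfg$min_sats)
    tracks <- lapply(tracks, daylight_filter, min_elevation = cfg$min_elevation)
    write_fixes(tracks, artifact("fixes_qc.csv"))
    note("qc", artifact("fixes_qc.csv"))
  }

  if ("dispersal" %in% stages) {
    .log("stage dispersal")
    need("dispersal", artifact("fixes_qc.csv"))
    tracks <- read_fixes(artifact("fixes_qc.csv"),
                         nests = read_nests(artifact("nests.csv")))
    rows <- list(); kept <- list()
    for (tr in tracks) {
      res <- detect_onset(tr, radius = cfg$territory_radius_m,
                          return_window = cfg$return_window_days)
      nfk <- 0L
      if (!is.na(res$onset_date)) {
        tr2 <- dispersal_window(tr, res, max_age = cfg$max_age_days)
        nfk <- n_fixes(tr2)
        kept[[tr$individual_id]] <- tr2
      }
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = tr$individual_id,
        onset_date = as.character(res$onset_date), n_fixes_retained = nfk)
    }
    utils::write.csv(do.call(rbind, rows), artifact("dispersal.csv"),
                     row.names = FALSE)
    write_fixes(kept, artifact("fixes_dispersal.csv"))
    note("dispersal", artifact("dispersal.csv"), artifact("fixes_dispersal.csv"))
  }

  if ("ranges" %in% stages) {
    .log("stage ranges")
    need("ranges", artifact("fixes_dispersal.csv"))
    tracks <- read_fixes(artifact("fixes_dispersal.csv"))
    rows <- list(); polys <- list(); props <- list()
    for (tr in tracks) {
      if (n_fixes(tr) < 20) next
      cand <- list(fit_movement_model(tr, "IID"), fit_movement_model(tr, "OU"))
      best <- select_model(cand)
      for (m in cand)
        rows[[length(rows) + 1]] <- data.frame(
          individual_id = tr$individual_id, kind = m$kind, sigma2 = m$sigma2,
          tau_pos = m$tau_pos, tau_vel = m$tau_vel, loglik = m$loglik,
          aicc = m$aicc, selected = identical(m$kind, best$kind))
      est <- akde(tr, best)
      ct <- range_contour(est, level = cfg$cfr_level)
      for (pg in ct$polygons) {
        polys[[length(polys) + 1]] <- pg
        props[[length(props) + 1]] <- data.frame(
          individual_id = tr$individual_id, area_km2 = ct$area_km2,
          ci_low = ct$ci_low / 1e6, ci_high = ct$ci_high / 1e6,
          model_kind = best$kind, n_area = est$n_area)
      }
    }
    utils::write.csv(do.call(rbind, rows), artifact("models.csv"),
                     row.names = FALSE)
    write_geojson_polygons(polys, artifact("cfr.geojson"),
                           proj = tracks[[1]]$proj,
                           properties = do.call(rbind, props))
    note("ranges", artifact("models.csv"), artifact("cfr.geojson"))
  }

  if ("tfa" %in% stages) {
    .log("stage tfa")
    need("tfa", artifact("cfr.geojson"))
    tracks <- read_fixes(artifact("fixes_dispersal.csv"))
    proj <- tracks[[1]]$proj
    gj <- jsonlite::read_json(artifact("cfr.geojson"))
    pop <- if (file.exists(artifact("pop_density.asc")))
      read_asc(artifact("pop_density.asc"))
    tabs <- list()
    for (tr in tracks) {
      rings <- list()
      for (ft in gj$features)
        if (ft$properties$individual_id == tr$individual_id) {
          m <- do.call(rbind, lapply(ft$geometry$coordinates[[1]],
                                     function(p) c(p[[1]], p[[2]])))
          rings[[length(rings) + 1]] <- project_xy(m[, 1], m[, 2], proj)
        }
      if (!length(rings)) next
      inside <- point_in_any(tr$fixes$x, tr$fixes$y, rings)
      sub <- replace_fixes(tr, tr$fixes[inside])
      if (n_fixes(sub) < cfg$tfa_min_pts) next
      tabs[[length(tabs) + 1]] <- extract_tfas(
        sub, eps = cfg$tfa_eps_m, min_pts = cfg$tfa_min_pts,
        pop_density = pop)
    }
    tfa <- data.table::rbindlist(tabs)
    data.table::fwrite(tfa, artifact("tfa.csv"))
    note("tfa", artifact("tfa.csv"))
  }

  if ("glmm" %in% stages) {
    .log("stage glmm")
    need("glmm", artifact("tfa.csv"))
    tfa <- data.table::fread(artifact("tfa.csv"))
    report <- list()
    if (nrow(tfa) >= 4 && length(unique(tfa$individual_id)) >= 2 &&
        all(is.finite(tfa$mean_pop_density))) {
      gseed <- stage_seed(cfg$seed, "glmm")
      for (spec in list(list(resp = "timespan_days", fam = "poisson"),
                        list(resp = "area_ha", fam = "gaussian"))) {
        alt <- fit_glmm(tfa, family = spec$fam, response = spec$resp,
                        predictor = "mean_pop_density")
        null <- fit_glmm(tfa, family = spec$fam, response = spec$resp,
                         predictor = "mean_pop_density", slope = FALSE)
        lrt <- bootstrap_lrt(null, alt, n_boot = cfg$n_boot, seed = gseed)
        report[[spec$fam]] <- list(
          family = spec$fam, beta = alt$beta, sigma2_u = alt$sigma2_u,
          lrt_statistic = lrt$statistic, df = lrt$df, p_boot = lrt$p_boot,
          n_boot = lrt$n_boot, seed = gseed)
      }
    } else {
      report$note <- "too few TFAs for GLMM fitting"
    }
    jsonlite::write_json(report, artifact("glmm.json"), auto_unbox = TRUE,
                         digits = 10)
    note("glmm", artifact("glmm.json"))
  }

  if ("predictors" %in% stages) {
    .log("stage predictors")
    need("predictors", artifact("tree_cover.asc"))
    layers <- c("tree_cover", "imperviousness", "pop_density", "human_footprint")
    sites <- data.table::fread(artifact("nest_sites.csv"))
    pseed <- stage_seed(cfg$seed, "predictors")
    h <- cfg$sim_extent_m / 2
    region <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
    bg <- sample_background(region, list(), nrow(sites),
                            ratio = cfg$background_ratio, seed = pseed)
    pts <- rbind(as.matrix(sites[, .(x, y)]), bg)
    tab <- data.table::data.table(site_id = seq_len(nrow(pts)),
                                  is_presence = rep(c(1, 0), c(nrow(sites), nrow(bg))))
    scales <- c(tree_cover = 50, pop_density = 50,
                imperviousness = 1000, human_footprint = 1000)
    for (nm in layers) {
      r <- resample_raster(read_asc(artifact(paste0(nm, ".asc"))), 50)
      tab[[nm]] <- vapply(seq_len(nrow(pts)), function(i)
        focal_mean(r, pts[i, ], scales[[nm]]), numeric(1))
    }
    hab <- read_asc(artifact("habitat.asc"), kind = "categorical")
    tab$habitat_type <- as.character(raster_value_at(hab, pts[, 1], pts[, 2]))
    keep <- collinearity_filter(tab[, ..layers], threshold = 0.7,
                                is_presence = tab$is_presence == 1,
                                seed = pseed)
    data.table::fwrite(tab, artifact("predictors.csv"))
    writeLines(keep, artifact("predictors_retained.txt"))
    note("predictors", artifact("predictors.csv"),
         artifact("predictors_retained.txt"))
  }

  if ("sdm" %in% stages) {
    .log("stage sdm")
    need("sdm", artifact("predictors.csv"))
    tab <- data.table::fread(artifact("predictors.csv"),
                             colClasses = list(character = "habitat_type"))
    keep <- readLines(artifact("predictors_retained.txt"))
    vars <- c(keep, "habitat_type")
    pres <- as.data.frame(tab[is_presence == 1, ..vars])
    bg <- as.data.frame(tab[is_presence == 0, ..vars])
    mseed <- stage_seed(cfg$seed, "sdm")
    cv <- cross_validate_maxent(pres, bg, k = min(cfg$cv_folds, nrow(pres)),
                                seed = mseed, hinge_knots = cfg$hinge_knots,
                                max_iter = cfg$max_iter)
    data.table::fwrite(cv$grid, artifact("model_grid.csv"))
    # continuous prediction over the landscape grid
    hab <- read_asc(artifact("habitat.asc"), kind = "categorical")
    cc <- cell_centres(hab)
    gx <- rep(cc$x, each = hab$n_rows); gy <- rep(cc$y, hab$n_cols)
    newd <- data.frame(row.names = seq_along(gx))
    for (nm in keep) {
      r <- resample_raster(read_asc(artifact(paste0(nm, ".asc"))), 50)
      newd[[nm]] <- raster_value_at(r, gx, gy)
    }
    newd$habitat_type <- as.character(raster_value_at(hab, gx, gy))
    pr <- predict(cv$best_model, newd)
    suit <- new_raster(matrix(pr, hab$n_rows), hab$origin, hab$cell)
    write_asc(suit, artifact("suitability.asc"))
    sites <- data.table::fread(artifact("nest_sites.csv"))
    rep_area <- binarize_and_account(suit, cv$threshold, habitat = hab,
                                     occupied_nests = as.matrix(sites))
    write_asc(rep_area$binary, artifact("suitability_binary.asc"))
    jsonlite::write_json(list(
      total_suitable_km2 = rep_area$total_suitable_km2,
      by_habitat_class_km2 = as.list(rep_area$by_habitat_class_km2),
      unoccupied_suitable_km2 = rep_area$unoccupied_suitable_km2,
      best_features = cv$best_config$features,
      best_multiplier = cv$best_config$multiplier,
      threshold = cv$threshold),
      artifact("area_report.json"), auto_unbox = TRUE, digits = 10)
    note("sdm", artifact("model_grid.csv"), artifact("suitability.asc"),
         artifact("suitability_binary.asc"), artifact("area_report.json"))
  }

  do.call(rbind, manifest)
}
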