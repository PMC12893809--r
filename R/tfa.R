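# Temporal foraging areas: density-based clusters of fixes inside the core
# range, delineated as 95% minimum convex polygons and qualified by minimum
# fix-count and duration rules.

#' Density-based clustering of fixes (DBSCAN)
#'
#' Standard DBSCAN on the projected coordinates: core points have at least
#' `min_pts` neighbours (self included) within `eps` metres; clusters are the
#' connected components of core points plus their border points; remaining
#' fixes are noise (cluster id 0).  When a categorical habitat raster or a
#' habitat polygon list is supplied, each density cluster is additionally
#' split by habitat membership, mirroring the per-habitat delineation of
#' foraging areas.
#'
#' @param fixes data.frame/data.table with columns `x`, `y` (and optionally
#'   `timestamp`); typically the subset of a track inside its 50% core range.
#' @param eps Neighbourhood radius, metres.
#' @param min_pts Core-point threshold.
#' @param habitat Optional `uraster` (categorical) or named list of polygons.
#' @return Integer vector of cluster labels (0 = noise), one per fix, plus a
#'   `habitat` attribute with per-fix habitat labels when habitat was given.
#' @export
cluster_fixes <- function(fixes, eps = 150, min_pts = 10, habitat = NULL) {
  fixes <- data.table::as.data.table(fixes)
  n <- nrow(fixes)
  if (n == 0) return(integer(0))
  # neighbour lists (block-wise to bound memory)
  nb <- vector("list", n)
  block <- 2000L
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(fixes$x[s:e], fixes$x, `-`)^2 + outer(fixes$y[s:e], fixes$y, `-`)^2
    for (i in s:e) nb[[i]] <- which(d2[i - s + 1L, ] <= eps^2)
  }
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (!core[j]) next
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  if (!is.null(habitat)) {
    hab <- if (inherits(habitat, "uraster")) {
      as.character(raster_value_at(habitat, fixes$x, fixes$y))
    } else {
      h <- rep(NA_character_, n)
      for (nm in names(habitat)) {
        inp <- point_in_polygon(fixes$x, fixes$y, habitat[[nm]])
        h[inp & is.na(h)] <- nm
      }
      h
    }
    old <- labels
    labels <- integer(n)
    cl <- 0L
    for (c0 in sort(unique(old[old > 0]))) {
      for (hl in unique(hab[old == c0])) {
        cl <- cl + 1L
        sel <- old == c0 & (hab == hl | (is.na(hab) & is.na(hl)))
        sel[is.na(sel)] <- FALSE
        labels[sel] <- cl
      }
    }
    attr(labels, "habitat") <- hab
  }
  labels
}

#' 95% minimum convex polygon
#'
#' Removes the `ceiling(0.05 * n)` points farthest (Euclidean) from the
#' arithmetic centroid - distance ties resolved by removing the earlier
#' timestamp first, then by row order - and returns the convex hull of the
#' remainder with its shoelace area.
#'
#' @param points Two-column matrix / data.frame of `x`, `y` (>= 5 points).
#' @param timestamps Optional vector for tie-breaking.
#' @return List: `polygon` (CCW hull ring), `area` (m^2), `area_ha`, `kept`
#'   (logical vector over input points).
#' @export
mcp95 <- function(points, timestamps = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 5) stop("need >= 5 points")
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  n_drop <- ceiling(0.05 * n)
  tie <- if (is.null(timestamps)) seq_len(n) else order(order(timestamps))
  ord <- order(-d, tie) # farthest first; ties: earliest timestamp removed first
  kept <- rep(TRUE, n)
  kept[ord[seq_len(n_drop)]] <- FALSE
  hp <- pts[kept, , drop = FALSE]
  hull <- convex_hull(hp)
  if (nrow(hull) < 3 || polygon_area(hull) == 0)
    stop("degenerate polygon: remaining points are collinear")
  area <- polygon_area(hull)
  list(polygon = hull, area = area, area_ha = area / 1e4, kept = kept)
}

#' Qualify a candidate foraging cluster
#'
#' A cluster qualifies as a temporal foraging area when it has at least
#' `min_fixes` GPS positions spanning at least `min_days` calendar days
#' (first to last date, inclusive).
#'
#' @param timestamps POSIXct fixes of the candidate cluster.
#' @param min_fixes,min_days Qualification thresholds.
#' @return List: `accept` (logical), `reasons` (character, empty on accept),
#'   `n_fixes`, `period_days`.
#' @export
qualify_tfa <- function(timestamps, min_fixes = 30, min_days = 10) {
  stopifnot(length(timestamps) >= 1)
  nf <- length(timestamps)
  dates <- as.Date(timestamps, tz = "UTC")
  period <- as.numeric(max(dates) - min(dates)) + 1
  reasons <- character(0)
  if (nf < min_fixes)
    reasons <- c(reasons, sprintf("only %d fixes (< %d)", nf, min_fixes))
  if (period < min_days)
    reasons <- c(reasons, sprintf("period %d day(s) (< %d)", period, min_days))
  list(accept = length(reasons) == 0, reasons = reasons,
       n_fixes = nf, period_days = period)
}

#' Occupancy time span of a foraging cluster
#'
#' The central 95% interquantile range of the fix timestamps (0.975 minus
#' 0.025 quantile, linearly interpolated), expressed in days - an
#' outlier-robust measure of how long the area stayed in use.
#'
#' @param timestamps POSIXct vector (>= 2 fixes).
#' @param convention `"central"` (default) for the central 95% range, or
#'   `"upper"` for the 0.95 quantile of time since the first fix.
#' @return Time span in days.
#' @export
occupancy_timespan <- function(timestamps, convention = c("central", "upper")) {
  convention <- match.arg(convention)
  stopifnot(length(timestamps) >= 2)
  tt <- sort(as.numeric(timestamps))
  span <- if (convention == "central") {
    q <- stats::quantile(tt, c(0.025, 0.975), names = FALSE, type = 7)
    q[2] - q[1]
  } else {
    stats::quantile(tt - tt[1], 0.95, names = FALSE, type = 7)
  }
  span / 86400
}

#' Mean of a continuous raster over a polygon
#'
#' Averages cells whose centres fall inside the polygon (boundary inclusive);
#' nodata cells are excluded.
#'
#' @param polygon Two-column ring matrix, metres.
#' @param raster A continuous `uraster`.
#' @return Mean cell value.
#' @export
mean_covariate <- function(polygon, raster) {
  stopifnot(inherits(raster, "uraster"))
  cc <- cell_centres(raster)
  bb <- apply(as.matrix(polygon), 2, range)
  cols <- which(cc$x >= bb[1, 1] - raster$cell & cc$x <= bb[2, 1] + raster$cell)
  rows <- which(cc$y >= bb[1, 2] - raster$cell & cc$y <= bb[2, 2] + raster$cell)
  if (!length(cols) || !length(rows)) stop("polygon overlaps no raster cells")
  gx <- rep(cc$x[cols], each = length(rows))
  gy <- rep(cc$y[rows], times = length(cols))
  inside <- point_in_polygon(gx, gy, polygon)
  vals <- raster$values[rows, cols, drop = FALSE][matrix(inside, length(rows))]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no raster cells with centres inside polygon")
  mean(vals)
}

#' Build the qualified TFA table for one individual
#'
#' Convenience wrapper: clusters the fixes inside the individual's core
#' range, builds 95% MCPs, applies the qualification rules, and assembles one
#' row per accepted TFA (area, occupancy span, optional mean population
#' density).
#'
#' @param track A `raptor_track` (fixes already limited to the core range).
#' @param eps,min_pts Clustering parameters, see [cluster_fixes()].
#' @param habitat Optional habitat raster/polygons for cluster splitting.
#' @param pop_density Optional continuous `uraster` of population density.
#' @return data.table with one row per accepted TFA: `individual_id`,
#'   `cluster`, `n_fixes`, `timespan_days`, `area_ha`, `habitat_label`,
#'   `mean_pop_density`; the MCP rings are attached as attribute `polygons`.
#' @export
extract_tfas <- function(track, eps = 150, min_pts = 10, habitat = NULL,
                         pop_density = NULL) {
  f <- track$fixes
  labels <- cluster_fixes(f, eps = eps, min_pts = min_pts, habitat = habitat)
  hab <- attr(labels, "habitat")
  rows <- list(); polys <- list()
  for (cl in sort(unique(labels[labels > 0]))) {
    sel <- labels == cl
    q <- qualify_tfa(f$timestamp[sel])
    if (!q$accept) next
    m <- try(mcp95(cbind(f$x[sel], f$y[sel]), f$timestamp[sel]), silent = TRUE)
    if (inherits(m, "try-error")) next
    pd <- if (is.null(pop_density)) NA_real_ else
      tryCatch(mean_covariate(m$polygon, pop_density),
               error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.table::data.table(
      individual_id = track$individual_id, cluster = cl, n_fixes = q$n_fixes,
      timespan_days = occupancy_timespan(f$timestamp[sel]),
      area_ha = m$area_ha,
      habitat_label = if (is.null(hab)) NA_character_ else
        names(sort(table(hab[sel]), decreasing = TRUE))[1],
      mean_pop_density = pd)
    polys[[length(polys) + 1]] <- m$polygon
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(individual_id = character(), cluster = integer(),
                           n_fixes = integer(), timespan_days = numeric(),
                           area_ha = numeric(), habitat_label = character(),
                           mean_pop_density = numeric())
  attr(out, "polygons") <- polys
  out
}
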