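# Planar geometry and the working map projection.
#
# The whole pipeline works in a single metric projection per study region: a
# spherical transverse Mercator centred on the region (or data) centroid.  At
# city scale (< ~30 km from the central meridian) scale distortion is below
# 1e-4, far inside the tolerances of any area reported here, and the forward /
# inverse pair is closed-form so coordinates round-trip to machine precision.

.EARTH_RADIUS <- 6371008.8 # mean Earth radius [m], IUGG

#' Define a local transverse-Mercator working projection
#'
#' @param lat0,lon0 Origin of the projection in decimal degrees; typically the
#'   centroid of the study region.  All projected coordinates are metres east
#'   (`x`) and north (`y`) of this origin.
#' @return An object of class `tm_projection`.
#' @export
tm_projection <- function(lat0, lon0) {
  stopifnot(is.finite(lat0), is.finite(lon0), abs(lat0) <= 90, abs(lon0) <= 180)
  structure(list(lat0 = lat0, lon0 = lon0), class = "tm_projection")
}

#' @export
print.tm_projection <- function(x, ...) {
  cat(sprintf("<tm_projection> centre %.5f N, %.5f E (spherical, metres)\n",
              x$lat0, x$lon0))
  invisible(x)
}

#' Project geographic coordinates to the working plane
#'
#' @param lon,lat Numeric vectors, decimal degrees (WGS84).
#' @param proj A [tm_projection()].
#' @return A two-column matrix `x`, `y` in metres.
#' @export
project_xy <- function(lon, lat, proj) {
  stopifnot(inherits(proj, "tm_projection"))
  phi <- lat * pi / 180
  lam <- (lon - proj$lon0) * pi / 180
  b <- cos(phi) * sin(lam)
  x <- .EARTH_RADIUS * atanh(b)
  y <- .EARTH_RADIUS * (atan2(tan(phi), cos(lam)) - proj$lat0 * pi / 180)
  cbind(x = x, y = y)
}

#' Inverse-project planar coordinates back to lon/lat
#'
#' @param x,y Numeric vectors, metres in the working projection.
#' @param proj A [tm_projection()].
#' @return A two-column matrix `lon`, `lat` in decimal degrees.
#' @export
unproject_xy <- function(x, y, proj) {
  stopifnot(inherits(proj, "tm_projection"))
  d <- y / .EARTH_RADIUS + proj$lat0 * pi / 180
  xr <- x / .EARTH_RADIUS
  phi <- asin(sin(d) / cosh(xr))
  lam <- atan2(sinh(xr), cos(d))
  cbind(lon = lam * 180 / pi + proj$lon0, lat = phi * 180 / pi)
}

#' Signed / absolute polygon area by the shoelace formula
#'
#' @param poly Two-column matrix of ring vertices (closed or open ring).
#' @param signed Return signed area (counter-clockwise positive)?
#' @return Area in squared input units.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1)) # previous vertex
  a <- sum(x[j] * y - x * y[j]) / 2
  if (signed) a else abs(a)
}

#' Point-in-polygon test (ray casting, boundary counts as inside)
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly Two-column vertex matrix of a simple polygon ring.
#' @param tol Absolute snap tolerance for the on-boundary test, metres.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    # boundary: point within tol of segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2))
    d2 <- (xi + t * dx - px)^2 + (yi + t * dy - py)^2
    on_edge <- on_edge | d2 <= tol * tol
    # ray cast (horizontal ray to +x)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Point-in-any-polygon over a polygon set
#'
#' @param px,py Point coordinates.
#' @param polys List of two-column vertex matrices (may be empty or `NULL`).
#' @export
point_in_any <- function(px, py, polys) {
  out <- logical(length(px))
  if (is.null(polys) || !length(polys)) return(out)
  for (p in polys) out <- out | point_in_polygon(px, py, p)
  out
}

#' Regular polygon approximating a circle
#'
#' @param centre Length-2 numeric `(x, y)`.
#' @param radius Radius in metres.
#' @param n Number of vertices.
#' @return Closed ring matrix.
#' @export
circle_polygon <- function(centre, radius, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

#' Convex hull of a point set
#'
#' Wrapper around [grDevices::chull()] returning the hull ring in
#' counter-clockwise order.
#' @param pts Two-column matrix.
#' @return Two-column matrix of hull vertices (open ring).
#' @export
convex_hull <- function(pts) {
  pts <- as.matrix(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[rev(idx), , drop = FALSE] # chull is clockwise; reverse to CCW
  colnames(hull) <- c("x", "y")
  hull
}

# --- GeoJSON helpers (WGS84 polygons) ---------------------------------------

#' Read polygons from a GeoJSON file
#'
#' Supports Polygon and MultiPolygon geometries inside a FeatureCollection or
#' bare geometry; only exterior rings are used (holes are ignored, which is
#' adequate for the region/water masks handled here).
#'
#' @param path File path.
#' @param proj Optional [tm_projection()]; when given, rings are projected to
#'   metres, otherwise returned in lon/lat degrees.
#' @return List of two-column vertex matrices.
#' @export
read_geojson_polygons <- function(path, proj = NULL) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- switch(g$type %||% "",
    FeatureCollection = lapply(g$features, function(f) f$geometry),
    Feature = list(g$geometry),
    list(g))
  rings <- list()
  for (geom in geoms) {
    if (is.null(geom)) next
    if (geom$type == "Polygon") {
      rings <- c(rings, list(geom$coordinates[[1]]))
    } else if (geom$type == "MultiPolygon") {
      rings <- c(rings, lapply(geom$coordinates, function(p) p[[1]]))
    }
  }
  out <- lapply(rings, function(r) {
    m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    if (!is.null(proj)) m <- project_xy(m[, 1], m[, 2], proj)
    colnames(m) <- if (is.null(proj)) c("lon", "lat") else c("x", "y")
    m
  })
  out
}

#' Write a set of polygons (with properties) to GeoJSON
#'
#' @param polys List of two-column vertex matrices in the working projection.
#' @param path Output path.
#' @param proj [tm_projection()] used to convert back to lon/lat.
#' @param properties Optional data.frame, one row per polygon.
#' @export
write_geojson_polygons <- function(polys, path, proj, properties = NULL) {
  features <- lapply(seq_along(polys), function(i) {
    m <- polys[[i]]
    if (m[1, 1] != m[nrow(m), 1] || m[1, 2] != m[nrow(m), 2])
      m <- rbind(m, m[1, ])
    ll <- unproject_xy(m[, 1], m[, 2], proj)
    coords <- lapply(seq_len(nrow(ll)), function(k) c(ll[k, 1], ll[k, 2]))
    props <- if (is.null(properties)) structure(list(), names = character(0))
             else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
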