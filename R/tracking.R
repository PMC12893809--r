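# GPS fix ingestion, quality control, daylight filtering and qualification.

#' Construct a track object
#'
#' A track bundles the time-ordered GPS fixes of one individual with its nest
#' location and hatch date.  Fixes are stored as a `data.table` with columns
#' `timestamp` (POSIXct, UTC), `lon`, `lat`, `x`, `y` (metres, working
#' projection), `hdop`, `n_satellites`.
#'
#' @param individual_id Character scalar.
#' @param fixes data.frame/data.table of fixes (see above); sorted by time.
#' @param proj The [tm_projection()] used for `x`, `y`.
#' @param nest Optional length-2 numeric `(x, y)` nest location, metres.
#' @param hatch_date Optional `Date`.
#' @return Object of class `raptor_track`.
#' @export
new_track <- function(individual_id, fixes, proj, nest = NULL, hatch_date = NULL) {
  fixes <- data.table::as.data.table(fixes)
  req <- c("timestamp", "lon", "lat", "x", "y", "hdop", "n_satellites")
  miss <- setdiff(req, names(fixes))
  if (length(miss))
    stop("track fixes missing column(s): ", paste(miss, collapse = ", "))
  data.table::setorder(fixes, timestamp)
  if (anyDuplicated(fixes$timestamp))
    stop("duplicate timestamps in track ", individual_id)
  structure(list(individual_id = as.character(individual_id),
                 fixes = fixes, proj = proj, nest = nest,
                 hatch_date = hatch_date),
            class = "raptor_track")
}

#' @export
print.raptor_track <- function(x, ...) {
  cat(sprintf("<raptor_track> %s: %d fixes, %s .. %s\n", x$individual_id,
              nrow(x$fixes),
              format(min(x$fixes$timestamp)), format(max(x$fixes$timestamp))))
  invisible(x)
}

#' Number of fixes in a track
#' @param track A `raptor_track`.
#' @export
n_fixes <- function(track) nrow(track$fixes)

#' Read tracker CSV into per-individual tracks
#'
#' Expects header columns `individual_id, timestamp, lon, lat, hdop,
#' n_satellites` (ISO-8601 UTC timestamps).  Rows are grouped by individual,
#' sorted by timestamp, and duplicate timestamps within an individual are
#' collapsed to the first occurrence with a warning.
#'
#' @param path CSV file path.
#' @param id_map Optional named character vector renaming file columns to the
#'   canonical names, e.g. `c("tag-local-identifier" = "individual_id")`.
#' @param proj Optional [tm_projection()]; defaults to one centred on the
#'   centroid of all fixes.
#' @param nests Optional nest table from [read_nests()] (attaches nest
#'   coordinates and hatch dates).
#' @return Named list of [new_track()] objects.
#' @export
read_fixes <- function(path, id_map = NULL, proj = NULL, nests = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, colClasses = list(character = 1))
  if (!is.null(id_map)) {
    for (old in names(id_map))
      if (old %in% names(dt)) data.table::setnames(dt, old, id_map[[old]])
  }
  req <- c("individual_id", "timestamp", "lon", "lat", "hdop", "n_satellites")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  ts <- rep(as.POSIXct(NA), nrow(dt))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- is.na(ts)
    if (!any(idx)) break
    ts[idx] <- as.POSIXct(strptime(dt$timestamp[idx], fmt, tz = "UTC"))
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable timestamp at data row %d: '%s'", bad,
                 dt$timestamp[bad]))
  }
  dt[, timestamp := ts]
  dt[, individual_id := as.character(individual_id)]
  if (is.null(proj))
    proj <- tm_projection(mean(dt$lat), mean(dt$lon))
  xy <- project_xy(dt$lon, dt$lat, proj)
  dt[, `:=`(x = xy[, 1], y = xy[, 2])]
  data.table::setorder(dt, individual_id, timestamp)
  tracks <- list()
  for (id in unique(dt$individual_id)) {
    sub <- dt[individual_id == id]
    dup <- duplicated(sub$timestamp)
    if (any(dup)) {
      warning(sprintf("%s: %d duplicate timestamp(s) collapsed to first fix",
                      id, sum(dup)))
      sub <- sub[!dup]
    }
    nest <- NULL; hatch <- NULL
    if (!is.null(nests) && id %in% nests$individual_id) {
      nr <- nests[nests$individual_id == id, ][1, ]
      nest <- as.numeric(project_xy(nr$nest_lon, nr$nest_lat, proj))
      hatch <- as.Date(nr$hatch_date)
    }
    tracks[[id]] <- new_track(id, sub[, !"individual_id"], proj,
                              nest = nest, hatch_date = hatch)
  }
  tracks
}

#' Read nest metadata CSV
#'
#' Columns: `individual_id, nest_lon, nest_lat, hatch_date`.
#' @param path CSV path.
#' @return data.table.
#' @export
read_nests <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "individual_id"))
  req <- c("individual_id", "nest_lon", "nest_lat", "hatch_date")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  dt[, hatch_date := as.Date(hatch_date)]
  dt
}

#' Write track fixes back to CSV
#'
#' Canonical dialect: header `individual_id,timestamp,lon,lat,hdop,
#' n_satellites,x,y`, ISO-8601 timestamps.
#' @param tracks List of tracks.
#' @param path Output CSV path.
#' @export
write_fixes <- function(tracks, path) {
  rows <- data.table::rbindlist(lapply(tracks, function(tr) {
    f <- data.table::copy(tr$fixes)
    f[, individual_id := tr$individual_id]
    f[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
    f[, .(individual_id, timestamp, lon, lat, hdop, n_satellites, x, y)]
  }))
  data.table::fwrite(rows, path)
  invisible(path)
}

#' Drop imprecise fixes by HDOP and satellite count
#'
#' Removes fixes with `hdop > hdop_max` or `n_satellites < min_sats`; the
#' boundary values (HDOP exactly 4, exactly 5 satellites) are retained.
#'
#' @param track A `raptor_track`.
#' @param hdop_max Maximum tolerated horizontal dilution of precision.
#' @param min_sats Minimum satellite count.
#' @return Filtered track (possibly with zero fixes).
#' @export
qc_filter <- function(track, hdop_max = 4, min_sats = 5) {
  stopifnot(inherits(track, "raptor_track"), nrow(track$fixes) > 0)
  keep <- track$fixes$hdop <= hdop_max & track$fixes$n_satellites >= min_sats
  replace_fixes(track, track$fixes[keep])
}

replace_fixes <- function(track, fixes) {
  track$fixes <- fixes
  track
}

#' Geometric solar elevation angle
#'
#' NOAA-style low-precision solar position: fractional-year based declination
#' and equation of time, then elevation from the hour angle.  Atmospheric
#' refraction is ignored (shifts the horizon crossing by < 0.6 degrees, well
#' inside the -12 degree twilight margin used downstream).
#'
#' @param lat,lon Decimal degrees.
#' @param t POSIXct, UTC.
#' @return Elevation above the horizon in degrees.
#' @export
solar_elevation <- function(lat, lon, t) {
  t <- as.POSIXlt(t, tz = "UTC")
  doy <- t$yday + 1
  hour <- t$hour + t$min / 60 + t$sec / 3600
  # fractional year [rad]
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  # equation of time [min], declination [rad] (Spencer / NOAA series)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour * 60 + eqtime + 4 * lon          # true solar time [min]
  ha <- (tst / 4 - 180) * pi / 180             # hour angle [rad]
  phi <- lat * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  cosz <- pmin(1, pmax(-1, cosz))
  90 - acos(cosz) * 180 / pi
}

#' Keep only daytime fixes (nautical twilight included)
#'
#' Retains fixes whose geometric solar elevation at the fix's own coordinates
#' and time is at least `min_elevation` degrees; the default -12 degrees marks
#' the nautical-twilight boundary.
#'
#' @param track A `raptor_track`.
#' @param min_elevation Threshold in degrees.
#' @return Filtered track.
#' @export
daylight_filter <- function(track, min_elevation = -12) {
  stopifnot(inherits(track, "raptor_track"), nrow(track$fixes) > 0)
  f <- track$fixes
  keep <- solar_elevation(f$lat, f$lon, f$timestamp) >= min_elevation
  replace_fixes(track, f[keep])
}

#' Clip tracks to the study region and keep adequately tracked individuals
#'
#' Drops fixes outside `region` (boundary counts as inside), then excludes any
#' individual with fewer than `min_tracking_days` distinct UTC calendar dates
#' of remaining data.  Exclusions are reported via `message()`.
#'
#' @param tracks List of `raptor_track`s.
#' @param region Two-column polygon ring, metres (working projection).
#' @param min_tracking_days Minimum number of distinct tracking days.
#' @return Named list of retained, clipped tracks.
#' @export
clip_and_qualify <- function(tracks, region, min_tracking_days = 30) {
  region <- as.matrix(region)
  if (polygon_area(region) <= 0) stop("degenerate region polygon (zero area)")
  out <- list()
  for (tr in tracks) {
    f <- tr$fixes
    keep <- point_in_polygon(f$x, f$y, region)
    f <- f[keep]
    ndays <- length(unique(as.Date(f$timestamp, tz = "UTC")))
    if (ndays < min_tracking_days) {
      message(sprintf("excluding %s: %d tracking day(s) < %d",
                      tr$individual_id, ndays, min_tracking_days))
      next
    }
    out[[tr$individual_id]] <- replace_fixes(tr, f)
  }
  out
}
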