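# Natal-dispersal onset by the distance-threshold rule, and truncation of
# tracks to the dispersal window (onset .. age 730 days).

#' Detect natal-dispersal onset
#'
#' Onset is the earliest calendar date on which every fix lies strictly more
#' than `radius` metres from the nest, with no fix at or within `radius`
#' during the following `return_window` days.  The default 1000 m radius
#' corresponds to a circular parental territory of ~3.1 km^2.  Days with no
#' fixes inside the return window count as non-returns (absence of evidence
#' cannot veto onset); such gaps are reported via `message()`.
#'
#' @param track A QC'd, time-sorted `raptor_track`.
#' @param nest Length-2 numeric `(x, y)` in metres; defaults to `track$nest`.
#' @param radius Territory radius, metres.
#' @param return_window Days that must stay outside before onset counts.
#' @return List of class `dispersal_result`: `individual_id`, `onset_date`
#'   (`Date` or `NA`), `territory_radius`, `return_window`.
#' @export
detect_onset <- function(track, nest = track$nest, radius = 1000,
                         return_window = 7) {
  stopifnot(inherits(track, "raptor_track"))
  if (nrow(track$fixes) == 0) stop("empty track")
  if (is.null(nest)) stop("no nest location on track and none supplied")
  f <- track$fixes
  d <- sqrt((f$x - nest[1])^2 + (f$y - nest[2])^2)
  date <- as.Date(f$timestamp, tz = "UTC")
  # per-day summary: any fix inside the territory circle?
  days <- sort(unique(date))
  any_inside <- vapply(days, function(D) any(d[date == D] <= radius), logical(1))
  onset <- as.Date(NA)
  for (k in seq_along(days)) {
    if (any_inside[k]) next
    D <- days[k]
    win <- days > D & days <= D + return_window
    if (any(any_inside[win])) next
    gap <- return_window - sum(win)
    if (gap > 0)
      message(sprintf("%s: %d day(s) without fixes in return window after %s treated as non-returns",
                      track$individual_id, gap, format(D)))
    onset <- D
    break
  }
  structure(list(individual_id = track$individual_id, onset_date = onset,
                 territory_radius = radius, return_window = return_window),
            class = "dispersal_result")
}

#' @export
print.dispersal_result <- function(x, ...) {
  cat(sprintf("<dispersal_result> %s: onset %s (radius %g m, window %d d)\n",
              x$individual_id,
              if (is.na(x$onset_date)) "not detected" else format(x$onset_date),
              x$territory_radius, x$return_window))
  invisible(x)
}

#' Truncate a track to the natal-dispersal window
#'
#' Keeps fixes on or after the detected onset date and up to an age of
#' `max_age` days (inclusive) past the hatch date.
#'
#' @param track A `raptor_track` with `hatch_date` set.
#' @param result A `dispersal_result` with a detected onset.
#' @param max_age Maximum age in days (default two years).
#' @return Truncated track.
#' @export
dispersal_window <- function(track, result, max_age = 730) {
  stopifnot(inherits(track, "raptor_track"), inherits(result, "dispersal_result"))
  if (is.na(result$onset_date))
    stop("no dispersal onset detected for ", track$individual_id,
         "; exclude this individual")
  if (is.null(track$hatch_date)) stop("track has no hatch_date")
  date <- as.Date(track$fixes$timestamp, tz = "UTC")
  age <- as.numeric(date - track$hatch_date)
  keep <- date >= result$onset_date & age <= max_age
  replace_fixes(track, track$fixes[keep])
}
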