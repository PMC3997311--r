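## Construction of the animal x camera analysis table: availability,
## detection events, proximity counts, and home-range covariates.

#' Group detection images into independent events
#'
#' Images of one animal at one camera are grouped into detection events: a
#' new event starts whenever the gap from the previous image is at least
#' `min_gap` minutes.
#'
#' @param timestamps POSIXct vector of image times (any order).
#' @param min_gap minimum separation in minutes (default 15).
#' @return data.frame with one row per event: `start`, `end`, `n_images`.
#'   `nrow()` of the result is the photo count.
#' @examples
#' t0 <- as.POSIXct("2009-01-01 12:00", tz = "UTC")
#' nrow(group_detections(t0 + c(0, 10 * 60)))  # 1 event
#' nrow(group_detections(t0 + c(0, 16 * 60)))  # 2 events
#' @export
group_detections <- function(timestamps, min_gap = 15) {
  if (length(timestamps) == 0)
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_images = integer()))
  ts <- sort(timestamps)
  gaps <- as.numeric(difftime(ts[-1], ts[-length(ts)], units = "mins"))
  ev <- cumsum(c(1L, as.integer(gaps >= min_gap)))
  data.frame(start = as.POSIXct(tapply(as.numeric(ts), ev, min),
                                origin = "1970-01-01", tz = "UTC"),
             end = as.POSIXct(tapply(as.numeric(ts), ev, max),
                              origin = "1970-01-01", tz = "UTC"),
             n_images = as.integer(table(ev)))
}

#' Count telemetry relocations within a camera neighbourhood
#'
#' Planar Euclidean count of one animal's relocations within `radius`
#' metres of a camera, restricted to a date window (the *NLocs* covariate).
#' Radii above half the minimum camera spacing void the guarantee that each
#' relocation is counted for at most one camera; a warning is issued when
#' `min_spacing` is supplied and violated.
#'
#' @param telemetry relocations of one animal (`date`, `x`, `y`).
#' @param camera_x,camera_y camera coordinates (metres).
#' @param radius neighbourhood radius in metres (250 or 500 in the standard
#'   design).
#' @param window optional `c(start, end)` dates (inclusive).
#' @param season optional season label; only relocations in that season are
#'   counted.
#' @param min_spacing optional minimum inter-camera spacing for the
#'   uniqueness warning.
#' @return integer count.
#' @export
count_relocations_within <- function(telemetry, camera_x, camera_y, radius,
                                     window = NULL, season = NULL,
                                     min_spacing = NULL) {
  if (!is.null(min_spacing) && radius > min_spacing / 2)
    warnf("radius %g m exceeds half the minimum camera spacing (%g m): relocations may be counted at several cameras",
          radius, min_spacing)
  keep <- rep(TRUE, nrow(telemetry))
  if (!is.null(window))
    keep <- keep & telemetry$date >= as_date(window[1]) &
      telemetry$date <= as_date(window[2])
  if (!is.null(season))
    keep <- keep & assign_season(telemetry$date) == season
  if (!any(keep)) return(0L)
  d2 <- (telemetry$x[keep] - camera_x)^2 + (telemetry$y[keep] - camera_y)^2
  sum(d2 <= radius^2)
}

default_tracking <- function(telemetry) {
  agg <- aggregate(date ~ animal_id + sex, telemetry,
                   function(d) c(min = min(d), max = max(d)))
  data.frame(animal_id = agg$animal_id, sex = agg$sex,
             start = as.Date(agg$date[, "min"], origin = "1970-01-01"),
             end = as.Date(agg$date[, "max"], origin = "1970-01-01"))
}

#' Estimate per-animal, per-period utilization distributions
#'
#' Runs [select_bandwidth()] for each animal and period and attaches a
#' 1%-step isopleth table (thresholds up to 95%).  Animals with fewer than
#' the minimum number of relocations for a period are skipped (reported in
#' the `skipped` attribute): the default floors are 25 relocations for a
#' seasonal range and 5 for an annual range.
#'
#' @param telemetry telemetry data.frame (`animal_id`, `sex`, `date`, `x`,
#'   `y`).
#' @param periods subset of `c("Annual", "FallWinter", "Summer")`.
#' @param min_relocs named vector of floors per period; `NULL` for the
#'   defaults.
#' @param ... passed to [select_bandwidth()].
#' @return nested list `hr[[animal_id]][[period]]`, each element a list
#'   with `ud`, `isos`, `multiplier`, `n`; attribute `skipped` is a
#'   data.frame of skipped combinations.
#' @export
estimate_homeranges <- function(telemetry, periods = c("FallWinter",
                                                       "Summer"),
                                min_relocs = NULL, ...) {
  if (is.null(min_relocs))
    min_relocs <- c(Annual = 5, FallWinter = 25, Summer = 25)
  out <- list()
  skipped <- list()
  for (id in unique(telemetry$animal_id)) {
    tel <- telemetry[telemetry$animal_id == id, ]
    for (per in periods) {
      pts <- tel[period_filter(tel$date, per), c("x", "y")]
      if (nrow(pts) < min_relocs[[per]]) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          animal_id = id, period = per, n = nrow(pts))
        next
      }
      sel <- select_bandwidth(pts, animal_id = id, period = per, ...)
      isos <- isopleths(sel$ud, 1:95, fragments = FALSE)
      out[[id]][[per]] <- list(ud = sel$ud, isos = isos,
                               multiplier = sel$multiplier, n = nrow(pts))
    }
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    NULL
  out
}

#' Identify available animal x camera pairs
#'
#' A camera is *available* to an animal, in a season, when (i) the camera
#' deployment window overlaps the animal's tracking window with at least
#' one non-excluded day of that season, and (ii) — when home ranges are
#' supplied — the camera point lies inside the animal's 90% isopleth (grid
#' membership: interpolated density at or above the 90% threshold).
#'
#' @param tracking data.frame (`animal_id`, `sex`, `start`, `end`) of
#'   tracking windows.
#' @param cameras camera deployments (`camera_id`, `x`, `y`, `start`,
#'   `end`).  Zero-length or reversed windows are dropped with a warning.
#' @param homeranges optional [estimate_homeranges()] result for the
#'   spatial criterion.
#' @param seasons seasons to generate rows for.
#' @param truncate availability isopleth in percent (default 90).
#' @return data.frame with one row per available (animal, camera, season):
#'   ids, sex, season, overlap window (`ov_start`, `ov_end`) and
#'   `exposure_days` (non-excluded days of that season inside the overlap).
#' @export
available_pairs <- function(tracking, cameras, homeranges = NULL,
                            seasons = season_levels, truncate = 90) {
  bad <- cameras$end < cameras$start
  if (any(bad)) {
    warnf("dropping %d camera(s) with empty deployment windows", sum(bad))
    cameras <- cameras[!bad, , drop = FALSE]
  }
  rows <- list()
  for (ai in seq_len(nrow(tracking))) {
    id <- tracking$animal_id[ai]
    hr <- homeranges[[id]]
    for (ci in seq_len(nrow(cameras))) {
      ov <- overlap_window(cameras$start[ci], cameras$end[ci],
                           tracking$start[ai], tracking$end[ai])
      if (is.null(ov)) next
      for (season in seasons) {
        if (!is.null(homeranges)) {
          h <- hr[[season]]
          if (is.null(h)) next   # no UD for this animal/season
          dens <- ud_at(h$ud, cameras$x[ci], cameras$y[ci])
          if (dens < iso_threshold(h$isos, truncate)) next
        }
        expo <- season_days(ov[1], ov[2], season)
        if (expo == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, camera_id = cameras$camera_id[ci],
          sex = tracking$sex[ai], season = season,
          ov_start = ov[1], ov_end = ov[2], exposure_days = expo,
          cam_x = cameras$x[ci], cam_y = cameras$y[ci])
      }
    }
  }
  if (!length(rows))
    return(data.frame(animal_id = character(), camera_id = character(),
                      sex = character(), season = character(),
                      ov_start = as.Date(character()),
                      ov_end = as.Date(character()),
                      exposure_days = integer(), cam_x = numeric(),
                      cam_y = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the animal x camera encounter table
#'
#' One row per available pair (split by season).  For the proximity
#' analysis, availability is temporal-overlap based and the `NLocs`
#' covariates are filled; for the home-range analysis, availability adds
#' the 90%-isopleth criterion and the `ud` / `isopleth_pct` / `core`
#' covariates are filled from the matching seasonal UD.  Detections and
#' photo counts come from [group_detections()] applied to the images inside
#' each row's overlap window and season; images that fall in no available
#' row are dropped and counted in the `n_dropped_images` attribute.
#'
#' @param telemetry telemetry data.frame.
#' @param cameras camera deployments.
#' @param detections image table (`camera_id`, `animal_id`, `timestamp`).
#' @param homeranges [estimate_homeranges()] result (required for
#'   `analysis = "homerange"`).
#' @param analysis `"proximity"` or `"homerange"`.
#' @param radii proximity radii in metres (subset of `c(250, 500)`).
#' @param truncate availability isopleth in percent.
#' @param min_gap detection-event separation in minutes.
#' @param tracking optional tracking windows; defaults to each animal's
#'   telemetry date range.
#' @return data.frame of encounter records with columns `animal_id`,
#'   `camera_id`, `sex`, `season`, `exposure_days`, `n_locs_250`,
#'   `n_locs_500`, `ud`, `isopleth_pct`, `core`, `detected`,
#'   `photo_count`; attribute `n_dropped_images` reports images outside
#'   available pairs.
#' @export
build_encounter_table <- function(telemetry, cameras, detections,
                                  homeranges = NULL,
                                  analysis = c("proximity", "homerange"),
                                  radii = c(250, 500), truncate = 90,
                                  min_gap = 15, tracking = NULL) {
  analysis <- match.arg(analysis)
  if (analysis == "homerange" && is.null(homeranges))
    stopf("homerange analysis requires estimated home ranges")
  if (!all(radii %in% c(250, 500)))
    stopf("radii must be a subset of {250, 500}")
  tracking <- tracking %||% default_tracking(telemetry)
  pairs <- available_pairs(tracking, cameras,
                           homeranges = if (analysis == "homerange")
                             homeranges else NULL,
                           truncate = truncate)
  if (nrow(pairs) == 0) {
    warnf("no available animal x camera pairs")
    return(pairs)
  }
  if (nrow(cameras) > 1) {
    dd <- as.matrix(stats::dist(cameras[, c("x", "y")]))
    diag(dd) <- Inf
    min_spacing <- min(dd)
    if (max(radii) > min_spacing / 2)
      warnf("radius %g m exceeds half the minimum camera spacing (%.0f m): relocations may be counted at several cameras",
            max(radii), min_spacing)
  }
  n <- nrow(pairs)
  pairs$n_locs_250 <- NA_integer_
  pairs$n_locs_500 <- NA_integer_
  pairs$ud <- NA_real_
  pairs$isopleth_pct <- NA_integer_
  pairs$core <- NA
  pairs$photo_count <- 0L
  det_season <- assign_season(as.Date(detections$timestamp, tz = "UTC"))
  used <- rep(FALSE, nrow(detections))
  for (i in seq_len(n)) {
    id <- pairs$animal_id[i]; cam <- pairs$camera_id[i]
    sel <- detections$animal_id == id & detections$camera_id == cam &
      as.Date(detections$timestamp, tz = "UTC") >= pairs$ov_start[i] &
      as.Date(detections$timestamp, tz = "UTC") <= pairs$ov_end[i] &
      det_season == pairs$season[i]
    used <- used | sel
    if (any(sel))
      pairs$photo_count[i] <- nrow(group_detections(
        detections$timestamp[sel], min_gap = min_gap))
    tel <- telemetry[telemetry$animal_id == id, ]
    for (r in radii)
      pairs[[paste0("n_locs_", r)]][i] <- count_relocations_within(
        tel, pairs$cam_x[i], pairs$cam_y[i], r,
        window = c(pairs$ov_start[i], pairs$ov_end[i]),
        season = pairs$season[i])
    if (analysis == "homerange") {
      h <- homeranges[[id]][[pairs$season[i]]]
      pairs$ud[i] <- ud_at(h$ud, pairs$cam_x[i], pairs$cam_y[i])
      pairs$isopleth_pct[i] <- isopleth_percentile_at(
        h$ud, h$isos, pairs$cam_x[i], pairs$cam_y[i], truncate = truncate)
    }
  }
  pairs$core <- pairs$isopleth_pct <= 50L
  pairs$detected <- as.integer(pairs$photo_count > 0)
  out <- pairs[, c("animal_id", "camera_id", "sex", "season",
                   "exposure_days", "n_locs_250", "n_locs_500", "ud",
                   "isopleth_pct", "core", "detected", "photo_count")]
  attr(out, "n_dropped_images") <- sum(!used)
  validate_encounters(out, analysis = analysis)
  out
}

#' Validate encounter-record invariants
#'
#' Checks, on every table build: `core` iff `isopleth_pct <= 50`,
#' `detected` iff `photo_count >= 1`, `n_locs_250 <= n_locs_500`, positive
#' exposure, and isopleth percentiles in `[1, 90]`.
#'
#' @param tab an encounter table.
#' @param analysis which analysis the table was built for.
#' @return `tab`, invisibly; errors on violation.
#' @export
validate_encounters <- function(tab, analysis = "homerange") {
  if (any(tab$exposure_days <= 0)) stopf("non-positive exposure_days")
  if (any((tab$detected == 1) != (tab$photo_count >= 1)))
    stopf("detected flag inconsistent with photo_count")
  both <- !is.na(tab$n_locs_250) & !is.na(tab$n_locs_500)
  if (any(tab$n_locs_250[both] > tab$n_locs_500[both]))
    stopf("n_locs_250 exceeds n_locs_500")
  if (analysis == "homerange") {
    if (any(is.na(tab$ud)) || any(tab$ud < 0))
      stopf("missing or negative utilization densities")
    ok <- !is.na(tab$isopleth_pct)
    if (any(tab$isopleth_pct[ok] < 1 | tab$isopleth_pct[ok] > 90))
      stopf("isopleth percentiles outside [1, 90]")
    if (any(tab$core[ok] != (tab$isopleth_pct[ok] <= 50)))
      stopf("core flag inconsistent with isopleth percentile")
  }
  invisible(tab)
}
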