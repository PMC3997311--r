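## Synthetic movement + camera-trap generator.
##
## Home ranges are stationary Gaussian mixtures (1-3 components): the
## downstream analyses only use marginal space-use frequency, which is
## exactly what a kernel home range measures, so trajectory autocorrelation
## is deliberately not modelled.  The "true" utilization density at a camera
## is the mixture density evaluated at the camera point, so kernel
## estimation error is a measurable property of the pipeline rather than a
## simulation artifact.

# bivariate normal density with explicit 2x2 covariance (closed form)
dmvnorm2 <- function(x, y, mu, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  dx <- x - mu[1]; dy <- y - mu[2]
  q <- (S[2, 2] * dx^2 - 2 * S[1, 2] * dx * dy + S[1, 1] * dy^2) / det
  exp(-q / 2) / (2 * pi * sqrt(det))
}

#' True utilization density of a simulated animal
#'
#' Evaluates the Gaussian-mixture home-range density (per m^2) at arbitrary
#' points.  This is the generating density, not a kernel estimate.
#'
#' @param animal an `animal_truth` element from [simulate_population()].
#' @param x,y point coordinates in metres (vectorized).
#' @return numeric vector of densities (per m^2).
#' @export
true_ud <- function(animal, x, y) {
  out <- 0
  for (cmp in animal$components)
    out <- out + cmp$w * dmvnorm2(x, y, cmp$mu, cmp$sigma)
  out
}

# draw n points from an animal's mixture (uses the current RNG stream)
rmixture <- function(n, animal) {
  k <- length(animal$components)
  w <- vapply(animal$components, `[[`, numeric(1), "w")
  idx <- sample.int(k, n, replace = TRUE, prob = w)
  out <- matrix(0, n, 2)
  for (j in seq_len(k)) {
    nj <- sum(idx == j)
    if (nj == 0) next
    cmp <- animal$components[[j]]
    L <- chol(cmp$sigma)
    z <- matrix(rnorm(2 * nj), nj, 2) %*% L
    out[idx == j, ] <- sweep(z, 2, cmp$mu, `+`)
  }
  out
}

#' Monte-Carlo isopleth quantities of the true mixture density
#'
#' For a density f, the p% isopleth region is `{x : f(x) >= t_p}` where
#' `t_p` is chosen so the region holds p% of the mass; equivalently `t_p` is
#' the `(1 - p/100)` quantile of `f(X)` for `X ~ f`.  These helpers estimate
#' the threshold, the isopleth percentile of a point
#' (`100 * P[f(X) >= f(point)]`), and the region's area
#' (`E[1{f(X) >= t} / f(X)]`) by Monte Carlo.
#'
#' @param animal an `animal_truth` object.
#' @param p isopleth percentage in (0, 100).
#' @param n_mc number of Monte-Carlo draws.
#' @return `true_isopleth_threshold`: density threshold (per m^2);
#'   `true_isopleth_area`: area in m^2; `true_isopleth_pct`: integer
#'   percentile (1-100) per point.
#' @name true_isopleth
#' @export
true_isopleth_threshold <- function(animal, p = 90, n_mc = 2000) {
  pts <- rmixture(n_mc, animal)
  dens <- true_ud(animal, pts[, 1], pts[, 2])
  unname(quantile(dens, 1 - p / 100, type = 7))
}

#' @rdname true_isopleth
#' @export
true_isopleth_area <- function(animal, p = 95, n_mc = 20000) {
  pts <- rmixture(n_mc, animal)
  dens <- true_ud(animal, pts[, 1], pts[, 2])
  t_p <- quantile(dens, 1 - p / 100, type = 7)
  mean((dens >= t_p) / dens)
}

#' @rdname true_isopleth
#' @param x,y point coordinates in metres (vectorized).
#' @export
true_isopleth_pct <- function(animal, x, y, n_mc = 2000) {
  pts <- rmixture(n_mc, animal)
  dens <- true_ud(animal, pts[, 1], pts[, 2])
  d0 <- true_ud(animal, x, y)
  pmax(1L, as.integer(ceiling(100 * vapply(
    d0, function(d) mean(dens >= d), numeric(1)))))
}

# one random mixture component; v = per-axis variance scale (m^2)
random_component <- function(mu, v) {
  u <- runif(1, 0.7, 1.3)        # component area factor, mean 1
  a <- runif(1, 0.8, 1.25)       # anisotropy ratio of axis SDs
  th <- runif(1, 0, pi)
  s1 <- sqrt(v * u) * a
  s2 <- sqrt(v * u) / a
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  list(mu = mu, sigma = R %*% diag(c(s1^2, s2^2)) %*% t(R), w = NA_real_)
}

#' Simulate a population of animals with sex-dimorphic home ranges
#'
#' Each animal receives a Gaussian-mixture home range (1 to
#' `config$max_components` components).  Male per-axis variances are
#' `range_scale_male` times female variances and male component offsets are
#' scaled by `sqrt(range_scale_male)`, so the expected male/female home-range
#' *area* ratio equals `range_scale_male` exactly.
#'
#' @param config a [sim_config()].
#' @param seed override of `config$seed` (used by replicate loops).
#' @return list of `animal_truth` objects: `animal_id`, `sex`, `components`
#'   (centre, covariance, weight), `range_scale`, `detect_intercept`,
#'   `frailty_shape` (filled at detection time), tracking window, `index`.
#' @examples
#' pop <- simulate_population(sim_config(n_females = 2, n_males = 1, seed = 7))
#' vapply(pop, `[[`, character(1), "sex")
#' @export
simulate_population <- function(config, seed = NULL) {
  set.seed(sub_seed(seed %||% config$seed, 1L))
  n <- config$n_females + config$n_males
  sexes <- c(rep("F", config$n_females), rep("M", config$n_males))
  t_start <- config$year_start
  t_end <- config$year_start + 364
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- sexes[i]
    scale <- if (sex == "M") config$range_scale_male else 1
    v <- config$sigma_female^2 * scale
    margin <- sqrt(v)
    if (any(config$extent <= 2 * margin))
      stopf("extent (%g x %g m) too small to hold a home range of SD %g m",
            config$extent[1], config$extent[2], margin)
    c1 <- c(runif(1, margin, config$extent[1] - margin),
            runif(1, margin, config$extent[2] - margin))
    k <- sample.int(config$max_components, 1)
    comps <- vector("list", k)
    comps[[1]] <- random_component(c1, v)
    if (k > 1) for (j in 2:k) {
      mu <- c1 + rnorm(2, 0, 1.2 * sqrt(v))
      mu <- pmin(pmax(mu, margin), config$extent - margin)
      comps[[j]] <- random_component(mu, v)
    }
    w <- rgamma(k, shape = 2)
    w <- w / sum(w)
    for (j in seq_len(k)) comps[[j]]$w <- w[j]
    id <- sprintf("%s%02d", sex, if (sex == "F") i else i - config$n_females)
    out[[i]] <- structure(list(
      animal_id = id, sex = sex, components = comps,
      range_scale = scale,
      detect_intercept = if (sex == "M") config$beta_m else config$beta_f,
      frailty_shape = NULL,
      tracking_start = t_start, tracking_end = t_end,
      index = i), class = "animal_truth")
  }
  out
}

#' Sample telemetry relocations for one animal
#'
#' Relocation days are drawn uniformly over the tracking window at a rate of
#' `relocs_per_week`; positions are mixture draws plus isotropic Gaussian
#' positional error with SD `telemetry_error_sd` per axis.  Fixes are at
#' most one per day (aerial-telemetry style); timestamps carry the date only.
#'
#' @param animal an `animal_truth` object.
#' @param window `c(start, end)` dates; defaults to the animal's tracking
#'   window.
#' @param config a [sim_config()].
#' @param seed override seed (defaults to a substream of `config$seed`
#'   specific to this animal).
#' @return data.frame with columns `animal_id`, `sex`, `date`, `x`, `y`.
#' @export
sample_relocations <- function(animal, window = NULL, config, seed = NULL) {
  window <- window %||% c(animal$tracking_start, animal$tracking_end)
  start <- as_date(window[1]); end <- as_date(window[2])
  if (start > end) stopf("empty relocation window")
  set.seed(seed %||% sub_seed(config$seed, 2L, animal$index))
  days <- seq(start, end, by = "day")
  n <- round(config$relocs_per_week * length(days) / 7)
  if (n < 1)
    return(data.frame(animal_id = character(), sex = character(),
                      date = as.Date(character()), x = numeric(),
                      y = numeric()))
  dates <- sort(days[sample.int(length(days), n,
                                replace = n > length(days))])
  pts <- rmixture(n, animal)
  err <- matrix(rnorm(2 * n, 0, config$telemetry_error_sd), n, 2)
  data.frame(animal_id = animal$animal_id, sex = animal$sex, date = dates,
             x = pts[, 1] + err[, 1], y = pts[, 2] + err[, 2])
}

#' Build a systematic camera grid with staggered deployments
#'
#' One camera per `camera_cell` grid cell at the cell centre plus uniform
#' jitter; deployment windows of `deployment_length_days` start uniformly
#' through the study year (not all cells can be surveyed at once in the
#' design being emulated).  Nearest-neighbour spacing is at least
#' `camera_cell - 2 * camera_jitter`.
#'
#' @param extent `c(width, height)` in metres; defaults to `config$extent`.
#' @param config a [sim_config()].
#' @param seed override seed.
#' @return data.frame with `camera_id`, `x`, `y`, `start`, `end`.
#' @examples
#' cams <- build_camera_grid(c(3000, 3000),
#'   sim_config(camera_jitter = 0, seed = 1))
#' nrow(cams)  # 9 cameras on a 3 x 3 grid
#' @export
build_camera_grid <- function(extent = config$extent, config, seed = NULL) {
  nx <- floor(extent[1] / config$camera_cell)
  ny <- floor(extent[2] / config$camera_cell)
  if (nx < 1 || ny < 1)
    stopf("extent spans no full %g-m camera cell", config$camera_cell)
  set.seed(seed %||% sub_seed(config$seed, 3L))
  centres <- expand.grid(
    x = (seq_len(nx) - 0.5) * config$camera_cell,
    y = (seq_len(ny) - 0.5) * config$camera_cell)
  n <- nrow(centres)
  jx <- runif(n, -config$camera_jitter, config$camera_jitter)
  jy <- runif(n, -config$camera_jitter, config$camera_jitter)
  len <- config$deployment_length_days
  start_day <- floor(runif(n, 0, 365 - len + 1))
  start <- config$year_start + start_day
  data.frame(camera_id = sprintf("C%03d", seq_len(n)),
             x = centres$x + jx, y = centres$y + jy,
             start = start, end = start + len - 1)
}

#' Calibrate the gamma-frailty shape to a target overdispersion
#'
#' With a unit-mean gamma frailty of shape `a` multiplying Poisson means
#' `mu`, the expected saturated-model Pearson dispersion is
#' `1 + mean(mu) / a` (exact for the Poisson-gamma mixture).  The shape
#' solving `1 + mean(mu)/a = target` is found by bisection.
#'
#' @param mu vector of Poisson means (hazard x exposure) on the analysis
#'   rows.
#' @param target desired Pearson dispersion (> 1).
#' @return gamma shape parameter (unit mean, variance `1/shape`).
#' @export
calibrate_frailty_shape <- function(mu, target) {
  if (target <= 1) stopf("overdispersion target must exceed 1")
  m <- mean(mu)
  if (m <= 0) stopf("all Poisson means are zero; cannot calibrate frailty")
  f <- function(a) 1 + m / a - target
  lo <- 1e-6; hi <- 1e9
  if (f(lo) < 0) return(lo)
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  sqrt(lo * hi)
}

# days of a deployment kept after the pipeline-wide reproductive-season
# exclusion, intersected with a tracking window
kept_days <- function(start, end, t_start, t_end) {
  w <- overlap_window(start, end, t_start, t_end)
  if (is.null(w)) return(as.Date(character()))
  d <- seq(w[1], w[2], by = "day")
  d[assign_season(d) != "Excluded"]
}

#' Simulate camera-trap detections from the true utilization densities
#'
#' For each animal x camera pair the capture rate is
#' `lambda = exp(beta_sex) * UD^beta_ud` per day, with `UD` the *true*
#' mixture density at the camera point.  The number of detection events over
#' the pair's exposure (deployment window intersected with the tracking
#' window, reproductive season removed) is Poisson with mean
#' `lambda * T` — multiplied by a unit-mean gamma frailty shared per pair
#' when `overdispersion_target` is set.  Event timestamps are uniform over
#' the exposure days.
#'
#' @param truth list of `animal_truth` from [simulate_population()].
#' @param cameras camera data.frame from [build_camera_grid()].
#' @param config a [sim_config()].
#' @param seed override seed.
#' @return list with `pairs` (one row per animal x camera with positive
#'   exposure: `animal_id`, `camera_id`, `sex`, `ud_true`, `exposure_days`,
#'   `mu`, `count`, `detected`) and `events` (`camera_id`, `animal_id`,
#'   `timestamp` POSIXct UTC), plus the calibrated `frailty_shape` (or NULL).
#' @export
simulate_detections <- function(truth, cameras, config, seed = NULL) {
  set.seed(seed %||% sub_seed(config$seed, 4L))
  day_lists <- lapply(seq_len(nrow(cameras)), function(ci)
    kept_days(cameras$start[ci], cameras$end[ci],
              config$year_start, config$year_start + 364))
  rows <- list(); ri <- 0L
  for (a in truth) {
    ud <- true_ud(a, cameras$x, cameras$y)
    for (ci in seq_len(nrow(cameras))) {
      dl <- day_lists[[ci]]
      dl <- dl[dl >= a$tracking_start & dl <= a$tracking_end]
      T_ac <- length(dl)
      if (T_ac == 0) next
      ri <- ri + 1L
      rows[[ri]] <- list(animal_id = a$animal_id, camera_id =
                           cameras$camera_id[ci], sex = a$sex,
                         ud_true = ud[ci], exposure_days = T_ac,
                         mu = exp(a$detect_intercept) *
                           ud[ci]^config$beta_ud * T_ac,
                         cam_idx = ci)
    }
  }
  pairs <- do.call(rbind, lapply(rows, as.data.frame))
  shape <- NULL
  g <- rep(1, nrow(pairs))
  if (!is.null(config$overdispersion_target)) {
    shape <- calibrate_frailty_shape(pairs$mu, config$overdispersion_target)
    g <- rgamma(nrow(pairs), shape = shape, rate = shape)
  }
  pairs$count <- rpois(nrow(pairs), pairs$mu * g)
  pairs$detected <- as.integer(pairs$count > 0)
  ev <- list(); ei <- 0L
  for (i in which(pairs$count > 0)) {
    dl <- day_lists[[pairs$cam_idx[i]]]
    n_ev <- pairs$count[i]
    if (config$dropout_prob > 0)
      n_ev <- rbinom(1, n_ev, 1 - config$dropout_prob)
    if (n_ev == 0) next
    dts <- dl[sample.int(length(dl), n_ev, replace = TRUE)]
    secs <- runif(n_ev, 0, 86399)
    ei <- ei + 1L
    ev[[ei]] <- data.frame(
      camera_id = pairs$camera_id[i], animal_id = pairs$animal_id[i],
      timestamp = as.POSIXct(dts, tz = "UTC") + secs)
  }
  events <- if (ei > 0) do.call(rbind, ev) else
    data.frame(camera_id = character(), animal_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"))
  events <- events[order(events$camera_id, events$animal_id,
                         events$timestamp), , drop = FALSE]
  rownames(events) <- NULL
  pairs$cam_idx <- NULL
  list(pairs = pairs, events = events, frailty_shape = shape)
}

#' Simulate a complete study (population, telemetry, cameras, detections)
#'
#' @param config a [sim_config()].
#' @param seed override of `config$seed`.
#' @return object of class `camtel_study`: list with `config`, `truth`,
#'   `telemetry`, `cameras`, `detections` (event table), `pairs` (truth-side
#'   animal x camera table) and `frailty_shape`.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(n_females = 4, n_males = 2,
#'                                    extent = c(8000, 8000), seed = 1))
#' head(study$telemetry)
#' }
#' @export
simulate_study <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  truth <- simulate_population(config, seed)
  telemetry <- do.call(rbind, lapply(truth, function(a)
    sample_relocations(a, config = config,
                       seed = sub_seed(seed, 2L, a$index))))
  rownames(telemetry) <- NULL
  cameras <- build_camera_grid(config$extent, config,
                               seed = sub_seed(seed, 3L))
  det <- simulate_detections(truth, cameras, config,
                             seed = sub_seed(seed, 4L))
  structure(list(config = config, truth = truth, telemetry = telemetry,
                 cameras = cameras, detections = det$events,
                 pairs = det$pairs, frailty_shape = det$frailty_shape),
            class = "camtel_study")
}

#' @export
print.camtel_study <- function(x, ...) {
  cat(sprintf(
    "<camtel_study> %d animals, %d relocations, %d cameras, %d detection events\n",
    length(x$truth), nrow(x$telemetry), nrow(x$cameras),
    nrow(x$detections)))
  invisible(x)
}

#' Fast generator of a model-ready encounter table from the true UD
#'
#' Bypasses telemetry and kernel estimation: animal x camera rows are built
#' directly from the true mixture density, truncated to each animal's
#' `truncate`% isopleth (Monte-Carlo threshold), with a fixed per-pair
#' exposure of `config$exposure_days`.  Binary detections then satisfy
#' `Pr(detect) = 1 - exp(-lambda * T)` exactly (frailty off), which makes
#' this the reference path for parameter-recovery experiments.
#'
#' @param config a [sim_config()].
#' @param truncate availability isopleth in percent (default 90); `NULL`
#'   keeps all pairs.
#' @param with_isopleth also compute the true isopleth percentile and core
#'   flag for every row (Monte Carlo; slower).
#' @param n_mc Monte-Carlo draws per animal for thresholds/percentiles.
#' @param seed override of `config$seed`.
#' @return encounter-table data.frame (schema of [build_encounter_table()])
#'   with attributes `truth`, `config` and `frailty_shape`.
#' @export
simulate_encounter_data <- function(config, truncate = 90,
                                    with_isopleth = FALSE, n_mc = 1000,
                                    seed = NULL) {
  seed <- seed %||% config$seed
  truth <- simulate_population(config, seed)
  cameras <- build_camera_grid(config$extent, config,
                               seed = sub_seed(seed, 3L))
  set.seed(sub_seed(seed, 5L))
  rows <- list()
  for (a in truth) {
    ud <- true_ud(a, cameras$x, cameras$y)
    keep <- rep(TRUE, length(ud))
    pct <- rep(NA_integer_, length(ud))
    if (!is.null(truncate) || with_isopleth) {
      pts <- rmixture(n_mc, a)
      dens <- true_ud(a, pts[, 1], pts[, 2])
      if (!is.null(truncate)) {
        thr <- quantile(dens, 1 - truncate / 100, type = 7)
        keep <- ud >= thr
      }
      if (with_isopleth)
        pct <- pmax(1L, as.integer(ceiling(100 * vapply(
          ud, function(d) mean(dens >= d), numeric(1)))))
    }
    if (!any(keep)) next
    rows[[a$animal_id]] <- data.frame(
      animal_id = a$animal_id, camera_id = cameras$camera_id[keep],
      sex = a$sex, season = NA_character_,
      exposure_days = config$exposure_days,
      n_locs_250 = NA_integer_, n_locs_500 = NA_integer_,
      ud = ud[keep], isopleth_pct = pct[keep],
      core = if (with_isopleth) pct[keep] <= 50 else NA,
      mu = exp(a$detect_intercept) * ud[keep]^config$beta_ud *
        config$exposure_days)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  shape <- NULL
  g <- rep(1, nrow(tab))
  if (!is.null(config$overdispersion_target)) {
    shape <- calibrate_frailty_shape(tab$mu, config$overdispersion_target)
    g <- rgamma(nrow(tab), shape = shape, rate = shape)
  }
  tab$photo_count <- rpois(nrow(tab), tab$mu * g)
  tab$detected <- as.integer(tab$photo_count > 0)
  tab$mu <- NULL
  attr(tab, "truth") <- truth
  attr(tab, "config") <- config
  attr(tab, "frailty_shape") <- shape
  tab
}

#' Write / read the study CSV interchange files
#'
#' Writes `telemetry.csv` (`animal_id, sex, date, x, y`), `cameras.csv`
#' (`camera_id, x, y, start, end`), `detections.csv`
#' (`camera_id, animal_id, timestamp`) and `truth.json` (all generator
#' parameters) into `dir`.  Dates are ISO-8601; coordinates are projected
#' metres with no CRS semantics.
#'
#' @param study a `camtel_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_csvs <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(study$telemetry, file.path(dir, "telemetry.csv"),
            row.names = FALSE)
  write.csv(study$cameras, file.path(dir, "cameras.csv"), row.names = FALSE)
  det <- study$detections
  det$timestamp <- format(det$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  truth <- lapply(study$truth, function(a) list(
    animal_id = a$animal_id, sex = a$sex, range_scale = a$range_scale,
    detect_intercept = a$detect_intercept,
    components = lapply(a$components, function(cmp) list(
      mu = cmp$mu, sigma = as.vector(cmp$sigma), w = cmp$w)),
    tracking_start = format(a$tracking_start),
    tracking_end = format(a$tracking_end)))
  cfg <- study$config
  cfg$year_start <- format(cfg$year_start)
  jsonlite::write_json(list(config = unclass(cfg), animals = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_study_csvs
#' @export
read_telemetry_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

#' @rdname write_study_csvs
#' @param path file path of the individual CSV.
#' @export
read_cameras_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$start <- as.Date(d$start); d$end <- as.Date(d$end)
  d
}

#' @rdname write_study_csvs
#' @export
read_detections_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  d
}
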