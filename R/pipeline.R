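## End-to-end analyses: proximity, home-range, cross-analysis summary,
## and parameter-recovery experiments.

drop_unidentifiable <- function(specs, data) {
  ok <- vapply(specs, function(sp) {
    vars <- all.vars(as.formula(paste("~", sp$fixed)))
    for (v in vars) {
      col <- data[[v]]
      if (is.null(col) || all(is.na(col))) return(FALSE)
      if (is.factor(col) && length(unique(na.omit(col))) < 2 &&
          v %in% c("Sex", "Season")) return(FALSE)
    }
    TRUE
  }, logical(1))
  specs[ok]
}

#' Proximity analysis: detection probability vs nearby relocations
#'
#' Fits the candidate binary models relating camera detection to the
#' number of telemetry relocations within `radius` m (NLocs), Sex and
#' Season — main effects plus the Sex x Season, NLocs x Sex and full
#' three-way interactions — with a per-animal random intercept, and ranks
#' them by AICc.  Also returns fixed-effect detection-probability curves
#' against NLocs with 95% Wald confidence bands for the best model.
#'
#' @param enc encounter table built in proximity mode.
#' @param radius 250 or 500.
#' @param link binary link for these models (default logit; configurable).
#' @param random random-intercept terms (default per-animal).
#' @param criterion selection criterion.
#' @param exposure_offset passed to [fit_detection_model()]; defaults off
#'   for the logit link.
#' @return list with `table` (a [selection_table()]), `fits`, `best` (the
#'   top `camtel_fit`) and `curves` (data.frame of predicted detection
#'   probability by NLocs, sex and season).
#' @export
run_proximity_analysis <- function(enc, radius = 250, link = "logit",
                                   random = "Fisher", criterion = "AICc",
                                   exposure_offset = link != "logit") {
  if (!radius %in% c(250, 500)) stopf("radius must be 250 or 500")
  nl <- paste0("NLocs", radius)
  if (all(is.na(enc[[paste0("n_locs_", radius)]])))
    stopf("encounter table was not built in proximity mode (no NLocs)")
  data <- build_model_frame(enc)
  fixed_sets <- c("1", nl,
                  paste("Sex +", nl), paste("Season +", nl),
                  paste("Sex + Season +", nl),
                  paste("Sex * Season +", nl),
                  paste(nl, "* Sex"), paste("Season *", nl),
                  paste("Sex * Season *", nl))
  specs <- lapply(fixed_sets, function(fx)
    model_spec("binary", fx, link = link, random = random))
  specs <- drop_unidentifiable(specs, data)
  if (!length(specs)) stopf("empty candidate list")
  fits <- lapply(specs, fit_detection_model, data = data,
                 exposure_offset = exposure_offset)
  tab <- selection_table(fits, criterion = criterion)
  best <- attr(tab, "fits")[[1]]
  curves <- prediction_curves(best, data, nl)
  list(table = tab, fits = fits, best = best, curves = curves)
}

# fixed-effect detection-probability curves vs NLocs with Wald bands
prediction_curves <- function(fit, data, nl, level = 0.95) {
  grid <- expand.grid(
    NLocs = seq(0, max(data[[nl]], na.rm = TRUE)),
    Sex = levels(droplevels(data$Sex)),
    Season = levels(droplevels(data$Season)),
    stringsAsFactors = FALSE)
  nd <- data.frame(Sex = factor(grid$Sex, levels(data$Sex)),
                   Season = factor(grid$Season, levels(data$Season)))
  nd[[nl]] <- grid$NLocs
  X <- model.matrix(as.formula(paste("~", fit$spec$fixed)), nd)
  beta <- fit$coefficients$estimate
  V <- as.matrix(vcov(fit$model))
  eta <- as.vector(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  zq <- qnorm(1 - (1 - level) / 2)
  inv <- switch(fit$spec$link,
                logit = function(e) 1 / (1 + exp(-e)),
                cloglog = function(e) -expm1(-exp(e)))
  data.frame(sex = grid$Sex, season = grid$Season, nlocs = grid$NLocs,
             prob = inv(eta), lower = inv(eta - zq * se),
             upper = inv(eta + zq * se))
}

homerange_candidates <- function(response, family = NULL) {
  defs <- list(
    list(fixed = "Sex", off = TRUE),
    list(fixed = "1", off = TRUE),
    list(fixed = "Sex * logUD", off = FALSE),
    list(fixed = "Sex + logUD", off = FALSE),
    list(fixed = "Sex * Core", off = TRUE),
    list(fixed = "Sex + Core", off = TRUE),
    list(fixed = "Sex * Isopleth", off = TRUE),
    list(fixed = "Sex + Isopleth", off = TRUE),
    list(fixed = "Isopleth + logUD", off = FALSE),
    list(fixed = "Sex * Isopleth", off = FALSE),
    list(fixed = "Sex + Isopleth", off = FALSE))
  lapply(defs, function(d)
    model_spec(response, d$fixed, offset_log_ud = d$off, family = family))
}

#' Two-stage random-effect selection with saturated fixed effects
#'
#' Stage one of the home-range analysis: the saturated fixed-effects model
#' is fitted as a plain GLM and with each candidate random-intercept
#' structure, and the structures are compared by AIC.  The chosen
#' structure (possibly none) is then used for the fixed-effect
#' comparison.
#'
#' @param data model frame.
#' @param response `"binary"` or `"count"`.
#' @param saturated_fixed fixed-effects string of the saturated model.
#' @param re_candidates random structures to try.
#' @param exposure_offset passed to [fit_detection_model()].
#' @return list with `best_random` (character vector, possibly empty) and
#'   `table` (label / K / AIC / converged).
#' @export
select_random_effects <- function(data, response,
                                  saturated_fixed = "Sex * Isopleth + logUD",
                                  re_candidates = list(
                                    character(), "Fisher", "Camera",
                                    "Fisher/Camera"),
                                  exposure_offset = TRUE) {
  rows <- list(); fits <- list()
  for (re in re_candidates) {
    sp <- model_spec(response, saturated_fixed, random = re,
                     label = if (length(re))
                       paste("saturated |", paste(re, collapse = "+"))
                     else "saturated GLM")
    f <- tryCatch(
      suppressWarnings(fit_detection_model(data, sp,
                                           exposure_offset =
                                             exposure_offset)),
      error = function(e) NULL)
    if (is.null(f)) next
    aic <- information_criteria(f, "AIC")$ic
    rows[[length(rows) + 1L]] <- data.frame(
      label = sp$label, K = f$K, AIC = aic, converged = f$converged)
    fits[[length(fits) + 1L]] <- list(re = re, aic = aic)
  }
  tab <- do.call(rbind, rows)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  list(best_random = best$re, table = tab)
}

#' Home-range analysis: does utilization density predict detections?
#'
#' Fits the predefined candidate sets for the binary (cloglog) and count
#' (log link) responses: the proportional "simple" model
#' `Sex + offset(log(UD))`, free-exponent `log(UD)` models, additive and
#' interactive `Core`/`Isopleth` models, and no-UD models.  Binary models
#' are ranked by AICc; count models by QAICc with the dispersion taken
#' from the saturated quasi-Poisson fit.  Random-effect structures are
#' chosen first with saturated fixed effects ([select_random_effects()]);
#' when a structure beats the GLM, a mixed candidate table (AIC) is also
#' returned.
#'
#' @param enc encounter table built in homerange mode.
#' @param season optional season filter (`"FallWinter"` or `"Summer"`).
#' @param exposure_offset include `offset(log(exposure_days))` (default
#'   TRUE; switch off to mirror designs with equal windows).
#' @param re_candidates random structures for stage one.
#' @return list with elements `binary` (GLM `table`, `re_selection`,
#'   optional `glmm_table`), `count` (`table` = QAICc table, `c_hat`,
#'   `re_selection`, optional `glmm_table`), and `n` (rows analysed).
#' @export
run_homerange_analysis <- function(enc, season = NULL,
                                   exposure_offset = TRUE,
                                   re_candidates = list(
                                     character(), "Fisher", "Camera",
                                     "Fisher/Camera")) {
  if (!is.null(season)) enc <- enc[enc$season == season, ]
  if (any(is.na(enc$ud) | enc$ud <= 0)) {
    n_bad <- sum(is.na(enc$ud) | enc$ud <= 0)
    stopf("%d row(s) with zero/missing utilization density; rebuild the table in homerange mode", n_bad)
  }
  data <- build_model_frame(enc)
  out <- list(n = nrow(data))

  ## binary response -----------------------------------------------------
  b_specs <- drop_unidentifiable(homerange_candidates("binary"), data)
  b_fits <- lapply(b_specs, fit_detection_model, data = data,
                   exposure_offset = exposure_offset)
  b_re <- select_random_effects(data, "binary",
                                re_candidates = re_candidates,
                                exposure_offset = exposure_offset)
  binary <- list(table = selection_table(b_fits, "AICc"),
                 re_selection = b_re)
  if (length(b_re$best_random)) {
    g_specs <- lapply(b_specs, function(sp)
      model_spec("binary", sp$fixed, offset_log_ud = sp$offset_log_ud,
                 random = b_re$best_random))
    g_fits <- lapply(g_specs, function(sp) tryCatch(
      suppressWarnings(fit_detection_model(data, sp,
                                           exposure_offset =
                                             exposure_offset)),
      error = function(e) NULL))
    g_fits <- Filter(Negate(is.null), g_fits)
    if (length(g_fits))
      binary$glmm_table <- selection_table(g_fits, "AIC")
  }
  out$binary <- binary

  ## count response ------------------------------------------------------
  sat <- model_spec("count", "Sex * Isopleth + logUD",
                    family = "quasipoisson", label = "saturated")
  sat_fit <- suppressWarnings(fit_detection_model(data, sat,
                                                  exposure_offset =
                                                    exposure_offset))
  c_hat <- quasi_dispersion(sat_fit)
  c_specs <- drop_unidentifiable(
    homerange_candidates("count", family = "quasipoisson"), data)
  c_fits <- lapply(c_specs, function(sp)
    suppressWarnings(fit_detection_model(data, sp,
                                         exposure_offset =
                                           exposure_offset)))
  c_re <- select_random_effects(data, "count",
                                re_candidates = re_candidates,
                                exposure_offset = exposure_offset)
  count <- list(table = selection_table(c_fits, "QAICc", c_hat = c_hat),
                c_hat = c_hat, re_selection = c_re,
                saturated = sat_fit)
  if (length(c_re$best_random)) {
    g_specs <- lapply(homerange_candidates("count"), function(sp)
      model_spec("count", sp$fixed, offset_log_ud = sp$offset_log_ud,
                 random = c_re$best_random))
    g_specs <- drop_unidentifiable(g_specs, data)
    g_fits <- lapply(g_specs, function(sp) tryCatch(
      suppressWarnings(fit_detection_model(data, sp,
                                           exposure_offset =
                                             exposure_offset)),
      error = function(e) NULL))
    g_fits <- Filter(Negate(is.null), g_fits)
    if (length(g_fits))
      count$glmm_table <- selection_table(g_fits, "AIC")
  }
  out$count <- count
  out
}

#' Relate proximity counts to utilization density at detecting cameras
#'
#' For cameras that detected an animal, bins the rows by utilization-
#' density decile (within sex) and reports the mean number of nearby
#' relocations per bin — the cross-analysis summary connecting the
#' proximity and home-range views.
#'
#' @param enc encounter table with both NLocs and UD columns filled.
#' @param n_bins number of UD quantile bins (default 10 = deciles).
#' @return data.frame with `sex`, `bin`, `mean_ud`, `mean_nlocs250`,
#'   `mean_nlocs500`, `n`.
#' @export
relocations_vs_ud_summary <- function(enc, n_bins = 10) {
  det <- enc[enc$detected == 1 & !is.na(enc$ud), ]
  if (nrow(det) == 0) {
    warnf("no detections: empty cross-analysis summary")
    return(data.frame(sex = character(), bin = integer(),
                      mean_ud = numeric(), mean_nlocs250 = numeric(),
                      mean_nlocs500 = numeric(), n = integer()))
  }
  rows <- list()
  for (s in unique(det$sex)) {
    d <- det[det$sex == s, ]
    qs <- unique(quantile(d$ud, probs = seq(0, 1, length.out =
                                              n_bins + 1)))
    bin <- cut(d$ud, qs, include.lowest = TRUE, labels = FALSE)
    for (b in sort(unique(bin))) {
      sel <- bin == b
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, bin = b, mean_ud = mean(d$ud[sel]),
        mean_nlocs250 = mean(d$n_locs_250[sel]),
        mean_nlocs500 = mean(d$n_locs_500[sel]), n = sum(sel))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare home-range areas between groups (Mann-Whitney U)
#'
#' Rank-sum comparison of home-range areas, e.g. male vs female 95% kernel
#' areas.  `U` counts the pairs in which the first group's value exceeds
#' the second's (so complete separation with smaller first-group values
#' gives `U = 0`).  The exact distribution is used for groups of at most
#' 20 without ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param x,y numeric vectors of areas (hectares) for the two groups.
#' @return list with `U`, `p`, `n1`, `n2`, `method`.
#' @export
compare_home_range_sizes <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both groups need at least one area")
  exact <- max(length(x), length(y)) <= 20 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y), method = wt$method)
}

#' Parameter-recovery experiment for the detection-rate model
#'
#' Replicates the full generative loop — simulate a population and camera
#' grid, build the encounter table, fit the free-exponent and offset
#' (proportional) cloglog models — and aggregates bias, RMSE and Wald-CI
#' coverage for the recovered parameters, plus how often each model wins
#' the AICc comparison.  With `ud_source = "kernel"`, telemetry is
#' simulated and the UD covariate is replaced by a fixed-kernel estimate,
#' quantifying the attenuation that kernel estimation error induces.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates.
#' @param ud_source `"true"` (mixture density at cameras) or `"kernel"`.
#' @param seed experiment seed (replicate substreams derive from it).
#' @param kernel_multiplier bandwidth multiplier for the kernel source.
#' @param level Wald confidence level.
#' @return object of class `recovery_report`: list with `estimates`
#'   (per-parameter truth / mean estimate / bias / RMSE / coverage),
#'   `top_model` frequency table, `n_reps`, `n_failed`, `ud_source`,
#'   `mean_rows`.
#' @export
run_recovery_experiment <- function(config, n_reps = 50,
                                    ud_source = c("true", "kernel"),
                                    seed = config$seed,
                                    kernel_multiplier = 0.8,
                                    level = 0.95) {
  ud_source <- match.arg(ud_source)
  zq <- qnorm(1 - (1 - level) / 2)
  truth_vals <- c(beta_ud = config$beta_ud, beta_f = config$beta_f,
                  sex_diff = config$beta_m - config$beta_f)
  res <- list(); fails <- 0L; rows_used <- numeric(0)
  for (r in seq_len(n_reps)) {
    rep_seed <- sub_seed(seed, 6L, r)
    rec <- tryCatch({
      tab <- simulate_encounter_data(config, truncate = 90,
                                     seed = rep_seed)
      if (ud_source == "kernel")
        tab <- kernel_ud_covariate(tab, config, rep_seed,
                                   kernel_multiplier)
      data <- build_model_frame(tab)
      chk <- offset_consistency_check(data, response = "binary",
                                      fixed = "Sex", level = level)
      est <- setNames(chk$fit_free$coefficients$estimate,
                      chk$fit_free$coefficients$term)
      se <- setNames(chk$fit_free$coefficients$se,
                     chk$fit_free$coefficients$term)
      got <- c(beta_ud = unname(est["logUD"]),
               beta_f = unname(est["(Intercept)"]),
               sex_diff = unname(est["SexM"]))
      ses <- c(beta_ud = unname(se["logUD"]),
               beta_f = unname(se["(Intercept)"]),
               sex_diff = unname(se["SexM"]))
      list(est = got, cover = abs(got - truth_vals) <= zq * ses,
           top = if (chk$aicc_offset <= chk$aicc_free) "offset" else
             "free", n = nrow(data))
    }, error = function(e) NULL)
    if (is.null(rec)) { fails <- fails + 1L; next }
    rows_used <- c(rows_used, rec$n)
    res[[length(res) + 1L]] <- rec
  }
  if (!length(res)) stopf("all replicates failed")
  ests <- do.call(rbind, lapply(res, `[[`, "est"))
  covs <- do.call(rbind, lapply(res, `[[`, "cover"))
  tops <- vapply(res, `[[`, character(1), "top")
  est_tab <- data.frame(
    parameter = colnames(ests), truth = unname(truth_vals),
    mean_estimate = colMeans(ests),
    bias = colMeans(ests) - unname(truth_vals),
    rmse = sqrt(colMeans(sweep(ests, 2, truth_vals)^2)),
    coverage = colMeans(covs))
  rownames(est_tab) <- NULL
  structure(list(estimates = est_tab,
                 top_model = table(tops) / length(tops),
                 n_reps = length(res), n_failed = fails,
                 ud_source = ud_source, mean_rows = mean(rows_used)),
            class = "recovery_report")
}

# replace the true-UD covariate of an encounter table by a fixed-kernel
# estimate from simulated telemetry (same population/camera substreams)
kernel_ud_covariate <- function(tab, config, rep_seed, multiplier) {
  truth <- attr(tab, "truth")
  cams <- build_camera_grid(config$extent, config,
                            seed = sub_seed(rep_seed, 3L))
  cam_xy <- setNames(split(cams[, c("x", "y")], cams$camera_id),
                     cams$camera_id)
  keep <- rep(TRUE, nrow(tab))
  for (a in truth) {
    tel <- sample_relocations(a, config = config,
                              seed = sub_seed(rep_seed, 2L, a$index))
    sel <- select_bandwidth(tel[, c("x", "y")], multipliers = multiplier,
                            criteria = FALSE, animal_id = a$animal_id,
                            period = "Annual")
    rows <- which(tab$animal_id == a$animal_id)
    if (!length(rows)) next
    xs <- cams$x[match(tab$camera_id[rows], cams$camera_id)]
    ys <- cams$y[match(tab$camera_id[rows], cams$camera_id)]
    dens <- ud_at(sel$ud, xs, ys)
    tab$ud[rows] <- dens
    keep[rows] <- dens > 0
  }
  tab[keep, , drop = FALSE]
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> %d replicates (%d failed), UD source: %s, mean rows %.0f\n",
    x$n_reps, x$n_failed, x$ud_source, x$mean_rows))
  print(transform(x$estimates, mean_estimate = round(mean_estimate, 3),
                  bias = round(bias, 3), rmse = round(rmse, 3)),
        row.names = FALSE)
  cat("top model frequencies:\n")
  print(x$top_model)
  invisible(x)
}
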