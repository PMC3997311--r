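## Detection models.  The linear predictor is the log camera-capture rate
##   eta_i = beta_Sex,i + beta_UD * log(UD_i)  (+ further terms),
## so the rate is lambda_i = exp(beta_Sex,i) * UD_i^beta_UD and, for binary
## responses over exposure T, the cloglog link gives
## Pr(detect) = 1 - exp(-lambda_i * T).  Setting beta_UD = 1 (the "simple"
## proportional model) forces 1 * log(UD_i) into the predictor as an offset.

#' Specify a candidate detection model
#'
#' @param response `"binary"` (detection / nondetection) or `"count"`
#'   (photo-count).
#' @param fixed right-hand-side fixed-effects formula as a string, e.g.
#'   `"Sex"`, `"Sex * Isopleth"`, `"Sex + Season + NLocs250"`, or `"1"`.
#'   Available covariates: `Sex`, `Season`, `NLocs250`, `NLocs500`,
#'   `logUD`, `Isopleth` (percentile / 100), `Core` (0/1).
#' @param offset_log_ud force `1 * log(UD)` into the linear predictor (the
#'   proportional-hazard offset).  Incompatible with a free `logUD` term.
#' @param family `"binomial"`, `"quasibinomial"`, `"poisson"` or
#'   `"quasipoisson"`; defaults to the non-quasi family of the response.
#' @param link `"cloglog"` or `"logit"` for binary (default cloglog),
#'   `"log"` for counts.
#' @param random random-intercept terms: subset of
#'   `c("Fisher", "Camera", "Fisher/Camera")`.  Quasi families cannot carry
#'   random terms.
#' @param label table label; defaults to a compact description.
#' @return object of class `model_spec`.
#' @examples
#' model_spec("binary", "Sex", offset_log_ud = TRUE)  # the simple model
#' @export
model_spec <- function(response = c("binary", "count"), fixed = "1",
                       offset_log_ud = FALSE, family = NULL, link = NULL,
                       random = character(), label = NULL) {
  response <- match.arg(response)
  family <- family %||% if (response == "binary") "binomial" else "poisson"
  link <- link %||% if (response == "binary") "cloglog" else "log"
  quasi <- family %in% c("quasibinomial", "quasipoisson")
  if (response == "binary" && !family %in% c("binomial", "quasibinomial"))
    stopf("binary response requires a (quasi)binomial family")
  if (response == "count" && !family %in% c("poisson", "quasipoisson"))
    stopf("count response requires a (quasi)poisson family")
  if (response == "binary" && !link %in% c("cloglog", "logit"))
    stopf("binary link must be cloglog or logit")
  if (response == "count" && link != "log")
    stopf("count models use the log link")
  if (quasi && length(random))
    stopf("quasi-likelihood families cannot carry random effects")
  if (!all(random %in% c("Fisher", "Camera", "Fisher/Camera")))
    stopf("random terms must be among Fisher, Camera, Fisher/Camera")
  if (offset_log_ud && grepl("logUD", fixed))
    stopf("offset(logUD) and a free logUD term are mutually exclusive")
  if (is.null(label)) {
    label <- if (fixed == "1" && !offset_log_ud) "1" else fixed
    if (offset_log_ud) label <- paste0(label, " + offset(logUD)")
    if (length(random))
      label <- paste0(label, " | ", paste(random, collapse = " + "))
    if (quasi) label <- paste0(label, " [", family, "]")
  }
  structure(list(response = response, fixed = fixed,
                 offset_log_ud = offset_log_ud, family = family,
                 link = link, quasi = quasi, random = random,
                 label = label), class = "model_spec")
}

#' Build the modelling frame from an encounter table
#'
#' Maps encounter-table columns to model covariates: `Sex` and `Season`
#' factors (F / FallWinter reference), `NLocs250/500`, `logUD`, `Isopleth`
#' scaled to `[0, 1]`, `Core` coded 0/1, `logT = log(exposure_days)`, and
#' grouping factors `Fisher`, `Camera`.
#'
#' @param enc encounter table from [build_encounter_table()] or
#'   [simulate_encounter_data()].
#' @return data.frame ready for [fit_detection_model()].
#' @export
build_model_frame <- function(enc) {
  data.frame(
    Detected = enc$detected, Count = enc$photo_count,
    Sex = factor(enc$sex, levels = c("F", "M")),
    Season = factor(enc$season, levels = season_levels),
    NLocs250 = enc$n_locs_250, NLocs500 = enc$n_locs_500,
    logUD = log(enc$ud),
    Isopleth = enc$isopleth_pct / 100,
    Core = as.integer(enc$core),
    logT = log(enc$exposure_days),
    Fisher = factor(enc$animal_id), Camera = factor(enc$camera_id))
}

spec_formula <- function(spec, exposure_offset) {
  resp <- if (spec$response == "binary") "Detected" else "Count"
  rhs <- spec$fixed
  if (spec$offset_log_ud) rhs <- paste(rhs, "+ offset(logUD)")
  if (exposure_offset) rhs <- paste(rhs, "+ offset(logT)")
  if (length(spec$random))
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", spec$random),
                            collapse = " + "), sep = " + ")
  as.formula(paste(resp, "~", rhs))
}

base_family <- function(spec) {
  if (spec$response == "binary") binomial(link = spec$link)
  else poisson(link = "log")
}

#' Fit a detection model (GLM or random-intercept GLMM)
#'
#' GLMs are fitted by iteratively reweighted least squares
#' (`stats::glm`, relative deviance tolerance `1e-12`, at most 100
#' iterations); mixed models by `lme4::glmer` (Laplace approximation, or
#' adaptive Gauss-Hermite via `nagq`).  Quasi-likelihood specs are fitted
#' at the base family — point estimates are therefore identical to the
#' non-quasi fit — and carry their Pearson dispersion; reported SEs scale
#' by `sqrt(c_hat)`.
#'
#' @param data model frame from [build_model_frame()].
#' @param spec a [model_spec()].
#' @param exposure_offset include `offset(log(exposure_days))`; default
#'   `TRUE` except for the logit link (where a rate offset has no
#'   interpretation).  Switch off to mirror designs with equal windows.
#' @param nagq number of adaptive Gauss-Hermite quadrature points for
#'   mixed fits with a single grouping factor (1 = Laplace).
#' @return object of class `camtel_fit`: list with `spec`, `model` (the
#'   glm/glmerMod object), `coefficients` (term / estimate / se),
#'   `log_lik`, `K` (estimated parameters: rank of the fixed design plus
#'   one per random-effect variance), `dispersion` (Pearson, quasi fits),
#'   `n`, `converged`, `is_mixed`, `re_variances`.
#' @export
fit_detection_model <- function(data, spec,
                                exposure_offset = spec$link != "logit",
                                nagq = 1L) {
  form <- spec_formula(spec, exposure_offset)
  fam <- base_family(spec)
  if (length(spec$random)) {
    # cloglog PIRLS is fragile with wide-ranging offsets: start the
    # optimizer from the fixed-effects GLM solution and skip the nAGQ0 step
    fixed_spec <- spec; fixed_spec$random <- character()
    beta0 <- coef(glm(spec_formula(fixed_spec, exposure_offset),
                      family = fam, data = data,
                      control = glm.control(epsilon = 1e-12, maxit = 100)))
    n_theta <- sum(vapply(strsplit(spec$random, "/", fixed = TRUE),
                          length, integer(1)))
    ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                               optimizer = "bobyqa",
                               nAGQ0initStep = FALSE)
    fit <- tryCatch(
      suppressMessages(lme4::glmer(
        form, data = data, family = fam, nAGQ = nagq, control = ctrl,
        start = list(fixef = beta0, theta = rep(1, n_theta)))),
      error = function(e) suppressMessages(lme4::glmer(
        form, data = data, family = fam, nAGQ = nagq,
        control = lme4::glmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_var <- setNames(vc$vcov, vc$grp)
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    K <- length(cf) + nrow(vc)
    conv <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0
    boundary <- any(re_var < 1e-8)
    res <- list(spec = spec, model = fit,
                coefficients = data.frame(term = names(cf), estimate =
                                            unname(cf), se = unname(se)),
                log_lik = as.numeric(logLik(fit)), K = K,
                dispersion = NA_real_, n = nrow(data), converged = conv,
                is_mixed = TRUE, re_variances = re_var,
                boundary = boundary, exposure_offset = exposure_offset)
  } else {
    fit <- glm(form, family = fam, data = data,
               control = glm.control(epsilon = 1e-12, maxit = 100))
    if (!fit$converged) warnf("GLM '%s' did not converge", spec$label)
    eta <- fit$linear.predictors
    if (any(abs(eta) > 30))
      warnf("possible separation in '%s': |eta| exceeds 30", spec$label)
    disp <- NA_real_
    sm <- summary(fit, dispersion = 1)
    cf <- sm$coefficients
    se <- cf[, "Std. Error"]
    if (spec$quasi) {
      disp <- sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
      se <- se * sqrt(max(disp, 1))
    }
    res <- list(spec = spec, model = fit,
                coefficients = data.frame(term = rownames(cf),
                                          estimate = unname(cf[, 1]),
                                          se = unname(se)),
                log_lik = as.numeric(logLik(fit)), K = fit$rank,
                dispersion = disp, n = nrow(data),
                converged = fit$converged, is_mixed = FALSE,
                re_variances = numeric(), boundary = FALSE,
                exposure_offset = exposure_offset)
  }
  structure(res, class = "camtel_fit")
}

#' @export
print.camtel_fit <- function(x, ...) {
  cat(sprintf("<camtel_fit> %s (%s, %s)%s\n", x$spec$label, x$spec$family,
              x$spec$link, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("  logLik %.3f, K %d, n %d%s\n", x$log_lik, x$K, x$n,
              if (is.na(x$dispersion)) "" else
                sprintf(", Pearson dispersion %.3f", x$dispersion)))
  invisible(x)
}

#' Pearson overdispersion from a saturated fit
#'
#' `c_hat = Pearson chi-square / residual df` from the most complex
#' (saturated fixed-effects) model, the value fed to QAICc.  Estimates
#' below 1 are reported but floored at 1 when used for QAICc.
#'
#' @param fit a `camtel_fit` (GLM).
#' @return the dispersion estimate (not floored).
#' @export
quasi_dispersion <- function(fit) {
  if (!fit$converged) stopf("dispersion from a non-converged fit")
  df <- df.residual(fit$model)
  if (df <= 0) stopf("zero residual degrees of freedom")
  sum(residuals(fit$model, type = "pearson")^2) / df
}

#' Information criteria (AIC, AICc, QAICc)
#'
#' `AIC = -2 l + 2K`; `AICc = AIC + 2K(K+1)/(n-K-1)`;
#' `QAICc = -2 l / c_hat + 2K + 2K(K+1)/(n-K-1)` where for QAICc the
#' parameter count `K` additionally includes the estimated dispersion.
#' `c_hat` is floored at 1.
#'
#' @param fit a `camtel_fit`, or a list with `log_lik`, `K`, `n`.
#' @param criterion `"AIC"`, `"AICc"` or `"QAICc"`.
#' @param c_hat overdispersion for QAICc.
#' @return list with `ic` and the `K` used.
#' @examples
#' f <- list(log_lik = -47, K = 3, n = 10)  # AIC = 100
#' information_criteria(f, "AICc")$ic        # 104
#' @export
information_criteria <- function(fit, criterion = c("AIC", "AICc",
                                                    "QAICc"), c_hat = 1) {
  criterion <- match.arg(criterion)
  K <- fit$K + (criterion == "QAICc")
  n <- fit$n
  ll <- fit$log_lik
  if (criterion != "AIC" && n <= K + 1)
    stopf("n = %d too small for %s with K = %d%s", n, criterion, K,
          if (!is.null(fit$spec$label)) paste0(" (model '",
                                               fit$spec$label, "')") else "")
  c_hat <- max(c_hat, 1)
  ic <- switch(criterion,
               AIC = -2 * ll + 2 * K,
               AICc = -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1),
               QAICc = -2 * ll / c_hat + 2 * K +
                 2 * K * (K + 1) / (n - K - 1))
  list(ic = ic, K = K)
}

#' Akaike model-selection table
#'
#' Ranks fits by the chosen criterion, with differences, Akaike weights
#' `w_i = exp(-Delta_i/2) / sum exp(-Delta/2)`, cumulative weights, and
#' the Nakagawa-Schielzeth conditional R-squared for mixed fits.  Ties are
#' broken by smaller `K`, then label order.
#'
#' @param fits list of `camtel_fit`s on identical rows and response.
#' @param criterion `"AIC"`, `"AICc"` or `"QAICc"`.
#' @param c_hat dispersion for QAICc (floored at 1).
#' @return object of class `selection_table` (a data.frame with
#'   `model`, `K`, `ic`, `delta`, `weight`, `cum_weight`, `r2c`), with
#'   attributes `criterion` and `c_hat`.
#' @export
selection_table <- function(fits, criterion = "AICc", c_hat = 1) {
  if (!length(fits)) stopf("empty candidate list")
  resp <- unique(vapply(fits, function(f) f$spec$response, character(1)))
  ns <- unique(vapply(fits, function(f) f$n, numeric(1)))
  if (length(resp) > 1) stopf("fits mix response types")
  if (length(ns) > 1) stopf("fits were made on different row sets")
  ics <- lapply(fits, information_criteria, criterion = criterion,
                c_hat = c_hat)
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$label, character(1)),
    K = vapply(ics, `[[`, numeric(1), "K"),
    ic = vapply(ics, `[[`, numeric(1), "ic"),
    r2c = vapply(fits, function(f)
      if (f$is_mixed) conditional_r2(f) else NA_real_, numeric(1)))
  ord <- order(tab$ic, tab$K, tab$model)
  tab <- tab[ord, ]
  tab$delta <- tab$ic - tab$ic[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab$cum_weight <- cumsum(tab$weight)
  tab <- tab[, c("model", "K", "ic", "delta", "weight", "cum_weight",
                 "r2c")]
  rownames(tab) <- NULL
  structure(tab, class = c("selection_table", "data.frame"),
            criterion = criterion, c_hat = c_hat,
            fits = fits[ord])
}

#' @export
print.selection_table <- function(x, digits = 3, ...) {
  cat(sprintf("Model selection (%s%s)\n", attr(x, "criterion"),
              if (attr(x, "criterion") == "QAICc")
                sprintf(", c_hat = %.2f", attr(x, "c_hat")) else ""))
  df <- as.data.frame(x)
  df$ic <- round(df$ic, 2); df$delta <- round(df$delta, 2)
  df$weight <- round(df$weight, digits)
  df$cum_weight <- round(df$cum_weight, digits)
  df$r2c <- round(df$r2c, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Nakagawa-Schielzeth conditional R-squared for a mixed fit
#'
#' `R2c = (var_f + var_r) / (var_f + var_r + var_d)` where `var_f` is the
#' variance of the fixed-effect linear predictor (offsets excluded),
#' `var_r` the summed random-intercept variances, and `var_d` the
#' distribution-specific variance: `pi^2/3` (logit), `pi^2/6` (cloglog),
#' `log(1 + 1/lambda_bar)` (Poisson log link, log-normal approximation
#' with `lambda_bar` the mean fitted count).
#'
#' @param fit a mixed `camtel_fit`.
#' @return conditional R-squared in `[0, 1]`.
#' @export
conditional_r2 <- function(fit) {
  if (!fit$is_mixed) stopf("conditional R2 requires a mixed fit")
  X <- lme4::getME(fit$model, "X")
  beta <- lme4::fixef(fit$model)
  var_f <- var(as.vector(X %*% beta))
  var_r <- sum(fit$re_variances)
  var_d <- switch(fit$spec$link,
                  logit = pi^2 / 3,
                  cloglog = pi^2 / 6,
                  log = log(1 + 1 / mean(fitted(fit$model))))
  (var_f + var_r) / (var_f + var_r + var_d)
}

spec_terms <- function(spec) {
  tl <- attr(stats::terms(as.formula(paste("~", spec$fixed))),
             "term.labels")
  c(tl, if (spec$offset_log_ud) "offset(logUD)")
}

#' Likelihood-ratio test of nested detection models
#'
#' @param nested,full converged `camtel_fit`s on the same rows; the nested
#'   model's terms must be a subset of the full model's.
#' @return list with `statistic` (`2 * (l_full - l_nested)`, floored at
#'   0), `df` (difference in K) and `p` (upper chi-square tail).
#' @export
likelihood_ratio_test <- function(nested, full) {
  if (nested$n != full$n) stopf("fits use different rows")
  t0 <- spec_terms(nested$spec); t1 <- spec_terms(full$spec)
  if (!all(t0 %in% t1) || nested$K > full$K)
    stopf("models are not nested ('%s' vs '%s')", nested$spec$label,
          full$spec$label)
  stat <- max(0, 2 * (full$log_lik - nested$log_lik))
  df <- full$K - nested$K
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

# log-likelihood of a binary/count detection model evaluated at an
# arbitrary coefficient vector (free-exponent design)
manual_log_lik <- function(data, spec, beta, exposure_offset = TRUE) {
  X <- model.matrix(as.formula(paste("~", spec$fixed)), data)
  eta <- as.vector(X %*% beta)
  if (spec$offset_log_ud) eta <- eta + data$logUD
  if (exposure_offset) eta <- eta + data$logT
  if (spec$response == "binary") {
    p <- switch(spec$link,
                cloglog = -expm1(-exp(eta)),
                logit = 1 / (1 + exp(-eta)))
    sum(dbinom(data$Detected, 1, p, log = TRUE))
  } else {
    sum(dpois(data$Count, exp(eta), log = TRUE))
  }
}

#' Check the offset / free-exponent likelihood identity
#'
#' The offset ("simple") model is the free-exponent model constrained to
#' `beta_UD = 1`: its maximized log-likelihood must equal the free model's
#' likelihood function evaluated at the offset fit's coefficients with
#' `beta_UD` set to 1.  Also reports the free exponent estimate with its
#' Wald confidence interval and whether 1 is inside, and the AICc of both
#' models.
#'
#' @param data model frame.
#' @param response `"binary"` or `"count"`.
#' @param fixed shared fixed terms besides `logUD` (default `"Sex"`).
#' @param level Wald confidence level.
#' @param ... passed to [fit_detection_model()].
#' @return list with `identity_gap` (absolute likelihood difference),
#'   `beta_ud`, `ci`, `covers_one`, `aicc_offset`, `aicc_free`, and the
#'   two fits.
#' @export
offset_consistency_check <- function(data, response = "binary",
                                     fixed = "Sex", level = 0.95, ...) {
  off_spec <- model_spec(response, fixed, offset_log_ud = TRUE)
  free_fixed <- paste(fixed, "+ logUD")
  free_spec <- model_spec(response, free_fixed)
  f_off <- fit_detection_model(data, off_spec, ...)
  f_free <- fit_detection_model(data, free_spec, ...)
  if (!f_off$converged || !f_free$converged)
    warnf("offset consistency check on non-converged fits")
  # free-design coefficient vector at the offset solution, beta_UD = 1
  X_free <- model.matrix(as.formula(paste("~", free_fixed)), data)
  beta <- setNames(numeric(ncol(X_free)), colnames(X_free))
  beta[f_off$coefficients$term] <- f_off$coefficients$estimate
  beta["logUD"] <- 1
  eval_spec <- free_spec
  eval_spec$offset_log_ud <- FALSE
  ll_at_one <- manual_log_lik(data, eval_spec, beta,
                              exposure_offset = f_off$exposure_offset)
  i <- match("logUD", f_free$coefficients$term)
  est <- f_free$coefficients$estimate[i]
  se <- f_free$coefficients$se[i]
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- c(est - zq * se, est + zq * se)
  list(identity_gap = abs(ll_at_one - f_off$log_lik),
       beta_ud = est, se = se, ci = ci,
       covers_one = ci[1] <= 1 && 1 <= ci[2],
       aicc_offset = information_criteria(f_off, "AICc")$ic,
       aicc_free = information_criteria(f_free, "AICc")$ic,
       fit_offset = f_off, fit_free = f_free)
}
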