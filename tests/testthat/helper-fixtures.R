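# shared fixtures and independent oracles (built in code, no stored data)

# standardized bivariate sample with exact per-axis SD `s` (so the
# reference-bandwidth closed form is exact)
exact_sd_points <- function(n, s = 1000, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); y <- rnorm(n)
  cbind((x - mean(x)) / sd(x) * s, (y - mean(y)) / sd(y) * s)
}

# small deterministic study used by several encounter tests
tiny_study <- function(seed = 7, n_f = 4, n_m = 2, extent = c(10000, 10000)) {
  cfg <- sim_config(n_females = n_f, n_males = n_m, extent = extent,
                    seed = seed)
  simulate_study(cfg)
}

# model frame generated from the true-UD fast path
tiny_frame <- function(seed = 3, n_f = 6, n_m = 6,
                       extent = c(8000, 6000), beta_ud = 1,
                       with_isopleth = FALSE, ...) {
  cfg <- sim_config(n_females = n_f, n_males = n_m, extent = extent,
                    beta_ud = beta_ud, seed = seed, ...)
  build_model_frame(simulate_encounter_data(cfg, seed = seed,
                                            with_isopleth = with_isopleth))
}

# ---- independent optimizer oracle for GLM likelihoods -------------------
# maximizes the same likelihood as the IRLS fit with BFGS from zero,
# analytic gradients; completely independent of stats::glm internals
optim_glm_oracle <- function(data, fixed, response = "binary",
                             link = "cloglog", offset = NULL) {
  X <- model.matrix(stats::as.formula(paste("~", fixed)), data)
  # centre non-intercept columns for a well-conditioned search, then map
  # the optimum back to the original parameterization
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  X[, -1] <- sweep(X[, -1, drop = FALSE], 2, ctr[-1])
  off <- if (is.null(offset)) rep(0, nrow(X)) else offset
  y <- if (response == "binary") data$Detected else data$Count
  nll <- function(beta) {
    eta <- as.vector(X %*% beta) + off
    if (response == "binary") {
      p <- if (link == "cloglog") -expm1(-exp(eta)) else plogis(eta)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    } else {
      mu <- exp(eta)
      -sum(y * eta - mu)
    }
  }
  grad <- function(beta) {
    eta <- as.vector(X %*% beta) + off
    if (response == "binary") {
      if (link == "cloglog") {
        p <- pmin(pmax(-expm1(-exp(eta)), 1e-12), 1 - 1e-12)
        w <- (y - p) * exp(eta) * exp(-exp(eta)) / (p * (1 - p))
      } else {
        p <- plogis(eta)
        w <- y - p
      }
      -as.vector(crossprod(X, w))
    } else {
      -as.vector(crossprod(X, y - exp(eta)))
    }
  }
  o <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  beta <- o$par
  # Newton polish with a numerical Hessian to push the gradient to ~0
  for (it in 1:20) {
    g <- grad(beta)
    if (max(abs(g)) < 1e-10) break
    H <- stats::optimHess(beta, nll, grad)
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    cand <- beta - step
    if (nll(cand) <= nll(beta)) beta <- cand else break
  }
  beta[1] <- beta[1] - sum(beta[-1] * ctr[-1])
  stats::setNames(beta, colnames(X))
}

# brute-force proximity count (plain loop, independent of the package path)
brute_count_within <- function(tel, cx, cy, radius, window = NULL,
                               season = NULL) {
  n <- 0L
  for (i in seq_len(nrow(tel))) {
    if (!is.null(window) &&
        (tel$date[i] < window[1] || tel$date[i] > window[2])) next
    if (!is.null(season) && assign_season(tel$date[i]) != season) next
    if (sqrt((tel$x[i] - cx)^2 + (tel$y[i] - cy)^2) <= radius) n <- n + 1L
  }
  n
}

# closed-form area (m^2) of the p% region of an isotropic Gaussian
gaussian_iso_area <- function(p, sigma) pi * (-2 * log(1 - p / 100)) * sigma^2

# hand-built two-blob UD object for fragment-count tests
two_blob_ud <- function() {
  gx <- seq(0, 99, by = 1); gy <- seq(0, 49, by = 1)
  z <- outer(gx, gy, function(x, y)
    exp(-((x - 20)^2 + (y - 25)^2) / 50) +
      exp(-((x - 80)^2 + (y - 25)^2) / 50))
  z <- z / sum(z)
  structure(list(x = gx, y = gy, z = z, cell = 1, h = 5, multiplier = 1,
                 n = 100, animal_id = "blob", period = "Annual",
                 bbox = c(xmin = 0, xmax = 99, ymin = 0, ymax = 49)),
            class = "camtel_ud")
}
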