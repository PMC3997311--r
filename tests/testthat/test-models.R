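test_that("model specifications enforce their invariants", {
  expect_error(model_spec("binary", "Sex + logUD", offset_log_ud = TRUE),
               "mutually exclusive")
  expect_error(model_spec("binary", "Sex", family = "quasibinomial",
                          random = "Fisher"), "random")
  expect_error(model_spec("count", "Sex", link = "logit"), "log link")
  expect_error(model_spec("binary", "Sex", family = "poisson"),
               "binomial")
  sp <- model_spec("binary", "Sex", offset_log_ud = TRUE)
  expect_equal(sp$label, "Sex + offset(logUD)")
  expect_equal(sp$link, "cloglog")
})

test_that("Poisson intercept-only fit reproduces log(mean) exactly", {
  d <- data.frame(Count = rpois(200, 3), Detected = 0,
                  Sex = factor("F", c("F", "M")),
                  Season = factor("FallWinter", season_levels),
                  NLocs250 = 0, NLocs500 = 0, logUD = 0, Isopleth = 0.5,
                  Core = 0L, logT = 0,
                  Fisher = factor("a"), Camera = factor("c"))
  f <- fit_detection_model(d, model_spec("count", "1"),
                           exposure_offset = FALSE)
  expect_equal(f$coefficients$estimate, log(mean(d$Count)),
               tolerance = 1e-10)
})

test_that("IRLS solutions match an independent optimizer", {
  mf <- tiny_frame(seed = 12)
  # free-exponent cloglog with exposure offset
  f1 <- fit_detection_model(mf, model_spec("binary", "Sex + logUD"))
  o1 <- optim_glm_oracle(mf, "Sex + logUD", "binary", "cloglog",
                         offset = mf$logT)
  expect_equal(f1$coefficients$estimate, unname(o1), tolerance = 1e-5)
  # Poisson log link
  f2 <- fit_detection_model(mf, model_spec("count", "Sex + logUD"))
  o2 <- optim_glm_oracle(mf, "Sex + logUD", "count", "log",
                         offset = mf$logT)
  expect_equal(f2$coefficients$estimate, unname(o2), tolerance = 1e-5)
})

test_that("free-exponent fits recover the generating coefficients", {
  mf <- tiny_frame(seed = 2, n_f = 15, n_m = 15, extent = c(12000, 9000))
  f <- fit_detection_model(mf, model_spec("binary", "Sex + logUD"))
  est <- setNames(f$coefficients$estimate, f$coefficients$term)
  se <- setNames(f$coefficients$se, f$coefficients$term)
  expect_lt(abs(est["logUD"] - 1), 3 * se["logUD"])
  expect_lt(abs(est["SexM"] - 0.7), 3 * se["SexM"])
})

test_that("quasi fits share point estimates and scale SEs by sqrt(c_hat)", {
  mf <- tiny_frame(seed = 9, overdispersion_target = 2.5)
  sp_p <- model_spec("count", "Sex", offset_log_ud = TRUE)
  sp_q <- model_spec("count", "Sex", offset_log_ud = TRUE,
                     family = "quasipoisson")
  fp <- fit_detection_model(mf, sp_p)
  fq <- fit_detection_model(mf, sp_q)
  expect_equal(fq$coefficients$estimate, fp$coefficients$estimate)
  expect_gt(fq$dispersion, 1)
  expect_equal(fq$coefficients$se,
               fp$coefficients$se * sqrt(fq$dispersion))
  expect_equal(fq$log_lik, fp$log_lik)   # QAICc uses the base likelihood
})

test_that("Pearson dispersion is near 1 for Poisson data and near target with frailty", {
  # moderate-count fixture (higher intercepts): the Pearson estimator is
  # evaluated in the regime it is meant for, not dominated by rows whose
  # expected counts are minuscule
  set.seed(30)
  chats <- replicate(12, {
    mf <- tiny_frame(seed = sample.int(1e6, 1), beta_f = 13.6,
                     beta_m = 14.3)
    quasi_dispersion(fit_detection_model(
      mf, model_spec("count", "Sex * logUD")))
  })
  expect_lt(abs(mean(chats) - 1), 3 * sd(chats) / sqrt(length(chats)))

  set.seed(31)
  chats2 <- replicate(12, {
    mf <- tiny_frame(seed = sample.int(1e6, 1), beta_f = 13.6,
                     beta_m = 14.3, overdispersion_target = 2.5)
    quasi_dispersion(fit_detection_model(
      mf, model_spec("count", "Sex * logUD")))
  })
  expect_equal(mean(chats2), 2.5, tolerance = 0.1)
})

test_that("information criteria follow the stated formulas", {
  f <- list(log_lik = -47, K = 3, n = 10)   # AIC = 100
  expect_equal(information_criteria(f, "AIC")$ic, 100)
  expect_equal(information_criteria(f, "AICc")$ic, 104)
  # AICc -> AIC as n grows
  f_big <- list(log_lik = -47, K = 3, n = 1e6)
  expect_lt(information_criteria(f_big, "AICc")$ic - 100, 1e-4)
  # QAICc at c_hat = 1 equals AICc computed with K+1 parameters, and
  # approaches AICc + 2 as n grows
  fq <- list(log_lik = -47, K = 3, n = 1e4)
  q <- information_criteria(fq, "QAICc", c_hat = 1)
  expect_equal(q$K, 4)
  expect_equal(q$ic,
               information_criteria(list(log_lik = -47, K = 4, n = 1e4),
                                    "AICc")$ic)
  expect_equal(q$ic - information_criteria(fq, "AICc")$ic, 2,
               tolerance = 0.01)
  # c_hat below 1 is floored
  expect_equal(information_criteria(fq, "QAICc", c_hat = 0.5)$ic, q$ic)
  expect_error(information_criteria(list(log_lik = -1, K = 9, n = 10),
                                    "AICc"), "too small")
})

test_that("selection tables rank, weight and normalize correctly", {
  mk <- function(ll, K, lab) structure(
    list(log_lik = ll, K = K, n = 100, is_mixed = FALSE,
         spec = list(label = lab, response = "binary")),
    class = "camtel_fit")
  # two models with Delta = {0, 2}: weights 0.731 / 0.269
  tab <- selection_table(list(mk(-50, 2, "A"), mk(-51, 2, "B")), "AIC")
  expect_equal(tab$delta, c(0, 2))
  expect_equal(tab$weight, c(0.731, 0.269), tolerance = 5e-4)
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$cum_weight[2], 1)
  one <- selection_table(list(mk(-50, 2, "A")), "AIC")
  expect_equal(one$weight, 1)
  bad <- mk(-50, 2, "C"); bad$spec$response <- "count"
  expect_error(selection_table(list(mk(-50, 2, "A"), bad), "AIC"),
               "mix response")
})

test_that("mixed fits recover variances, agree with AGQ, and match GLMs when variance is zero", {
  # logit GLMM, 150 groups of 12, sigma^2 = 1
  set.seed(50)
  ng <- 150; m <- 12
  g <- factor(rep(seq_len(ng), each = m))
  b <- rnorm(ng, 0, 1)
  x <- rnorm(ng * m)
  eta <- -0.3 + 0.8 * x + b[as.integer(g)]
  d <- data.frame(Detected = rbinom(ng * m, 1, plogis(eta)),
                  Count = 0L, Sex = factor("F", c("F", "M")),
                  Season = factor("FallWinter", season_levels),
                  NLocs250 = x, NLocs500 = x, logUD = 0, Isopleth = 0.5,
                  Core = 0L, logT = 0, Fisher = g,
                  Camera = factor(seq_len(ng * m)))
  sp <- model_spec("binary", "NLocs250", link = "logit",
                   random = "Fisher")
  f1 <- fit_detection_model(d, sp, exposure_offset = FALSE)
  expect_true(f1$is_mixed)
  expect_gt(unname(f1$re_variances["Fisher"]), 0.7)
  expect_lt(unname(f1$re_variances["Fisher"]), 1.4)
  expect_equal(f1$K, 3)

  # Laplace vs 9-node adaptive quadrature: the approximations converge as
  # the information per group grows, so compare them on 50 groups of 100
  # binary observations with moderate between-group variance
  set.seed(52)
  ng2 <- 50; m2 <- 100
  g2 <- factor(rep(seq_len(ng2), each = m2))
  x2 <- rnorm(ng2 * m2)
  eta2 <- -0.3 + 0.8 * x2 + rnorm(ng2, 0, 0.5)[as.integer(g2)]
  d2 <- d[seq_len(ng2 * m2), ]
  d2$Detected <- rbinom(ng2 * m2, 1, plogis(eta2))
  d2$NLocs250 <- x2
  d2$Fisher <- g2
  f1b <- fit_detection_model(d2, sp, exposure_offset = FALSE)
  f9b <- fit_detection_model(d2, sp, exposure_offset = FALSE, nagq = 9L)
  expect_lt(abs(f1b$log_lik - f9b$log_lik), 0.1)

  # conditional R2: plug-in truth (var_f + var_r)/(var_f + var_r + pi^2/3)
  r2 <- conditional_r2(f1)
  truth <- (var(0.8 * x) + 1) / (var(0.8 * x) + 1 + pi^2 / 3)
  expect_lt(abs(r2 - truth), 0.05)
  expect_error(conditional_r2(fit_detection_model(
    d, model_spec("binary", "NLocs250", link = "logit"),
    exposure_offset = FALSE)), "mixed")

  # zero-variance data: GLMM collapses onto the GLM
  set.seed(51)
  d0 <- d
  d0$Detected <- rbinom(ng * m, 1, plogis(-0.3 + 0.8 * x))
  f0m <- fit_detection_model(d0, sp, exposure_offset = FALSE)
  f0g <- fit_detection_model(d0, model_spec("binary", "NLocs250",
                                            link = "logit"),
                             exposure_offset = FALSE)
  expect_lt(unname(f0m$re_variances["Fisher"]), 0.02)
  expect_equal(f0m$coefficients$estimate, f0g$coefficients$estimate,
               tolerance = 0.02)
})

test_that("likelihood-ratio tests are zero for identical models and chi-squared under the null", {
  mf <- tiny_frame(seed = 18, with_isopleth = TRUE)
  f_small <- fit_detection_model(mf, model_spec("binary", "Sex",
                                                offset_log_ud = TRUE))
  f_big <- fit_detection_model(mf, model_spec("binary", "Sex + Core",
                                              offset_log_ud = TRUE))
  same <- likelihood_ratio_test(f_small, f_small)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(f_small, f_big)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_error(likelihood_ratio_test(f_big, f_small), "not nested")

  # null distribution: simulate Poisson data with no covariate effect,
  # test the added covariate; statistics should follow chi-squared(1)
  set.seed(60)
  stats <- replicate(300, {
    n <- 120
    d <- data.frame(Count = rpois(n, 2), Detected = 0L,
                    Sex = factor("F", c("F", "M")),
                    Season = factor("FallWinter", season_levels),
                    NLocs250 = rnorm(n), NLocs500 = 0, logUD = 0,
                    Isopleth = 0.5, Core = 0L, logT = 0,
                    Fisher = factor("a"), Camera = factor("c"))
    f0 <- fit_detection_model(d, model_spec("count", "1"),
                              exposure_offset = FALSE)
    f1 <- fit_detection_model(d, model_spec("count", "NLocs250"),
                              exposure_offset = FALSE)
    likelihood_ratio_test(f0, f1)$statistic
  })
  ks <- suppressWarnings(stats::ks.test(stats, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("offset model likelihood equals the free likelihood at exponent 1", {
  for (seed in c(5, 23)) {
    mf <- tiny_frame(seed = seed)
    chk_b <- offset_consistency_check(mf, response = "binary")
    expect_lt(chk_b$identity_gap, 1e-8)
    chk_c <- offset_consistency_check(mf, response = "count")
    expect_lt(chk_c$identity_gap, 1e-8)
  }
})

test_that("the information criteria detect a non-proportional exponent", {
  # truth beta_ud = 2: the free model should beat the offset model
  mf <- tiny_frame(seed = 77, n_f = 20, n_m = 20,
                   extent = c(12000, 9000), beta_ud = 2, beta_f = 29,
                   beta_m = 29.7)
  chk <- offset_consistency_check(mf, response = "binary")
  expect_gt(chk$beta_ud, 1.5)
  expect_gt(chk$aicc_offset, chk$aicc_free)
  expect_false(chk$covers_one)
})
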