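test_that("configuration is validated", {
  expect_error(sim_config(n_females = 0, n_males = 0), "at least one")
  expect_error(sim_config(camera_jitter = 600), "camera_jitter")
  expect_error(sim_config(beta_ud = Inf), "beta_ud")
  expect_error(sim_config(overdispersion_target = 0.8), "exceed 1")
  expect_s3_class(sim_config(n_females = 0, n_males = 1), "sim_config")
})

test_that("population generation is deterministic and respects counts", {
  cfg <- sim_config(n_females = 0, n_males = 1, extent = c(12000, 12000),
                    seed = 5)
  pop <- simulate_population(cfg)
  expect_length(pop, 1)
  expect_equal(pop[[1]]$sex, "M")
  expect_identical(simulate_population(cfg), pop)
  # mixture weights sum to 1, covariances positive definite
  cfg2 <- sim_config(n_females = 5, n_males = 5, seed = 11)
  for (a in simulate_population(cfg2)) {
    w <- vapply(a$components, `[[`, numeric(1), "w")
    expect_equal(sum(w), 1)
    for (cmp in a$components)
      expect_true(all(eigen(cmp$sigma, only.values = TRUE)$values > 0))
  }
  expect_error(
    simulate_population(sim_config(n_females = 1, extent = c(500, 500))),
    "too small")
})

test_that("male home-range areas exceed female areas by the area scale", {
  cfg <- sim_config(n_females = 40, n_males = 40,
                    extent = c(40000, 40000), seed = 19)
  pop <- simulate_population(cfg)
  set.seed(99)
  areas <- vapply(pop, true_isopleth_area, numeric(1), p = 95,
                  n_mc = 4000)
  sex <- vapply(pop, `[[`, character(1), "sex")
  ratio <- mean(areas[sex == "M"]) / mean(areas[sex == "F"])
  # expected ratio is range_scale_male = 3.06 (Monte-Carlo + sampling error)
  expect_gt(ratio, 3.06 * 0.8)
  expect_lt(ratio, 3.06 * 1.25)
  # and the female mean matches the single-Gaussian calibration magnitude
  expect_gt(mean(areas[sex == "F"]) / 1e4, 1000)   # ha
  expect_lt(mean(areas[sex == "F"]) / 1e4, 9000)
})

test_that("relocation sampling has the configured rate, error and moments", {
  cfg <- sim_config(n_females = 1, n_males = 0, relocs_per_week = 7,
                    extent = c(12000, 12000), seed = 2)
  a <- simulate_population(cfg)[[1]]
  one_day <- sample_relocations(
    a, window = c(cfg$year_start, cfg$year_start), config = cfg)
  expect_equal(nrow(one_day), 1)

  # zero telemetry error, single component: empirical covariance converges
  # to the component covariance
  cfg0 <- sim_config(n_females = 1, n_males = 0, telemetry_error_sd = 0,
                     max_components = 1, relocs_per_week = 100,
                     extent = c(12000, 12000), seed = 3)
  a0 <- simulate_population(cfg0)[[1]]
  tel <- sample_relocations(a0, config = cfg0)
  expect_gt(nrow(tel), 4000)
  emp <- cov(cbind(tel$x, tel$y))
  expect_equal(emp, unname(a0$components[[1]]$sigma),
               tolerance = 0.1)

  # telemetry error: mean radial displacement = sd * sqrt(pi/2) = 338.9 m
  cfg_e <- sim_config(n_females = 1, n_males = 0, sigma_female = 1e-3,
                      max_components = 1, relocs_per_week = 150,
                      extent = c(10, 10), camera_cell = 1,
                      camera_jitter = 0, seed = 4)
  a_e <- simulate_population(cfg_e)[[1]]
  tel_e <- sample_relocations(a_e, config = cfg_e)
  centre <- a_e$components[[1]]$mu
  r <- sqrt((tel_e$x - centre[1])^2 + (tel_e$y - centre[2])^2)
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 338.9), 3 * se + 1)
})

test_that("camera grid has exact centres without jitter and bounded spacing with it", {
  cfg0 <- sim_config(camera_jitter = 0, seed = 1)
  cams <- build_camera_grid(c(3000, 3000), cfg0)
  expect_equal(nrow(cams), 9)
  expect_setequal(unique(cams$x), c(500, 1500, 2500))
  dd <- as.matrix(dist(cams[, c("x", "y")])); diag(dd) <- Inf
  expect_equal(min(dd), 1000)
  expect_true(all(cams$end - cams$start + 1 ==
                    cfg0$deployment_length_days))

  cfg_j <- sim_config(camera_jitter = 200,
                      deployment_length_days = 32, seed = 8)
  cams_j <- build_camera_grid(c(5000, 5000), cfg_j)
  dd <- as.matrix(dist(cams_j[, c("x", "y")])); diag(dd) <- Inf
  nn <- apply(dd, 1, min)
  expect_true(all(nn >= 1000 - 2 * 200))
  expect_true(all(nn <= 1400 * sqrt(2)))
  expect_true(all(cams_j$end - cams_j$start + 1 == 32))
  expect_error(build_camera_grid(c(800, 800), cfg0), "no full")
})

test_that("detection counts follow the Poisson rate law and zero-UD rule", {
  # beta_ud = 0 makes every pair's rate exp(beta_f), so lambda*T is known
  lamT <- 0.5
  cfg <- sim_config(n_females = 30, n_males = 0, beta_ud = 0,
                    beta_f = log(lamT / 36), extent = c(10000, 10000),
                    max_components = 1, seed = 21)
  tab <- simulate_encounter_data(cfg, truncate = NULL, seed = 21)
  expect_gt(nrow(tab), 2000)
  p_hat <- mean(tab$detected)
  p_true <- 1 - exp(-lamT)
  se <- sqrt(p_true * (1 - p_true) / nrow(tab))
  expect_lt(abs(p_hat - p_true), 3 * se)
  # Poisson mean law: mean count / (lambda T) near 1
  expect_lt(abs(mean(tab$photo_count) / lamT - 1),
            3 * sd(tab$photo_count) / lamT / sqrt(nrow(tab)))
})

test_that("frailty calibration hits the requested dispersion analytically", {
  mu <- runif(500, 0.01, 2)
  a <- calibrate_frailty_shape(mu, 2.5)
  expect_equal(1 + mean(mu) / a, 2.5, tolerance = 1e-9)
  expect_error(calibrate_frailty_shape(mu, 1), "exceed 1")
})

test_that("no relocation can be claimed by two cameras when the spacing invariant holds", {
  cfg <- sim_config(n_females = 3, n_males = 1, camera_jitter = 0,
                    extent = c(8000, 8000), seed = 13)
  study <- simulate_study(cfg)
  cams <- study$cameras
  tel <- study$telemetry
  # brute force: each relocation within 500 m of at most one camera
  for (i in seq_len(nrow(tel))) {
    d <- sqrt((cams$x - tel$x[i])^2 + (cams$y - tel$y[i])^2)
    expect_lte(sum(d <= 500), 1)
  }
})

test_that("full-study simulation is deterministic and round-trips CSVs", {
  cfg <- sim_config(n_females = 2, n_males = 1, extent = c(8000, 8000),
                    seed = 31)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$telemetry, s2$telemetry)
  expect_identical(s1$cameras, s2$cameras)
  expect_identical(s1$detections, s2$detections)

  dir <- withr::local_tempdir()
  write_study_csvs(s1, dir)
  tel <- read_telemetry_csv(file.path(dir, "telemetry.csv"))
  cams <- read_cameras_csv(file.path(dir, "cameras.csv"))
  det <- read_detections_csv(file.path(dir, "detections.csv"))
  expect_equal(tel$x, s1$telemetry$x, tolerance = 1e-8)
  expect_identical(cams$start, s1$cameras$start)
  expect_equal(nrow(det), nrow(s1$detections))
  expect_s3_class(det$timestamp, "POSIXct")
})
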