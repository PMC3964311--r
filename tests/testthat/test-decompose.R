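# The core statistic: log-scale moments, alpha calibration and the
# intrinsic/extrinsic decomposition.

test_that("log_stats computes unbiased log moments and guards its domain", {
  v <- c(10, 20, 40, 80)
  ev <- tiny_events(4, green = v, red = v)
  st <- log_stats(ev)
  expect_equal(st$var_log_x, stats::var(log(v)))
  expect_equal(st$cov_log, st$var_log_x)       # identical channels
  expect_equal(st$mean_log_x, mean(log(v)))
  expect_equal(st$cv2_x, stats::var(v) / mean(v)^2)
  expect_error(log_stats(tiny_events(1)), "2 events")
  bad <- tiny_events(3, green = c(1, -2, 3), red = c(1, 2, 3))
  expect_error(log_stats(bad), "non-positive")
})

test_that("alpha calibration is the covariance ratio against the fully induced well", {
  sts <- list(fake_stats(0.02), fake_stats(0.01), fake_stats(0.04))
  a <- calibrate_alpha(sts)
  expect_equal(a, c(0.5, 0.25, 1))
  expect_identical(a[3], 1)                    # exactly 1, not within tolerance
  # negative covariance clamps to zero with a warning
  expect_warning(a2 <- calibrate_alpha(list(fake_stats(-0.005),
                                            fake_stats(0.04))),
                 "clamped")
  expect_equal(a2, c(0, 1))
  # undefined when the induced well has non-positive covariance
  expect_error(calibrate_alpha(list(fake_stats(0.02), fake_stats(0))),
               "undefined")
  expect_error(calibrate_alpha(list(fake_stats(0.02), fake_stats(-0.01))),
               "undefined")
})

test_that("decomposition conserves total = extrinsic + intrinsic in both modes", {
  set.seed(41)
  for (mode in c("log", "linear")) {
    for (rep in 1:5) {
      n <- 2000
      ev <- tiny_events(n, green = rlnorm(n, 5, runif(1, 0.05, 0.4)),
                        red = rlnorm(n, 5, runif(1, 0.05, 0.4)))
      bd <- suppressWarnings(decompose_well(log_stats(ev),
                                            alpha = runif(1, 0, 1.5),
                                            mode = mode))
      expect_lt(max(abs(bd$cv2_ext + bd$cv2_int - bd$cv2_total)), 1e-12)
      expect_true(all(bd$cv2_ext >= 0))
    }
  }
})

test_that("pure scenarios decompose into a single component", {
  ev <- make_validation_scenario("pure_extrinsic",
                                 generative_params(sigma_int_x = 0,
                                                   sigma_int_y = 0,
                                                   alpha_true = 1),
                                 20000, seed = 43)
  bd <- decompose_well(log_stats(ev), alpha = 1)
  expect_lt(max(bd$cv2_int / bd$cv2_total), 0.05)

  ev <- make_validation_scenario("pure_intrinsic",
                                 generative_params(sigma_ext = 0),
                                 20000, seed = 44)
  bd <- suppressWarnings(decompose_well(log_stats(ev), alpha = 1))
  expect_lt(max(bd$cv2_ext / bd$cv2_total), 0.05)
})

test_that("mixture components are recovered within bootstrap error", {
  n <- 30000
  wells <- generative_series(alpha_true = 0.7, n = n, seed = 47,
                             sigma_ext = 0.2, sigma_int_x = 0.1,
                             sigma_int_y = 0.14)
  bd <- decompose_series(wells)
  se <- bootstrap_series(wells, B = 60, seed = 48)
  w1x <- bd$well_id == "w1" & bd$reporter == "X"
  w1y <- bd$well_id == "w1" & bd$reporter == "Y"
  truth <- expected_noise_components(
    generative_params(sigma_ext = 0.2, sigma_int_x = 0.1,
                      sigma_int_y = 0.14, alpha_true = 0.7))
  expect_lt(abs(bd$cv2_ext[w1x] - truth$ext_x), 3 * se$se_cv2_ext[w1x])
  expect_lt(abs(bd$cv2_int[w1x] - truth$int_x), 3 * se$se_cv2_int[w1x])
  expect_lt(abs(bd$cv2_int[w1y] - truth$int_y), 3 * se$se_cv2_int[w1y])
  expect_lt(abs(bd$alpha[w1x] - 0.7), 3 * se$se_alpha[w1x])
})

test_that("alpha is recovered across a three-well titration", {
  alphas <- c(0.3, 0.6, 1.0)
  wells <- lapply(seq_along(alphas), function(i)
    make_validation_scenario("mixture",
                             generative_params(alpha_true = alphas[i]),
                             30000, split_seed(53, i),
                             iptg = c(0.1, 1, 25)[i], well_id = paste0("w", i)))
  bd <- decompose_series(wells)
  se <- bootstrap_series(wells, B = 60, seed = 54)
  for (i in 1:2) {
    row <- bd$well_id == paste0("w", i) & bd$reporter == "X"
    expect_lt(abs(bd$alpha[row] - alphas[i]), 3 * se$se_alpha[row])
  }
  expect_identical(unique(bd$alpha[bd$well_id == "w3"]), 1)
})

test_that("the calibration identity pins the constitutive extrinsic component to the induced covariance", {
  wells <- c(generative_series(0.4, 5000, seed = 59),
             list(make_validation_scenario("mixture",
                                           generative_params(alpha_true = 0.8),
                                           5000, split_seed(59, 9),
                                           iptg = 5, well_id = "w3")))
  bd <- decompose_series(wells)
  sts <- attr(bd, "log_stats")
  cov_n <- sts[["r1:w2"]]$cov_log
  exty <- bd$cv2_ext[bd$reporter == "Y"]
  expect_identical(exty, rep(cov_n, length(exty)))
})

test_that("log-mode decomposition matches the classical raw-moment estimators for identical reporters", {
  gen <- generative_params(sigma_ext = 0.1, sigma_int_x = 0.1,
                           sigma_int_y = 0.1, alpha_true = 1)
  ev <- make_validation_scenario("mixture", gen, 100000, seed = 61)
  lg <- decompose_well(log_stats(ev), alpha = 1)
  cl <- elowitz_decompose(ev)
  expect_lt(abs(lg$cv2_ext[1] - cl$ext) / cl$ext, 0.1)
  expect_lt(abs(lg$cv2_int[1] - cl$int) / cl$int, 0.1)
})

test_that("classical estimator degenerates correctly", {
  v <- rlnorm(1000, 5, 0.2)
  same <- tiny_events(1000, green = v, red = v)
  expect_equal(elowitz_decompose(same)$int, 0)
  set.seed(67)
  ind <- tiny_events(50000, green = rlnorm(50000, 5, 0.1),
                     red = rlnorm(50000, 5, 0.1))
  cl <- elowitz_decompose(ind)
  expect_lt(abs(cl$ext), 3 * 0.1^2 / sqrt(50000) * 2)
})

test_that("a series of identical wells gives identical breakdowns with alpha 1", {
  base <- make_validation_scenario("mixture", generative_params(),
                                   5000, seed = 71, iptg = 1, well_id = "wA")
  copy <- base
  copy$iptg_uM <- 5
  copy$well_id <- "wB"
  bd <- decompose_series(list(base, event_table(copy)))
  expect_true(all(bd$alpha == 1))
  for (col in c("cv2_total", "cv2_ext", "cv2_int"))
    expect_equal(bd[[col]][bd$well_id == "wA"],
                 bd[[col]][bd$well_id == "wB"])
  # duplicated inducer levels are rejected
  dup <- base
  dup$well_id <- "wC"
  expect_error(decompose_series(list(base, event_table(dup))), "duplicated")
})

test_that("replicate aggregation is the across-replicate mean and s.d.", {
  wells <- unlist(lapply(c("r1", "r2"), function(r)
    generative_series(0.5, 2000, seed = if (r == "r1") 73 else 74,
                      replicate = r)), recursive = FALSE)
  bd <- decompose_series(wells)
  agg <- aggregate_replicates(bd)
  expect_equal(nrow(agg), 4)  # 2 wells x 2 reporters
  expect_true(all(agg$n_replicates == 2))
  one <- bd[bd$iptg_uM == 1 & bd$reporter == "X", "cv2_total"]
  expect_equal(agg$cv2_total_mean[agg$iptg_uM == 1 & agg$reporter == "X"],
               mean(one))
  expect_equal(agg$cv2_total_sd[agg$iptg_uM == 1 & agg$reporter == "X"],
               stats::sd(one))
  # hand arithmetic: components 0.1 and 0.3 -> mean 0.2, s.d. sqrt(0.02)
  fake <- bd[bd$reporter == "X" & bd$iptg_uM == 1, ]
  fake$cv2_total <- c(0.1, 0.3)
  fake2 <- fake; fake2$iptg_uM <- 25
  agg2 <- aggregate_replicates(rbind(fake, fake2))
  expect_equal(agg2$cv2_total_mean[1], 0.2)
  expect_equal(agg2$cv2_total_sd[1], sqrt(0.02), tolerance = 1e-12)
  # identical replicates have zero spread
  same <- rbind(fake, fake)
  same$replicate <- c("r1", "r2", "r1", "r2")
  same$cv2_total <- 0.25
  expect_equal(unique(aggregate_replicates(same)$cv2_total_sd), 0)
  # mismatched well sets across replicates are an error
  expect_error(aggregate_replicates(bd[-1, ]), "different well sets")
  expect_error(aggregate_replicates(bd[bd$replicate == "r1", ]),
               "2 replicates")
})

test_that("linear mode agrees with log mode to first order in small noise", {
  wells <- generative_series(0.7, 50000, seed = 79, sigma_ext = 0.1,
                             sigma_int_x = 0.1, sigma_int_y = 0.1)
  lg <- decompose_series(wells, mode = "log")
  ln <- decompose_series(wells, mode = "linear")
  keep <- lg$cv2_ext > 1e-4
  expect_lt(max(abs(ln$cv2_ext[keep] / lg$cv2_ext[keep] - 1)), 0.1)
  expect_lt(max(abs(ln$cv2_total / lg$cv2_total - 1)), 0.1)
})
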