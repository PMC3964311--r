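# Circuit simulator: fixed point, dose response, population draws and the
# generative validation scenarios.

hill_A <- function(dox, K, h) 1 / (1 + (K / dox)^h)

test_that("negative-feedback steady state matches the closed-form quadratic root when laci_h = 1", {
  # with Hill coefficient 1 and f = 1 (no IPTG) the fixed point solves
  # L^2/K + L - U = 0, whose positive root is (-K + sqrt(K^2 + 4KU))/2
  p <- circuit_params("negative_feedback", laci_K = 50, laci_h = 1,
                      v_green = 400, dox_K = 1000, dox_h = 2)
  cond <- well_condition(iptg = 0, dox = 5000)
  A <- hill_A(5000, 1000, 2)
  for (e in c(0.5, 1, 2)) {
    for (i in c(0.8, 1.3)) {
      U <- 1 * 400 * A * e * i
      expected <- (-50 + sqrt(50^2 + 4 * 50 * U)) / 2
      got <- steady_state_laci(p, cond, ext_factor = e, int_factor = i)
      expect_lt(abs(got - expected) / expected, 1e-10)
    }
  }
})

test_that("feedback steady state reduces to the unrepressed closed form in the no-repression limits", {
  A <- hill_A(5000, 1000, 2)
  unrepressed <- 1 * 400 * A
  # IPTG -> infinity: active LacI fraction vanishes
  p <- circuit_params("negative_feedback", v_green = 400)
  far <- steady_state_laci(p, well_condition(iptg = 1e9, dox = 5000))
  expect_lt(abs(far - unrepressed) / unrepressed, 1e-6)
  # laci_K -> infinity: repression term vanishes at any IPTG
  p2 <- circuit_params("negative_feedback", v_green = 400, laci_K = 1e12)
  weak <- steady_state_laci(p2, well_condition(iptg = 0, dox = 5000))
  expect_lt(abs(weak - unrepressed) / unrepressed, 1e-6)
  # simple regulation is the closed form exactly
  p3 <- circuit_params("simple_regulation", v_green = 400, copy_number = 2)
  expect_equal(steady_state_laci(p3, well_condition(iptg = 0, dox = 5000)),
               2 * 400 * A, tolerance = 1e-12)
})

test_that("steady_state_laci rejects non-positive noise factors", {
  p <- circuit_params("negative_feedback")
  cond <- well_condition(iptg = 1, dox = 5000)
  expect_error(steady_state_laci(p, cond, ext_factor = 0), "positive")
  expect_error(steady_state_laci(p, cond, int_factor = -1), "positive")
})

test_that("with every noise source off the population equals the deterministic dose response", {
  for (arch in c("negative_feedback", "simple_regulation")) {
    p <- circuit_params(arch, sigma_ext = 0, sigma_int_green = 0,
                        sigma_int_red = 0, int_abund = 0,
                        bg_sd_green = 0, bg_sd_red = 0)
    cond <- well_condition(iptg = 1, dox = 5000)
    ev <- simulate_population(p, cond, 50, seed = 7)
    m <- mean_dose_response(p, cond)
    expect_equal(ev$green, rep(m[["green"]] + p$bg_mean_green, 50))
    expect_equal(ev$red, rep(m[["red"]] + p$bg_mean_red, 50))
    # CV after background subtraction is 0
    expect_equal(stats::sd(ev$green - p$bg_mean_green), 0)
  }
})

test_that("simulate_population is deterministic in the seed and leaves the caller RNG alone", {
  p <- circuit_params("negative_feedback")
  cond <- well_condition(iptg = 1, dox = 5000)
  set.seed(99)
  before <- .Random.seed
  a <- simulate_population(p, cond, 500, seed = 11)
  expect_identical(.Random.seed, before)
  b <- simulate_population(p, cond, 500, seed = 11)
  expect_identical(a, b)
  c <- simulate_population(p, cond, 500, seed = 12)
  expect_false(identical(a$green, c$green))
})

test_that("deterministic dose response is monotone in IPTG for the regulated channel and flat for the constitutive one", {
  grid <- exp(seq(log(0.0625), log(25), length.out = 9))
  for (arch in c("negative_feedback", "simple_regulation")) {
    p <- circuit_params(arch)
    m <- sapply(grid, function(ig)
      mean_dose_response(p, well_condition(iptg = ig, dox = 5000)))
    reg <- regulated_channel(arch)
    con <- constitutive_channel(arch)
    expect_true(all(diff(m[reg, ]) > 0))
    expect_equal(diff(range(m[con, ])), 0)
  }
})

test_that("simulated population means follow the dose-response ordering", {
  grid <- c(0.0625, 0.5, 3, 25)
  p <- circuit_params("negative_feedback")
  means <- sapply(seq_along(grid), function(k) {
    ev <- simulate_population(p, well_condition(iptg = grid[k], dox = 5000),
                              20000, seed = split_seed(31, k))
    c(green = mean(ev$green), red = mean(ev$red),
      se_red = stats::sd(ev$red) / sqrt(nrow(ev)))
  })
  # regulated channel strictly increasing across well means
  expect_true(all(diff(means["green", ]) > 0))
  # constitutive channel invariant within sampling error
  dred <- abs(means["red", 4] - means["red", 1])
  expect_lt(dred, 4 * sqrt(means["se_red", 1]^2 + means["se_red", 4]^2))
})

test_that("validation scenarios reproduce their defining correlation structure", {
  # perfectly correlated reporters when one shared factor drives both
  ev <- make_validation_scenario("pure_extrinsic",
                                 generative_params(sigma_int_x = 0,
                                                   sigma_int_y = 0,
                                                   alpha_true = 1),
                                 20000, seed = 5)
  expect_gt(stats::cor(log(ev$green), log(ev$red)), 0.9999)

  # independent variation: |cov| below 3 standard errors
  ev <- make_validation_scenario("pure_intrinsic",
                                 generative_params(sigma_ext = 0),
                                 100000, seed = 6)
  lg <- log(ev$green); lr <- log(ev$red)
  se <- sqrt(stats::var(lg) * stats::var(lr) / length(lg))
  expect_lt(abs(stats::cov(lg, lr)), 3 * se)

  # mixture: cov(log X, log Y) = alpha_true * sigma_ext^2 = 0.7 * 0.04
  gen <- generative_params(sigma_ext = 0.2, sigma_int_x = 0.1,
                           sigma_int_y = 0.14, alpha_true = 0.7)
  ev <- make_validation_scenario("mixture", gen, 100000, seed = 7)
  lg <- log(ev$green); lr <- log(ev$red)
  cv <- stats::cov(lg, lr)
  se <- sqrt((stats::var(lg) * stats::var(lr) + cv^2) / length(lg))
  expect_lt(abs(cv - 0.7 * 0.04), 3 * se)
})

test_that("scenario kinds enforce their parameter constraints", {
  expect_error(make_validation_scenario("pure_extrinsic",
                                        generative_params(sigma_int_x = 0.1,
                                                          sigma_int_y = 0),
                                        10, 1),
               "sigma_int")
  expect_error(make_validation_scenario("pure_intrinsic",
                                        generative_params(sigma_ext = 0.2),
                                        10, 1),
               "sigma_ext")
})

test_that("expected_noise_components is the generative arithmetic", {
  gen <- generative_params(sigma_ext = 0.2, sigma_int_x = 0.1,
                           sigma_int_y = 0.14, alpha_true = 0.7)
  comp <- expected_noise_components(gen)
  expect_equal(comp$ext_x, 0.0196)
  expect_equal(comp$ext_y, 0.04)
  expect_equal(comp$int_x, 0.01)
  expect_equal(comp$int_y, 0.0196)
  # no extrinsic component without an extrinsic source
  z <- expected_noise_components(generative_params(sigma_ext = 0))
  expect_equal(z$ext_x, 0)
  expect_equal(z$ext_y, 0)
  # identical sensitivity means identical extrinsic components
  one <- expected_noise_components(generative_params(alpha_true = 1))
  expect_equal(one$ext_x, one$ext_y)
})

test_that("split_seed stays in the 32-bit range and is deterministic", {
  s <- split_seed(2147483646, 10000)
  expect_true(is.integer(s) && s >= 0 && s < 2147483647)
  expect_identical(split_seed(5, 3), split_seed(5, 3))
  expect_false(split_seed(5, 3) == split_seed(5, 4))
})
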