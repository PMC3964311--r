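# Shared fixture builders. All synthetic data is generated in code with
# fixed seeds; no binary fixtures.

# A minimal valid event table built by hand.
tiny_events <- function(n = 3, green = NULL, red = NULL, well_id = "w1",
                        iptg = 1, dox = 5000, replicate = "r1",
                        fsc = NULL, ssc = NULL) {
  if (is.null(green)) green <- seq(100, 100 + n - 1)
  if (is.null(red)) red <- seq(200, 200 + n - 1)
  if (is.null(fsc)) fsc <- rep(5e4, n)
  if (is.null(ssc)) ssc <- rep(4e4, n)
  event_table(data.frame(well_id = well_id, iptg_uM = iptg,
                         dox_ng_ml = dox, replicate = replicate,
                         fsc = fsc, ssc = ssc, green = green, red = red,
                         stringsAsFactors = FALSE))
}

# Event table from raw channel vectors (noise in fluorescence only).
events_from_channels <- function(green, red, seed = 1, ...) {
  n <- length(green)
  set.seed(seed)
  tiny_events(n, green = green, red = red,
              fsc = 5e4 * exp(0.25 * stats::rnorm(n)),
              ssc = 5e4 * exp(0.25 * stats::rnorm(n)), ...)
}

# Fake log_stats object with a prescribed covariance (for calibration
# algebra tests that need no events).
fake_stats <- function(cov_log, var_x = 0.05, var_y = 0.05) {
  structure(list(mean_log_x = 5, mean_log_y = 5,
                 var_log_x = var_x, var_log_y = var_y, cov_log = cov_log,
                 n_events = 1000L, mean_x = 150, mean_y = 150,
                 cv2_x = var_x, cv2_y = var_y,
                 x_channel = "green", y_channel = "red"),
            class = "log_stats")
}

# Two-well generative titration: well 1 with alpha_true, well 2 fully
# induced (alpha = 1). Used for calibration/recovery checks.
generative_series <- function(alpha_true, n, seed,
                              sigma_ext = 0.2, sigma_int_x = 0.1,
                              sigma_int_y = 0.14, replicate = "r1") {
  alphas <- c(alpha_true, 1)
  iptg <- c(1, 25)
  lapply(seq_along(alphas), function(i) {
    make_validation_scenario(
      "mixture",
      generative_params(sigma_ext = sigma_ext, sigma_int_x = sigma_int_x,
                        sigma_int_y = sigma_int_y, alpha_true = alphas[i]),
      n, split_seed(seed, i), iptg = iptg[i], dox = 5000,
      replicate = replicate, well_id = paste0("w", i))
  })
}
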