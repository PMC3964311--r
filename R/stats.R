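# Per-well moment statistics and the alpha-calibrated noise decomposition.
#
# Model: reporter fluctuations are products of a shared extrinsic random
# variable and gene-specific intrinsic random variables. Taking logs turns
# the products into sums, so on the log scale the extrinsic noise of two
# constitutive reporters is their covariance and the intrinsic noise is the
# reporter's variance minus that covariance. When reporter X is regulated,
# its sensitivity to the shared extrinsic variable is a coefficient alpha
# (1 for two identically behaving constitutive reporters), calibrated per
# titration so that the constitutive reporter's extrinsic noise matches the
# fully induced well.

#' Log-scale sample moments of a two-reporter event table
#'
#' Unbiased (n-1) moments of the natural-log intensities, plus the linear
#' means and raw CV^2 needed for the linear-scale decomposition mode.
#'
#' @param events an [event_table()] with strictly positive intensities in
#'   both analysis channels (filter with [drop_nonpositive()] first).
#' @param x_channel,y_channel channels holding the regulated reporter X and
#'   the constitutive reporter Y.
#' @return An object of class `log_stats`: `mean_log_x`, `mean_log_y`,
#'   `var_log_x`, `var_log_y`, `cov_log`, `n_events`, and the raw-scale
#'   `mean_x`, `mean_y`, `cv2_x`, `cv2_y`.
#' @export
log_stats <- function(events, x_channel = "green", y_channel = "red") {
  x <- events[[x_channel]]
  y <- events[[y_channel]]
  if (length(x) < 2L)
    stop("log_stats: need at least 2 events", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("log_stats: non-positive intensities present; filter with ",
         "drop_nonpositive() before computing log statistics", call. = FALSE)
  lx <- log(x)
  ly <- log(y)
  structure(list(mean_log_x = mean(lx), mean_log_y = mean(ly),
                 var_log_x = stats::var(lx), var_log_y = stats::var(ly),
                 cov_log = stats::cov(lx, ly),
                 n_events = length(x),
                 mean_x = mean(x), mean_y = mean(y),
                 cv2_x = stats::var(x) / mean(x)^2,
                 cv2_y = stats::var(y) / mean(y)^2,
                 x_channel = x_channel, y_channel = y_channel),
            class = "log_stats")
}

#' @export
print.log_stats <- function(x, ...) {
  cat(sprintf("Log statistics (%d events)\n", x$n_events))
  cat(sprintf("  X (%s): mean log %.4f, var log %.5f (raw CV^2 %.5f)\n",
              x$x_channel, x$mean_log_x, x$var_log_x, x$cv2_x))
  cat(sprintf("  Y (%s): mean log %.4f, var log %.5f (raw CV^2 %.5f)\n",
              x$y_channel, x$mean_log_y, x$var_log_y, x$cv2_y))
  cat(sprintf("  cov log = %.5f\n", x$cov_log))
  invisible(x)
}

#' Calibrate the regulated reporter's extrinsic sensitivity
#'
#' For a titration indexed `i = 1..N` with well `N` fully induced, the
#' sensitivity coefficient is `alpha_i = cov_log(i) / cov_log(N)`. This is
#' the unique choice for which the constitutive reporter's extrinsic noise
#' `cov_log(i) / alpha_i` equals its value in the fully induced well for
#' every `i`; at well `N` it gives `alpha_N = 1` exactly.
#'
#' @param stats_list list of [log_stats()] objects, one per well, in
#'   titration order.
#' @param induced index of the fully induced well (default: the last).
#' @return Numeric vector of sensitivities, one per well. Wells with a
#'   negative sample covariance are clamped to `alpha = 0` with a warning
#'   (extrinsic variance cannot be negative, but finite-sample covariances
#'   can be).
#' @export
calibrate_alpha <- function(stats_list, induced = length(stats_list)) {
  covs <- vapply(stats_list, function(s) s$cov_log, numeric(1))
  if (induced < 1L || induced > length(covs))
    stop("calibrate_alpha: 'induced' is out of range", call. = FALSE)
  cov_n <- covs[induced]
  if (!is.finite(cov_n) || cov_n <= 0)
    stop("calibrate_alpha: calibration undefined; the fully induced well ",
         "has non-positive log-covariance (", format(cov_n), ")",
         call. = FALSE)
  alpha <- covs / cov_n
  neg <- alpha < 0
  if (any(neg)) {
    warning("calibrate_alpha: ", sum(neg), " well(s) with negative ",
            "log-covariance; alpha clamped to 0", call. = FALSE)
    alpha[neg] <- 0
  }
  alpha
}

#' Decompose one well's noise into extrinsic and intrinsic components
#'
#' In the default log mode the total noise of a reporter is the variance of
#' its log intensity; the regulated reporter's extrinsic component is
#' `alpha * cov_log` and the constitutive reporter's is `cov_log / alpha`
#' (equal to the fully induced covariance when `alpha` comes from
#' [calibrate_alpha()]; supplied directly via `ext_y` by
#' [decompose_series()] so the identity is exact). Intrinsic noise is the
#' difference between the total and the extrinsic component. In linear mode
#' the total is the raw CV^2 and the extrinsic components are
#' `exp(alpha * cov_log) - 1` and `exp(cov_log / alpha) - 1`; the two modes
#' agree to first order in the small-noise limit. With `alpha = 0` both
#' extrinsic components are 0. Extrinsic components are clamped into
#' `[0, total]` so that `total = extrinsic + intrinsic` holds exactly.
#'
#' @param stats a [log_stats()] object.
#' @param alpha sensitivity coefficient (>= 0) for the well.
#' @param mode `"log"` or `"linear"`.
#' @param ext_y optional value for the constitutive reporter's extrinsic
#'   component on the log scale (the calibration identity's
#'   `cov_log(N)`); default `cov_log / alpha`.
#' @return Data frame with one row per reporter (`"X"`, `"Y"`) and columns
#'   `alpha`, `cv2_total`, `cv2_ext`, `cv2_int`, `mean`, `n_events`.
#' @export
decompose_well <- function(stats, alpha, mode = c("log", "linear"),
                           ext_y = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(stats, "log_stats"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("decompose_well: 'alpha' must be a single non-negative number",
         call. = FALSE)
  cov_l <- stats$cov_log
  ext_x_log <- if (alpha > 0) alpha * cov_l else 0
  ext_y_log <- if (alpha > 0) {
    if (is.null(ext_y)) cov_l / alpha else ext_y
  } else 0
  if (mode == "log") {
    tot <- c(stats$var_log_x, stats$var_log_y)
    ext <- c(ext_x_log, ext_y_log)
  } else {
    tot <- c(stats$cv2_x, stats$cv2_y)
    ext <- c(if (ext_x_log != 0) exp(ext_x_log) - 1 else 0,
             if (ext_y_log != 0) exp(ext_y_log) - 1 else 0)
  }
  clamped <- ext > tot
  if (any(clamped))
    warning("decompose_well: extrinsic component exceeded the total for ",
            "reporter ", paste(c("X", "Y")[clamped], collapse = ", "),
            "; clamped to the total", call. = FALSE)
  ext <- pmin(pmax(ext, 0), tot)
  data.frame(reporter = c("X", "Y"),
             alpha = alpha,
             cv2_total = tot,
             cv2_ext = ext,
             cv2_int = tot - ext,
             mean = c(stats$mean_x, stats$mean_y),
             n_events = stats$n_events,
             stringsAsFactors = FALSE)
}

#' Classical two-reporter decomposition on the raw scale
#'
#' The standard raw-moment estimators for two identically regulated
#' reporters: extrinsic noise `(<xy> - <x><y>) / (<x><y>)` and intrinsic
#' noise `<(x - y)^2> / (2 <x><y>)`. Serves as the independent alpha = 1
#' oracle for the log-scale decomposition in the small-noise regime.
#'
#' @param events an [event_table()] with positive intensities.
#' @param x_channel,y_channel reporter channels.
#' @return Named list with `ext` and `int` (raw CV^2 scale).
#' @export
elowitz_decompose <- function(events, x_channel = "green",
                              y_channel = "red") {
  x <- events[[x_channel]]
  y <- events[[y_channel]]
  if (length(x) < 2L)
    stop("elowitz_decompose: need at least 2 events", call. = FALSE)
  mx <- mean(x)
  my <- mean(y)
  if (mx == 0 || my == 0)
    stop("elowitz_decompose: zero channel mean", call. = FALSE)
  list(ext = (mean(x * y) - mx * my) / (mx * my),
       int = mean((x - y)^2) / (2 * mx * my))
}
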