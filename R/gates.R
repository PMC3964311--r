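# Gating and trimming rules applied to event tables before any statistics.
# The chain is fixed: scatter gate -> positive gate -> s.d. trim, with an
# optional background floor for the low-expression regime.

#' Positive gate against an uninduced control
#'
#' Retains events whose constitutive-channel intensity exceeds the threshold
#' of negative cells, defined as a high quantile (default 0.995) of the
#' uninduced control population in the same channel.
#'
#' @param events an [event_table()] of induced sample events.
#' @param uninduced_control an [event_table()] measured without induction.
#' @param channel constitutive channel to gate on (`"red"` for the
#'   negative-feedback clone, `"green"` for simple regulation; see
#'   [constitutive_channel()]).
#' @param quantile control quantile defining the threshold, in (0, 1).
#' @return The gated table; see [gate_report()].
#' @export
gate_positive <- function(events, uninduced_control, channel,
                          quantile = 0.995) {
  stopifnot(inherits(events, "event_table"),
            inherits(uninduced_control, "event_table"))
  if (!nrow(uninduced_control))
    stop("gate_positive: empty uninduced control", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("gate_positive: 'quantile' must lie in (0, 1)", call. = FALSE)
  thr <- stats::quantile(uninduced_control[[channel]], quantile,
                         names = FALSE, type = 7)
  keep <- events[[channel]] > thr
  if (!any(keep))
    stop("gate_positive: no events above the negative-cell threshold (",
         format(thr), "); induction appears to have failed", call. = FALSE)
  add_gate_step(subset_events(events, keep), paste0("positive_", channel),
                nrow(events), sum(keep), thr)
}

#' Trim outlier events around the population mean
#'
#' Retains events whose intensity lies within `mean +/- k * sd` on the
#' linear scale, computed once per fluorescence channel on the input table;
#' an event must pass in every trimmed channel. With constant intensity
#' (s.d. 0) the band collapses to the mean and equal values pass.
#'
#' @param events an [event_table()].
#' @param k band half-width in standard deviations (> 0, default 2.5;
#'   `Inf` is the identity).
#' @param channels channels trimmed jointly.
#' @return The trimmed table; see [gate_report()].
#' @export
trim_outliers <- function(events, k = 2.5, channels = c("green", "red")) {
  stopifnot(inherits(events, "event_table"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop("trim_outliers: 'k' must be a single positive number", call. = FALSE)
  if (nrow(events) < 2L)
    stop("trim_outliers: need at least 2 events", call. = FALSE)
  if (!is.finite(k))
    return(add_gate_step(events, "trim_sd", nrow(events), nrow(events), Inf))
  keep <- rep(TRUE, nrow(events))
  for (ch in channels) {
    v <- events[[ch]]
    m <- mean(v)
    s <- stats::sd(v)
    keep <- keep & v >= m - k * s & v <= m + k * s
  }
  add_gate_step(subset_events(events, keep), "trim_sd",
                nrow(events), sum(keep), k)
}

#' Shrinkable forward/side-scatter gate
#'
#' Retains the `keep_fraction` of events closest to the FSC/SSC centroid in
#' Mahalanobis distance. Because cell-wide (extrinsic) state correlates with
#' scatter, shrinking this gate preferentially removes extrinsic variation
#' while leaving intrinsic noise essentially unchanged.
#'
#' @param events an [event_table()].
#' @param keep_fraction fraction of events to retain, in (0, 1]; exactly
#'   `ceiling(keep_fraction * n)` events are kept.
#' @return The gated table; see [gate_report()].
#' @export
gate_scatter <- function(events, keep_fraction) {
  stopifnot(inherits(events, "event_table"))
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("gate_scatter: 'keep_fraction' must lie in (0, 1]", call. = FALSE)
  n <- nrow(events)
  if (keep_fraction == 1)
    return(add_gate_step(events, "scatter", n, n, 1))
  sc <- cbind(events$fsc, events$ssc)
  S <- stats::cov(sc)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps * prod(diag(S)))
    stop("gate_scatter: degenerate FSC/SSC covariance", call. = FALSE)
  d <- stats::mahalanobis(sc, colMeans(sc), S)
  n_keep <- ceiling(keep_fraction * n)
  keep_idx <- sort(order(d)[seq_len(n_keep)])
  keep <- logical(n)
  keep[keep_idx] <- TRUE
  add_gate_step(subset_events(events, keep), "scatter", n, n_keep,
                keep_fraction)
}

#' Remove events that merge with the background signal
#'
#' Drops events below an intensity floor in one channel. Intended only for
#' the low-expression regime of the simple-regulation clone, where the
#' repressed reporter's distribution runs into autofluorescence.
#'
#' @param events an [event_table()].
#' @param channel channel to filter.
#' @param floor intensity floor (a.u., >= 0); events `>= floor` are kept.
#' @return The filtered table; see [gate_report()].
#' @export
background_floor_filter <- function(events, channel, floor) {
  stopifnot(inherits(events, "event_table"))
  if (floor < 0)
    stop("background_floor_filter: 'floor' must be non-negative",
         call. = FALSE)
  keep <- events[[channel]] >= floor
  if (!any(keep))
    warning("background_floor_filter: floor ", format(floor),
            " removes every event in channel '", channel, "'", call. = FALSE)
  add_gate_step(subset_events(events, keep), paste0("floor_", channel),
                nrow(events), sum(keep), floor)
}

#' Standard preprocessing chain for one well
#'
#' Applies the gates in the fixed order scatter -> positive -> (optional
#' background floor) -> s.d. trim, then removes non-positive events in the
#' analysis channels. All steps are recorded in the gate report.
#'
#' @param events an [event_table()].
#' @param control uninduced-control [event_table()] for the positive gate,
#'   or `NULL` to skip it.
#' @param constitutive channel used by the positive gate.
#' @param positive_quantile control quantile of the positive gate.
#' @param trim_k s.d. multiplier of the trimming band.
#' @param scatter_keep scatter-gate keep fraction (1 = no scatter gating).
#' @param background_floor optional intensity floor, applied to
#'   `floor_channel`.
#' @param floor_channel channel for the background floor (defaults to the
#'   regulated channel being the one that merges with background).
#' @return The preprocessed [event_table()].
#' @export
preprocess_events <- function(events, control = NULL, constitutive = "red",
                              positive_quantile = 0.995, trim_k = 2.5,
                              scatter_keep = 1, background_floor = NULL,
                              floor_channel = NULL) {
  out <- gate_scatter(events, scatter_keep)
  if (!is.null(control))
    out <- gate_positive(out, control, constitutive, positive_quantile)
  if (!is.null(background_floor) && is.finite(background_floor)) {
    if (is.null(floor_channel))
      floor_channel <- setdiff(c("green", "red"), constitutive)
    out <- background_floor_filter(out, floor_channel, background_floor)
  }
  out <- trim_outliers(out, trim_k)
  drop_nonpositive(out)
}
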