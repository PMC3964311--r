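# Titration-series decomposition: log_stats -> calibrate_alpha ->
# decompose_well per well, replicate by replicate.

#' Decompose an inducer titration series
#'
#' Runs the full per-well chain on an ordered IPTG titration: computes
#' log-scale moments, calibrates the regulated reporter's sensitivity
#' coefficient against the fully induced well of the same replicate, and
#' splits each reporter's total noise into extrinsic and intrinsic
#' components. Each replicate is calibrated against its own fully induced
#' well so that replicate-level extrinsic states are never mixed.
#'
#' @param wells list of [event_table()]s, one per well; each table's
#'   metadata (`iptg_uM`, `replicate`, `well_id`) identifies it. Within a
#'   replicate the IPTG concentrations must be distinct; wells are ordered
#'   by increasing IPTG.
#' @param x_channel,y_channel channels of the regulated (X) and constitutive
#'   (Y) reporters; see [regulated_channel()].
#' @param mode noise scale, `"log"` (default) or `"linear"`; see
#'   [decompose_well()].
#' @param fully_induced optional `well_id` of the fully induced well
#'   (per replicate); by default the well with the highest IPTG.
#' @param drop_nonpos drop non-positive events before the log transform
#'   (default `TRUE`; set `FALSE` if already filtered).
#' @return An object of class `noise_breakdown`: a data frame with one row
#'   per well, replicate and reporter, columns `well_id`, `replicate`,
#'   `iptg_uM`, `dox_ng_ml`, `fully_induced`, `reporter`, `channel`,
#'   `alpha`, `cv2_total`, `cv2_ext`, `cv2_int`, `mean`, `n_events`. The
#'   per-well [log_stats()] objects are attached as
#'   `attr(x, "log_stats")` (named `replicate:well_id`).
#' @seealso [aggregate_replicates()], [bootstrap_series()],
#'   [plot.noise_breakdown()]
#' @export
decompose_series <- function(wells, x_channel = "green", y_channel = "red",
                             mode = c("log", "linear"), fully_induced = NULL,
                             drop_nonpos = TRUE) {
  mode <- match.arg(mode)
  if (!length(wells)) stop("decompose_series: empty series", call. = FALSE)
  if (inherits(wells, "event_table")) wells <- list(wells)
  meta <- do.call(rbind, lapply(wells, function(w) {
    stopifnot(inherits(w, "event_table"))
    if (!nrow(w)) stop("decompose_series: empty well", call. = FALSE)
    data.frame(well_id = w$well_id[1], iptg_uM = w$iptg_uM[1],
               dox_ng_ml = w$dox_ng_ml[1], replicate = w$replicate[1],
               stringsAsFactors = FALSE)
  }))

  rows <- list()
  stats_store <- list()
  for (rep_id in unique(meta$replicate)) {
    idx <- which(meta$replicate == rep_id)
    ord <- idx[order(meta$iptg_uM[idx])]
    iptg <- meta$iptg_uM[ord]
    if (anyDuplicated(iptg[!is.na(iptg)]))
      stop("decompose_series: duplicated IPTG concentrations in replicate '",
           rep_id, "'; inducer levels must be strictly increasing",
           call. = FALSE)
    if (is.null(fully_induced)) {
      n_idx <- length(ord)  # highest inducer = fully induced
    } else {
      n_idx <- match(fully_induced, meta$well_id[ord])
      if (is.na(n_idx))
        stop("decompose_series: fully induced well '", fully_induced,
             "' not found in replicate '", rep_id, "'", call. = FALSE)
    }
    stats_list <- lapply(ord, function(i) {
      w <- wells[[i]]
      if (drop_nonpos) w <- suppressWarnings(drop_nonpositive(w))
      log_stats(w, x_channel, y_channel)
    })
    alpha <- calibrate_alpha(stats_list, induced = n_idx)
    cov_n <- stats_list[[n_idx]]$cov_log
    for (k in seq_along(ord)) {
      bd <- decompose_well(stats_list[[k]], alpha[k], mode = mode,
                           ext_y = if (mode == "log") cov_n else NULL)
      bd <- cbind(data.frame(well_id = meta$well_id[ord[k]],
                             replicate = rep_id,
                             iptg_uM = meta$iptg_uM[ord[k]],
                             dox_ng_ml = meta$dox_ng_ml[ord[k]],
                             fully_induced = k == n_idx,
                             stringsAsFactors = FALSE),
                  bd)
      bd$channel <- ifelse(bd$reporter == "X", x_channel, y_channel)
      rows[[length(rows) + 1L]] <- bd
      stats_store[[paste(rep_id, meta$well_id[ord[k]], sep = ":")]] <-
        stats_list[[k]]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("noise_breakdown", "data.frame"),
            mode = mode, x_channel = x_channel, y_channel = y_channel,
            log_stats = stats_store)
}

#' @export
print.noise_breakdown <- function(x, digits = 4, ...) {
  cat(sprintf("Noise breakdown (%s mode): %d wells x %d replicate(s)\n",
              attr(x, "mode"),
              length(unique(x$well_id)), length(unique(x$replicate))))
  cat(sprintf("  X = regulated (%s), Y = constitutive (%s)\n",
              attr(x, "x_channel"), attr(x, "y_channel")))
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Average noise components across replicates
#'
#' Per titration point and reporter, the mean and standard deviation of each
#' component across replicates (the error bars of the usual
#' noise-versus-inducer plots).
#'
#' @param breakdown a `noise_breakdown` from [decompose_series()], with at
#'   least two replicates per well; every replicate must cover the same
#'   set of titration points.
#' @return Data frame keyed by `iptg_uM` and `reporter` with
#'   `n_replicates`, and `mean`/`sd` columns for `alpha`, `cv2_total`,
#'   `cv2_ext`, `cv2_int` and the reporter mean intensity.
#' @export
aggregate_replicates <- function(breakdown) {
  stopifnot(inherits(breakdown, "noise_breakdown") ||
              is.data.frame(breakdown))
  key <- interaction(breakdown$iptg_uM, breakdown$reporter, drop = TRUE)
  counts <- table(key)
  if (length(unique(counts)) > 1L)
    stop("aggregate_replicates: replicates cover different well sets",
         call. = FALSE)
  if (min(counts) < 2L)
    stop("aggregate_replicates: need at least 2 replicates per well",
         call. = FALSE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- function(v) as.vector(tapply(as.character(v), key,
                                        function(z) z[1]))
  out <- data.frame(iptg_uM = as.numeric(first(breakdown$iptg_uM)),
                    reporter = first(breakdown$reporter),
                    n_replicates = as.integer(counts),
                    alpha_mean = agg(breakdown$alpha, mean),
                    alpha_sd = agg(breakdown$alpha, stats::sd),
                    cv2_total_mean = agg(breakdown$cv2_total, mean),
                    cv2_total_sd = agg(breakdown$cv2_total, stats::sd),
                    cv2_ext_mean = agg(breakdown$cv2_ext, mean),
                    cv2_ext_sd = agg(breakdown$cv2_ext, stats::sd),
                    cv2_int_mean = agg(breakdown$cv2_int, mean),
                    cv2_int_sd = agg(breakdown$cv2_int, stats::sd),
                    mean_mean = agg(breakdown$mean, mean),
                    mean_sd = agg(breakdown$mean, stats::sd),
                    stringsAsFactors = FALSE)
  out[order(out$reporter, out$iptg_uM), , drop = FALSE]
}

#' @export
summary.noise_breakdown <- function(object, ...) {
  if (length(unique(object$replicate)) >= 2L) aggregate_replicates(object)
  else as.data.frame(object)
}

#' Event-level bootstrap of the series decomposition
#'
#' Nonparametric uncertainty for every component: events are resampled with
#' replacement within each well (jointly across channels), the whole
#' calibration and decomposition is rerun, and the standard deviation across
#' resamples is reported.
#'
#' @param wells list of [event_table()]s, as for [decompose_series()].
#' @param B number of bootstrap resamples (default 200).
#' @param seed integer seed.
#' @param ... passed to [decompose_series()].
#' @return Data frame with one row per well, replicate and reporter and
#'   bootstrap standard errors `se_alpha`, `se_cv2_total`, `se_cv2_ext`,
#'   `se_cv2_int`.
#' @export
bootstrap_series <- function(wells, B = 200, seed = 1, ...) {
  if (inherits(wells, "event_table")) wells <- list(wells)
  base <- suppressWarnings(decompose_series(wells, ...))
  draws <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      resampled <- lapply(wells, function(w) {
        idx <- sample.int(nrow(w), replace = TRUE)
        subset_events(w, idx)
      })
      bd <- suppressWarnings(decompose_series(resampled, ...))
      bd[c("alpha", "cv2_total", "cv2_ext", "cv2_int")]
    })
  })
  se <- function(col) apply(sapply(draws, `[[`, col), 1L, stats::sd)
  data.frame(well_id = base$well_id, replicate = base$replicate,
             reporter = base$reporter,
             se_alpha = se("alpha"), se_cv2_total = se("cv2_total"),
             se_cv2_ext = se("cv2_ext"), se_cv2_int = se("cv2_int"),
             stringsAsFactors = FALSE)
}

#' Plot noise components along a titration
#'
#' Reproduces the two standard views: each component against the inducer
#' concentration, or against the mean intensity of the plotted reporter.
#' Total noise is drawn with green squares, extrinsic with red triangles and
#' intrinsic with blue diamonds; with replicates, error bars show the
#' replicate standard deviation.
#'
#' @param x a `noise_breakdown`.
#' @param reporter `"X"` (regulated) or `"Y"` (constitutive).
#' @param against x-axis: `"iptg"` or `"mean"`.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.noise_breakdown <- function(x, reporter = "X",
                                 against = c("iptg", "mean"),
                                 main = NULL, ...) {
  against <- match.arg(against)
  sub <- x[x$reporter == reporter, , drop = FALSE]
  if (!nrow(sub)) stop("plot.noise_breakdown: no rows for reporter ",
                       reporter, call. = FALSE)
  multi <- length(unique(sub$replicate)) >= 2L
  if (multi) {
    agg <- aggregate_replicates(sub)
    xs <- if (against == "iptg") agg$iptg_uM else agg$mean_mean
    comp <- cbind(total = agg$cv2_total_mean, ext = agg$cv2_ext_mean,
                  int = agg$cv2_int_mean)
    sds <- cbind(agg$cv2_total_sd, agg$cv2_ext_sd, agg$cv2_int_sd)
  } else {
    xs <- if (against == "iptg") sub$iptg_uM else sub$mean
    comp <- cbind(total = sub$cv2_total, ext = sub$cv2_ext,
                  int = sub$cv2_int)
    sds <- NULL
  }
  ord <- order(xs)
  xs <- xs[ord]
  comp <- comp[ord, , drop = FALSE]
  if (!is.null(sds)) sds <- sds[ord, , drop = FALSE]
  cols <- c("darkgreen", "red3", "blue3")
  pchs <- c(15, 17, 18)
  xlab <- if (against == "iptg") "IPTG (uM)" else "mean intensity (a.u.)"
  if (is.null(main))
    main <- sprintf("Noise components, reporter %s (%s)", reporter,
                    attr(x, "mode"))
  ylim <- range(0, comp + if (is.null(sds)) 0 else sds, na.rm = TRUE)
  graphics::plot(xs, comp[, 1], log = if (against == "iptg") "x" else "",
                 type = "b", pch = pchs[1], col = cols[1], ylim = ylim,
                 xlab = xlab, ylab = "noise (CV^2 / log-variance)",
                 main = main, ...)
  for (j in 2:3)
    graphics::lines(xs, comp[, j], type = "b", pch = pchs[j], col = cols[j])
  if (!is.null(sds))
    for (j in 1:3)
      graphics::arrows(xs, comp[, j] - sds[, j], xs, comp[, j] + sds[, j],
                       angle = 90, code = 3, length = 0.03, col = cols[j])
  graphics::legend("topleft", c("total", "extrinsic", "intrinsic"),
                   col = cols, pch = pchs, bty = "n")
  invisible(x)
}
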