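# Efficiency-corrected delta-delta-Ct copy-number estimation.
#
# relative copies = (1 + E_target)^(-dCt_target) / (1 + E_ref)^(-dCt_ref),
# with each gene's amplification efficiency E estimated from a dilution
# curve of Ct versus log2(DNA amount) on the single-copy calibrator line.
# dCt is sample Ct minus calibrator Ct for the same gene, so lower sample
# Ct means more template and a ratio above 1.

#' Amplification efficiency from a dilution curve
#'
#' Ordinary least-squares fit of Ct on `log2(amount)`; with slope `m` the
#' per-cycle amplification factor is `2^(-1/m)` and the efficiency
#' `E = 2^(-1/m) - 1`. Perfect doubling chemistry (`m = -1`) gives `E = 1`.
#'
#' @param amounts input DNA amounts (ng), at least 3 distinct values.
#' @param cts measured cycle thresholds, same length.
#' @return Efficiency `E` (a number in practice near 1); the fitted slope is
#'   attached as `attr(E, "slope")`.
#' @export
#' @examples
#' amounts <- c(6.25, 12.5, 25, 50, 100)
#' efficiency_from_dilution(amounts, 30 - log2(amounts))  # ideal: E = 1
efficiency_from_dilution <- function(amounts, cts) {
  if (length(amounts) != length(cts))
    stop("efficiency_from_dilution: 'amounts' and 'cts' lengths differ",
         call. = FALSE)
  if (length(unique(amounts)) < 3L)
    stop("efficiency_from_dilution: need at least 3 distinct DNA amounts",
         call. = FALSE)
  if (any(amounts <= 0))
    stop("efficiency_from_dilution: DNA amounts must be strictly positive",
         call. = FALSE)
  fit <- stats::lm(cts ~ I(log2(amounts)))
  m <- unname(stats::coef(fit)[2L])
  if (!is.finite(m) || m >= 0)
    stop("efficiency_from_dilution: non-negative slope (", format(m),
         "); dilution series failed", call. = FALSE)
  structure(2^(-1 / m) - 1, slope = m)
}

#' Relative copy number by the efficiency-corrected delta-delta-Ct formula
#'
#' `(1 + e_target)^(-dct_target) / (1 + e_ref)^(-dct_ref)`, the
#' generalisation of `2^-ddCt` to unequal amplification efficiencies. With
#' `e_target = e_ref = 1` it reduces exactly to `2^-(dct_target - dct_ref)`.
#'
#' @param dct_target,dct_ref sample-minus-calibrator Ct differences for the
#'   transgene and the endogenous reference gene (cycles); vectorised.
#' @param e_target,e_ref amplification efficiencies (> -1).
#' @return Relative copy number(s); 1 means equal to the single-copy
#'   calibrator.
#' @export
copy_ratio <- function(dct_target, dct_ref, e_target, e_ref) {
  if (any(e_target <= -1) || any(e_ref <= -1))
    stop("copy_ratio: efficiencies must be > -1", call. = FALSE)
  (1 + e_target)^(-dct_target) / (1 + e_ref)^(-dct_ref)
}

#' Summarise replicate copy-number ratios into an integer call
#'
#' @param ratios relative copy numbers from at least 2 replicates.
#' @return List with `mean`, `sd`, the nearest positive integer `call`, and
#'   `ambiguous = TRUE` when the mean lies within 0.25 of a half-integer
#'   (the rounding boundary), flagging an unreliable call.
#' @export
summarize_copies <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2L)
    stop("summarize_copies: need at least 2 replicate ratios", call. = FALSE)
  m <- mean(ratios)
  list(mean = m, sd = stats::sd(ratios),
       call = max(1L, as.integer(round(m))),
       ambiguous = abs(m - (floor(m) + 0.5)) < 0.25)
}

#' Copy-number estimation from a qPCR Ct table
#'
#' End-to-end delta-delta-Ct workflow on a long-format Ct table with columns
#' `target` (`"transgene"` or `"reference"`), `ct`, `amount` (ng; required
#' for dilution rows), `replicate` and `role` (`"dilution"`, `"calibrator"`
#' or `"sample"`). Efficiencies come from each target's dilution rows unless
#' supplied; dCt pairs sample and calibrator Ct per target (calibrator Ct
#' averaged across its replicates), and per-replicate ratios are summarised
#' with [summarize_copies()].
#'
#' @param ct_table data frame (or CSV path) in the schema above.
#' @param e_target,e_ref optional efficiencies overriding the dilution fit.
#' @return Object of class `qpcr_copies`: list with `efficiencies`,
#'   per-replicate `ratios`, and the `summary` from [summarize_copies()].
#' @export
qpcr_copy_number <- function(ct_table, e_target = NULL, e_ref = NULL) {
  if (is.character(ct_table))
    ct_table <- as.data.frame(data.table::fread(ct_table, showProgress = FALSE))
  needed <- c("target", "ct", "amount", "replicate", "role")
  missing_cols <- setdiff(needed, names(ct_table))
  if (length(missing_cols))
    stop("qpcr_copy_number: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0))
    stop("qpcr_copy_number: all Ct values must be finite and positive",
         call. = FALSE)
  bad_target <- setdiff(unique(ct_table$target), c("transgene", "reference"))
  if (length(bad_target))
    stop("qpcr_copy_number: unknown target(s): ",
         paste(bad_target, collapse = ", "), call. = FALSE)

  eff <- function(target, supplied) {
    if (!is.null(supplied)) return(supplied)
    d <- ct_table[ct_table$target == target & ct_table$role == "dilution", ]
    if (!nrow(d))
      stop("qpcr_copy_number: no dilution rows for target '", target,
           "' and no efficiency supplied", call. = FALSE)
    efficiency_from_dilution(d$amount, d$ct)
  }
  e_t <- eff("transgene", e_target)
  e_r <- eff("reference", e_ref)

  dct <- function(target) {
    cal <- ct_table[ct_table$target == target & ct_table$role == "calibrator", ]
    smp <- ct_table[ct_table$target == target & ct_table$role == "sample", ]
    if (!nrow(cal) || !nrow(smp))
      stop("qpcr_copy_number: target '", target,
           "' needs both calibrator and sample rows", call. = FALSE)
    d <- smp$ct - mean(cal$ct)
    names(d) <- smp$replicate
    d
  }
  dct_t <- dct("transgene")
  dct_r <- dct("reference")
  reps <- intersect(names(dct_t), names(dct_r))
  if (length(reps) < 2L)
    stop("qpcr_copy_number: need at least 2 replicates present for both ",
         "targets", call. = FALSE)
  ratios <- copy_ratio(dct_t[reps], dct_r[reps], e_t, e_r)
  structure(list(efficiencies = c(transgene = as.numeric(e_t),
                                  reference = as.numeric(e_r)),
                 ratios = ratios,
                 summary = summarize_copies(ratios)),
            class = "qpcr_copies")
}

#' @export
print.qpcr_copies <- function(x, ...) {
  cat("qPCR copy-number estimate (delta-delta-Ct)\n")
  cat(sprintf("  efficiencies: transgene %.3f, reference %.3f\n",
              x$efficiencies[["transgene"]], x$efficiencies[["reference"]]))
  cat(sprintf("  ratios: %s\n",
              paste(sprintf("%.3f", x$ratios), collapse = ", ")))
  s <- x$summary
  cat(sprintf("  mean %.3f +/- %.3f  ->  call: %d cop%s%s\n", s$mean, s$sd,
              s$call, if (s$call == 1L) "y" else "ies",
              if (s$ambiguous) "  (ambiguous)" else ""))
  invisible(x)
}
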