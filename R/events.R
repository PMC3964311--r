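# Event tables: per-cell scatter + two-colour fluorescence with well
# metadata. CSV schema (header required, comma separator, '.' decimal):
# well_id, iptg_uM, dox_ng_ml, replicate, fsc, ssc, green, red.

EVENT_META_COLS <- c("well_id", "iptg_uM", "dox_ng_ml", "replicate")
EVENT_NUM_COLS <- c("fsc", "ssc", "green", "red")
EVENT_COLS <- c(EVENT_META_COLS, EVENT_NUM_COLS)

#' Construct and validate a per-cell event table
#'
#' @param df data frame with columns `well_id`, `iptg_uM`, `dox_ng_ml`,
#'   `replicate` (constant within a table), `fsc`, `ssc`, `green`, `red`.
#'   Intensity columns must be finite; negative fluorescence is allowed at
#'   this stage (autofluorescence-subtracted or background-dominated events)
#'   and is removed by [drop_nonpositive()] before any log transform.
#' @param validate set to `FALSE` to skip checks on trusted internal input.
#' @return A data frame of class `event_table`.
#' @export
event_table <- function(df, validate = TRUE) {
  if (validate) {
    missing_cols <- setdiff(EVENT_COLS, names(df))
    if (length(missing_cols))
      stop("event_table: missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    for (nm in EVENT_NUM_COLS) {
      v <- df[[nm]]
      if (!is.numeric(v))
        stop("event_table: column '", nm, "' must be numeric", call. = FALSE)
      bad <- which(!is.finite(v))
      if (length(bad))
        stop("event_table: non-finite values in '", nm, "' at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "),
             if (length(bad) > 5L) ", ...", call. = FALSE)
    }
    for (nm in EVENT_META_COLS)
      if (nrow(df) > 0L && length(unique(df[[nm]])) > 1L)
        stop("event_table: metadata column '", nm,
             "' is not constant within the table", call. = FALSE)
  }
  df <- as.data.frame(df)[c(EVENT_COLS, setdiff(names(df), EVENT_COLS))]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d events, well '%s' (IPTG %s uM, Dox %s ng/ml, %s)\n",
              nrow(x), x$well_id[1], format(x$iptg_uM[1]),
              format(x$dox_ng_ml[1]), x$replicate[1]))
  rep <- gate_report(x)
  if (!is.null(rep)) {
    cat("Gating chain:\n")
    print.data.frame(rep, row.names = FALSE)
  }
  invisible(x)
}

#' Read per-cell events from disk
#'
#' @param path file path.
#' @param format `"csv"` for the package CSV schema. `"fcs"` is reserved for
#'   raw cytometer output (FCS 3.x with a channel-name map) and is not
#'   available in this build; export events to CSV instead.
#' @param channel_map named character vector mapping instrument channel
#'   names to schema channels, used only by the FCS path.
#' @return An [event_table()].
#' @export
read_events <- function(path, format = c("csv", "fcs"), channel_map = NULL) {
  format <- match.arg(format)
  if (format == "fcs")
    stop("read_events: FCS ingestion requires an FCS 3.x reader, which this ",
         "build does not include; export the events to the CSV schema ",
         "(well_id, iptg_uM, dox_ng_ml, replicate, fsc, ssc, green, red)",
         call. = FALSE)
  if (!file.exists(path))
    stop("read_events: file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, sep = ",", dec = ".",
                                        header = TRUE, showProgress = FALSE))
  missing_cols <- setdiff(EVENT_COLS, names(df))
  if (length(missing_cols))
    stop("read_events: ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (nm in EVENT_NUM_COLS) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("read_events: unparseable or non-finite '", nm, "' at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) ", ...", call. = FALSE)
    df[[nm]] <- v
  }
  event_table(df)
}

#' Write an event table to the package CSV schema
#'
#' Uses a shortest-round-trip decimal representation so that a write/read
#' cycle reproduces the numeric values exactly.
#'
#' @param events an [event_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  data.table::fwrite(as.data.frame(events)[EVENT_COLS], path)
  invisible(path)
}

#' Drop events that are non-positive in an analysis channel
#'
#' Log-scale statistics require strictly positive intensities; events at or
#' below zero in either analysis channel are excluded and counted.
#'
#' @param events an [event_table()].
#' @param channels channels that must be strictly positive.
#' @return The filtered table; the number of removed events is available as
#'   `attr(x, "n_dropped_nonpositive")` and in the gate report.
#' @export
drop_nonpositive <- function(events, channels = c("green", "red")) {
  stopifnot(inherits(events, "event_table"))
  keep <- Reduce(`&`, lapply(channels, function(ch) events[[ch]] > 0))
  out <- subset_events(events, keep)
  attr(out, "n_dropped_nonpositive") <- sum(!keep)
  add_gate_step(out, "drop_nonpositive", nrow(events), sum(keep))
}

# Row subset that preserves class and gate report.
subset_events <- function(events, keep) {
  out <- as.data.frame(events)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(events)
  attr(out, "gate_report") <- attr(events, "gate_report")
  attr(out, "n_dropped_nonpositive") <- attr(events, "n_dropped_nonpositive")
  out
}

add_gate_step <- function(events, step, n_in, n_out, threshold = NA_real_) {
  row <- data.frame(step = step, n_in = as.integer(n_in),
                    n_out = as.integer(n_out),
                    threshold = as.numeric(threshold),
                    stringsAsFactors = FALSE)
  attr(events, "gate_report") <- rbind(attr(events, "gate_report"), row)
  events
}

#' Gating report of an event table
#'
#' One row per processing step with input/output event counts (guaranteed
#' non-increasing along the chain) and the threshold used, where applicable.
#'
#' @param events an [event_table()] that has passed through one or more
#'   gates.
#' @return A data frame, or `NULL` if no gate has been applied.
#' @export
gate_report <- function(events) attr(events, "gate_report")
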