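#' Per-event flow cytometry table
#'
#' An `event_table` holds one cytometry sample: one row per recorded event
#' with forward scatter (`fsc`), side scatter (`ssc`) and one or more
#' fluorescence channels, plus sample-level metadata carried in attributes.
#' The calibration state is tracked explicitly and may only move from
#' `"raw"` (arbitrary instrument units) to `"calibrated"` (standardized
#' MEFL/MEAP units); [to_mefl()] performs that transition.
#'
#' @param data data.frame with numeric columns `fsc`, `ssc` and at least one
#'   fluorescence channel (default name `fl1`). An `event_id` column is added
#'   if absent.
#' @param sample_id character scalar identifying the sample.
#' @param channels names of the fluorescence channel columns.
#' @param units unit label for the fluorescence channels, e.g. `"au"`
#'   (arbitrary units) or `"MEFL"`.
#' @param calibration_state `"raw"` or `"calibrated"`.
#' @param gated logical; whether the table has already been density gated.
#'
#' @return A data.frame of class `event_table`.
#' @seealso [density_gate()], [fit_bead_calibration()], [to_mefl()],
#'   [summarize_sample()]
#' @export
event_table <- function(data, sample_id = "sample",
                        channels = NULL,
                        units = "au",
                        calibration_state = c("raw", "calibrated"),
                        gated = FALSE) {
  calibration_state <- match.arg(calibration_state)
  data <- as.data.frame(data)
  if (nrow(data) < 1L) stop("event table must contain at least one event", call. = FALSE)
  for (col in c("fsc", "ssc")) {
    if (!col %in% names(data)) stop(sprintf("missing column '%s'", col), call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- setdiff(names(data), c("event_id", "fsc", "ssc", "units"))
  }
  if (length(channels) < 1L) stop("at least one fluorescence channel is required", call. = FALSE)
  missing_ch <- setdiff(channels, names(data))
  if (length(missing_ch)) {
    stop(sprintf("fluorescence channel(s) not found: %s", paste(missing_ch, collapse = ", ")),
         call. = FALSE)
  }
  if (!"event_id" %in% names(data)) data$event_id <- seq_len(nrow(data))
  data <- data[, c("event_id", "fsc", "ssc", channels)]
  structure(data,
            class = c("event_table", "data.frame"),
            sample_id = sample_id,
            channels = channels,
            units = units,
            calibration_state = calibration_state,
            gated = gated)
}

is_event_table <- function(x) inherits(x, "event_table")

assert_event_table <- function(x) {
  if (!is_event_table(x)) stop("expected an `event_table`", call. = FALSE)
  invisible(x)
}

# rebuild attributes after row subsetting (base [.data.frame drops them)
restore_event_attrs <- function(new, template, gated = NULL) {
  event_table(new,
              sample_id = attr(template, "sample_id"),
              channels = attr(template, "channels"),
              units = attr(template, "units"),
              calibration_state = attr(template, "calibration_state"),
              gated = gated %||% attr(template, "gated"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table '%s': %d events, channels [%s], units %s, %s%s>\n",
              attr(x, "sample_id"), nrow(x),
              paste(attr(x, "channels"), collapse = ", "),
              attr(x, "units"), attr(x, "calibration_state"),
              if (isTRUE(attr(x, "gated"))) ", gated" else ""))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more events\n", nrow(x) - 5L))
  invisible(x)
}

#' Read / write the canonical event CSV
#'
#' The canonical interchange format is a plain CSV with header columns
#' `event_id, fsc, ssc, fl1[, fl2, ...], units`; the `units` column is a
#' per-file flag (`au` for raw instrument units, `MEFL`/`MEAP` once
#' calibrated) repeated on every row.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the file name.
#' @return [read_event_csv()] returns an `event_table`;
#'   [write_event_csv()] invisibly returns `path`.
#' @export
read_event_csv <- function(path, sample_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  units <- if ("units" %in% names(df)) as.character(df$units[1]) else "au"
  df$units <- NULL
  state <- if (units %in% c("MEFL", "MEAP")) "calibrated" else "raw"
  event_table(df,
              sample_id = sample_id %||% sub("\\.csv$", "", basename(path)),
              units = units, calibration_state = state)
}

#' @rdname read_event_csv
#' @param events an `event_table`.
#' @export
write_event_csv <- function(events, path) {
  assert_event_table(events)
  df <- as.data.frame(events)
  df$units <- attr(events, "units")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
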