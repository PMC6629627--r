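#' Fit a calibration-bead mapping from channel units to MEFL/MEAP
#'
#' Locates the modes of the log-channel histogram of a bead sample by
#' kernel-density peak finding, matches them in increasing order to the
#' bead lot's assigned values, and fits a straight line in
#' log10(channel) vs log10(assigned value) by least squares. The fitted
#' mapping converts arbitrary instrument units into standardized MEFL
#' (Molecules of Equivalent Fluorescein) or MEAP values.
#'
#' @param bead_events raw `event_table` from a bead sample.
#' @param assigned_values strictly increasing MEFL/MEAP values of the bead
#'   peaks (>= 2).
#' @param channel fluorescence channel to calibrate.
#' @param instrument_max optional saturation value; events within 1% of it
#'   are excluded before peak finding (saturated top peak).
#' @param min_height_frac local maxima below this fraction of the tallest
#'   mode are ignored as noise.
#' @return list of class `bead_calibration` with `peak_channel_positions`,
#'   `assigned_values`, `slope`, `intercept` (log10-log10 space),
#'   `residual` (sum of squared log10 residuals) and `channel`.
#' @export
fit_bead_calibration <- function(bead_events, assigned_values, channel = "fl1",
                                 instrument_max = NULL, min_height_frac = 0.05) {
  assert_event_table(bead_events)
  n_peaks <- length(assigned_values)
  if (n_peaks < 2L) stop("need at least 2 assigned bead values", call. = FALSE)
  if (any(assigned_values <= 0) || any(diff(assigned_values) <= 0)) {
    stop("assigned_values must be strictly increasing and positive", call. = FALSE)
  }
  x <- as.data.frame(bead_events)[[channel]]
  if (is.null(x)) stop(sprintf("channel '%s' not found", channel), call. = FALSE)
  if (!is.null(instrument_max)) x <- x[x < 0.99 * instrument_max]
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 2L * n_peaks) stop("too few positive bead events", call. = FALSE)

  lx <- log10(x)
  d <- density(lx, n = 2048)
  modes <- local_maxima(d$x, d$y, min_height_frac)
  if (length(modes) < n_peaks) {
    stop(sprintf("found %d mode(s) in the bead channel histogram, need %d",
                 length(modes), n_peaks), call. = FALSE)
  }
  if (length(modes) > n_peaks) {
    # keep the n_peaks tallest modes (peaks carry similar event counts)
    h <- d$y[match(modes, d$x)]
    modes <- modes[order(-h)][seq_len(n_peaks)]
  }
  modes <- sort(modes)
  # refine each mode beyond KDE grid resolution: assign events to the
  # nearest mode and take the within-peak median
  assign_idx <- apply(abs(outer(lx, modes, "-")), 1L, which.min)
  peak_log <- vapply(seq_len(n_peaks), function(i) median(lx[assign_idx == i]),
                     numeric(1))
  if (any(!is.finite(peak_log)) || any(diff(peak_log) <= 0)) {
    stop("non-monotone peak/value pairing", call. = FALSE)
  }
  fit <- lm(log10(assigned_values) ~ peak_log)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) stop("fitted bead mapping is not increasing", call. = FALSE)
  structure(list(peak_channel_positions = 10^peak_log,
                 assigned_values = assigned_values,
                 slope = slope,
                 intercept = intercept,
                 residual = sum(residuals(fit)^2),
                 channel = channel),
            class = "bead_calibration")
}

local_maxima <- function(x, y, min_height_frac) {
  i <- which(diff(sign(diff(y))) == -2) + 1L
  i <- i[y[i] >= min_height_frac * max(y)]
  x[i]
}

#' @export
print.bead_calibration <- function(x, ...) {
  cat(sprintf("<bead_calibration: %d peaks, log10(MEFL) = %.4f + %.4f * log10(channel), residual %.3g>\n",
              length(x$assigned_values), x$intercept, x$slope, x$residual))
  invisible(x)
}

#' Apply a bead calibration to convert events to MEFL/MEAP
#'
#' Transforms the named channel through the fitted log-log mapping and
#' marks the table calibrated. The calibration state machine admits only
#' the raw -> calibrated transition: applying a calibration twice is an
#' error.
#'
#' @param events raw `event_table`.
#' @param calib a [fit_bead_calibration()] result.
#' @param channel channel to transform (defaults to the calibrated one).
#' @param units unit label of the calibrated values.
#' @return A calibrated `event_table`.
#' @export
to_mefl <- function(events, calib, channel = calib$channel, units = "MEFL") {
  assert_event_table(events)
  if (!inherits(calib, "bead_calibration")) stop("`calib` must be a bead_calibration", call. = FALSE)
  if (attr(events, "calibration_state") == "calibrated") {
    stop("events are already calibrated; refusing to apply a bead calibration twice",
         call. = FALSE)
  }
  df <- as.data.frame(events)
  v <- df[[channel]]
  if (is.null(v)) stop(sprintf("channel '%s' not found", channel), call. = FALSE)
  if (any(v <= 0)) stop("cannot calibrate non-positive channel values", call. = FALSE)
  df[[channel]] <- 10^(calib$intercept + calib$slope * log10(v))
  event_table(df, sample_id = attr(events, "sample_id"),
              channels = attr(events, "channels"),
              units = units, calibration_state = "calibrated",
              gated = attr(events, "gated"))
}
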