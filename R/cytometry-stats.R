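#' Summarize a sample as its median fluorescence
#'
#' The cell fluorescence of a culture sample is the median of the named
#' channel over all (gated, calibrated) events; an even event count uses
#' the mean-of-the-two-middle-values convention of [stats::median()].
#'
#' @param events an `event_table`.
#' @param channel channel to summarize (default: first channel).
#' @return Numeric scalar, in the table's units.
#' @export
summarize_sample <- function(events, channel = NULL) {
  assert_event_table(events)
  if (nrow(events) < 1L) stop("empty event table", call. = FALSE)
  channel <- channel %||% attr(events, "channels")[1]
  v <- as.data.frame(events)[[channel]]
  if (is.null(v)) stop(sprintf("channel '%s' not found", channel), call. = FALSE)
  median(v)
}

#' Subtract same-day autofluorescence
#'
#' Reporter fluorescence is the cell fluorescence of a sample minus the
#' cell fluorescence of a reporter-free control strain measured the same
#' day. The result may be negative; negativity is resolved downstream by
#' the detection test, never by flooring.
#'
#' @param sample,control cell fluorescence values in identical calibrated
#'   units.
#' @param units,control_units unit labels; a mismatch is an error.
#' @return sample - control.
#' @export
subtract_autofluorescence <- function(sample, control,
                                      units = "MEFL", control_units = units) {
  if (!identical(units, control_units)) {
    stop(sprintf("unit mismatch: sample in %s, control in %s", units, control_units),
         call. = FALSE)
  }
  sample - control
}

#' Detection test for replicate reporter measurements
#'
#' One-sample one-sided t-test of day replicates against zero
#' (alternative: mean > 0). A replicate set failing the test at p < 0.05
#' is reported as not detected (N.D.). Degenerate zero-variance replicates
#' take the t-distribution limit: p = 0 if the mean is positive, else
#' p = 1, flagged in the result.
#'
#' @param replicate_values numeric vector of reporter fluorescence values,
#'   one per day replicate; length >= 2.
#' @param alpha detection level.
#' @return list of class `replicate_stat`: `mean`, `sd`, `n`, `p_value`,
#'   `detected`, `degenerate`.
#' @export
detect <- function(replicate_values, alpha = 0.05) {
  x <- replicate_values
  if (length(x) < 2L) stop("need at least 2 replicates", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite replicate values", call. = FALSE)
  s <- sd(x)
  if (s == 0) {
    p <- if (mean(x) > 0) 0 else 1
    degenerate <- TRUE
  } else {
    p <- t.test(x, mu = 0, alternative = "greater")$p.value
    degenerate <- FALSE
  }
  structure(list(mean = mean(x), sd = s, n = length(x),
                 p_value = p, detected = p < alpha, degenerate = degenerate),
            class = "replicate_stat")
}

#' @export
print.replicate_stat <- function(x, ...) {
  cat(sprintf("<replicate_stat: %.4g +/- %.4g (n=%d), p=%.3g, %s%s>\n",
              x$mean, x$sd, x$n, x$p_value,
              if (isTRUE(x$detected)) "detected" else "N.D.",
              if (isTRUE(x$degenerate)) ", degenerate sd=0" else ""))
  invisible(x)
}

#' Welch's unequal-variances two-sample t-test
#'
#' Two-sided test of the difference in means with the Welch statistic and
#' Welch-Satterthwaite degrees of freedom. Implemented directly from the
#' defining formulas; zero-variance groups take the limiting values
#' (t = 0, p = 1 for identical constant groups, |t| = Inf, p = 0
#' otherwise).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_test <- function(group_a, group_b) {
  a <- group_a; b <- group_b
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values", call. = FALSE)
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  delta <- mean(a) - mean(b)
  if (va + vb == 0) {
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    return(list(t = t_stat, df = na + nb - 2,
                p_value = if (delta == 0) 1 else 0))
  }
  t_stat <- delta / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

#' Fold change between two replicate sets
#'
#' Dynamic range / fold activation of an output between two conditions
#' (e.g. green vs red light). With `pairing = "by_day"` (default) the
#' ratio is computed within each matched day replicate and summarized as
#' mean and sd over days; with `pairing = "ratio_of_means"` a single ratio
#' of the group means is returned with its sd from first-order error
#' propagation.
#'
#' @param numerator_reps,denominator_reps replicate values; the
#'   denominator must be strictly positive.
#' @param pairing `"by_day"` (requires equal lengths, matched order) or
#'   `"ratio_of_means"`.
#' @return list of class `replicate_stat` (dimensionless): `mean`, `sd`,
#'   `n`, `p_value = NA`, `detected = NA`, `pairing`.
#' @export
fold_change <- function(numerator_reps, denominator_reps,
                        pairing = c("by_day", "ratio_of_means")) {
  pairing <- match.arg(pairing)
  if (any(denominator_reps <= 0)) {
    stop("denominator replicates must be strictly positive", call. = FALSE)
  }
  if (pairing == "by_day") {
    if (length(numerator_reps) != length(denominator_reps)) {
      stop("by_day pairing requires equal replicate counts", call. = FALSE)
    }
    r <- numerator_reps / denominator_reps
    out <- list(mean = mean(r), sd = if (length(r) >= 2) sd(r) else NA_real_,
                n = length(r))
  } else {
    ma <- mean(numerator_reps); mb <- mean(denominator_reps)
    R <- ma / mb
    sa <- sd(numerator_reps); sb <- sd(denominator_reps)
    out <- list(mean = R,
                sd = abs(R) * sqrt((sa / ma)^2 + (sb / mb)^2),
                n = length(numerator_reps))
  }
  structure(c(out, list(p_value = NA_real_, detected = NA, degenerate = FALSE,
                        pairing = pairing)),
            class = "replicate_stat")
}
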