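#' Specification for a synthetic cytometry sample
#'
#' Describes one simulated cell population. Event-level fluorescence is the
#' sum of an autofluorescence draw and a reporter draw, each lognormal and
#' parameterized by its median and coefficient of variation (CV), so the
#' reporter median is defined after autofluorescence subtraction, mirroring
#' the measurement pipeline. Scatter values form a single elliptical
#' Gaussian cluster around `scatter_center`, optionally contaminated by a
#' uniform background fraction emulating debris/doublets.
#'
#' @param n_events number of events (>= 1).
#' @param median_fluorescence reporter median, MEFL (or arbitrary units
#'   before calibration); >= 0.
#' @param event_cv CV of the lognormal event distribution (> 0).
#' @param autofluorescence_median autofluorescence median in the same units.
#' @param autofluorescence_cv CV of the autofluorescence component.
#' @param scatter_center length-2 vector `c(fsc, ssc)`, arbitrary units.
#' @param scatter_spread relative spread (sd / center) of the scatter cluster.
#' @param background_fraction fraction of events drawn uniformly over an
#'   expanded scatter box instead of the cluster, in `[0, 1)`.
#' @param seed integer seed; all generation is reproducible given the seed.
#' @return A list of class `event_gen_spec`.
#' @export
event_gen_spec <- function(n_events,
                           median_fluorescence,
                           event_cv = 0.35,
                           autofluorescence_median = 0,
                           autofluorescence_cv = event_cv,
                           scatter_center = c(fsc = 50000, ssc = 30000),
                           scatter_spread = 0.15,
                           background_fraction = 0,
                           seed = 1L) {
  stopifnot(length(n_events) == 1L, length(median_fluorescence) == 1L)
  if (!is.finite(n_events) || n_events < 1) {
    stop("n_events must be >= 1", call. = FALSE)
  }
  if (!is.finite(median_fluorescence) || median_fluorescence < 0 ||
      !is.finite(autofluorescence_median) || autofluorescence_median < 0) {
    stop("medians must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(event_cv) || event_cv <= 0) stop("event_cv must be > 0", call. = FALSE)
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("background_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_events = as.integer(n_events),
                 median_fluorescence = median_fluorescence,
                 event_cv = event_cv,
                 autofluorescence_median = autofluorescence_median,
                 autofluorescence_cv = autofluorescence_cv,
                 scatter_center = scatter_center,
                 scatter_spread = scatter_spread,
                 background_fraction = background_fraction,
                 seed = as.integer(seed)),
            class = "event_gen_spec")
}

#' Generate an event-level cytometry sample
#'
#' @param spec an [event_gen_spec()].
#' @param sample_id sample identifier stored on the result.
#' @param units unit label of the generated fluorescence values; `"MEFL"`
#'   yields a calibrated table, anything else a raw one.
#' @return An [event_table()] with channel `fl1`.
#' @export
gen_events <- function(spec, sample_id = "synthetic", units = "MEFL") {
  if (!inherits(spec, "event_gen_spec")) stop("`spec` must be an event_gen_spec", call. = FALSE)
  n <- spec$n_events
  with_seed(spec$seed, {
    n_bg <- round(spec$background_fraction * n)
    n_cl <- n - n_bg
    ctr <- spec$scatter_center
    fsc <- c(abs(rnorm(n_cl, ctr[1], spec$scatter_spread * ctr[1])),
             runif(n_bg, 0, 2.5 * ctr[1]))
    ssc <- c(abs(rnorm(n_cl, ctr[2], spec$scatter_spread * ctr[2])),
             runif(n_bg, 0, 2.5 * ctr[2]))
    reporter <- rlnorm_median_cv(n, spec$median_fluorescence, spec$event_cv)
    auto <- rlnorm_median_cv(n, spec$autofluorescence_median, spec$autofluorescence_cv)
    df <- data.frame(fsc = fsc, ssc = ssc, fl1 = auto + reporter)
    event_table(df, sample_id = sample_id, channels = "fl1",
                units = units,
                calibration_state = if (units %in% c("MEFL", "MEAP")) "calibrated" else "raw")
  })
}

#' Generate a calibration-bead sample with known channel mapping
#'
#' Emulates a multi-peak rainbow calibration bead suspension. Each bead peak
#' with true value `v` (MEFL) appears at channel position
#' `channel_offset + channel_gain * v^exponent`, spread lognormally with CV
#' `peak_cv`. The true mapping is returned alongside for round-trip tests.
#'
#' @param peak_true_values strictly increasing positive MEFL values, >= 2.
#' @param channel_gain positive scale of the channel mapping.
#' @param channel_offset additive channel offset (default 0; nonzero values
#'   depart from a pure power law in log-log space).
#' @param peak_cv lognormal CV of events around each peak.
#' @param events_per_peak events per bead peak.
#' @param seed integer seed.
#' @param exponent power-law exponent of the mapping (slope in log-log space).
#' @return list with elements `events` (raw `event_table`) and `truth`
#'   (named list: `peak_true_values`, `peak_channel_positions`,
#'   `channel_gain`, `channel_offset`, `exponent`).
#' @export
gen_bead_sample <- function(peak_true_values, channel_gain = 1, channel_offset = 0,
                            peak_cv = 0.05, events_per_peak = 1000L, seed = 1L,
                            exponent = 1) {
  v <- peak_true_values
  if (length(v) < 2L) stop("calibration is underdetermined with fewer than 2 bead peaks", call. = FALSE)
  if (any(v <= 0) || any(diff(v) <= 0)) {
    stop("peak_true_values must be strictly increasing and positive", call. = FALSE)
  }
  if (channel_gain <= 0) stop("channel_gain must be positive", call. = FALSE)
  peak_pos <- channel_offset + channel_gain * v^exponent
  with_seed(seed, {
    fl <- unlist(lapply(peak_pos, function(p) {
      if (peak_cv <= 0) rep(p, events_per_peak) else rlnorm_median_cv(events_per_peak, p, peak_cv)
    }))
    n <- length(fl)
    df <- data.frame(fsc = abs(rnorm(n, 40000, 4000)),
                     ssc = abs(rnorm(n, 25000, 2500)),
                     fl1 = fl)
    list(events = event_table(df, sample_id = "beads", channels = "fl1",
                              units = "au", calibration_state = "raw"),
         truth = list(peak_true_values = v,
                      peak_channel_positions = peak_pos,
                      channel_gain = channel_gain,
                      channel_offset = channel_offset,
                      exponent = exponent))
  })
}

#' Design of a synthetic steady-state dose-response experiment
#'
#' @param truth a [hill_params()] object: the generating transfer function.
#' @param doses input-dose values (light intensity in umol m-2 s-1, xylose
#'   %, or IPTG uM); non-negative, strictly positive where log spacing is
#'   intended.
#' @param n_replicates replicates (separate "days") per dose, >= 1.
#' @param replicate_cv multiplicative lognormal noise CV applied to each
#'   sample median (median-1 lognormal, so noise is symmetric on the log
#'   scale the fit operates on).
#' @param seed integer seed.
#' @return list of class `dose_response_design`.
#' @export
dose_response_design <- function(truth, doses, n_replicates = 3L,
                                 replicate_cv = 0.1, seed = 1L) {
  assert_hill_params(truth)
  if (any(!is.finite(doses)) || any(doses < 0)) stop("doses must be finite and >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (replicate_cv < 0) stop("replicate_cv must be >= 0", call. = FALSE)
  structure(list(truth = truth, doses = doses,
                 n_replicates = as.integer(n_replicates),
                 replicate_cv = replicate_cv, seed = as.integer(seed)),
            class = "dose_response_design")
}

#' Generate replicate sample medians along a Hill dose-response
#'
#' Each sample median is `hill_eval(truth, dose)` multiplied by a median-1
#' lognormal factor with CV `replicate_cv`; records carry replicate labels
#' suitable for pooled fitting with [fit_hill()].
#'
#' @param design a [dose_response_design()].
#' @return data.frame with columns `dose`, `replicate`,
#'   `median_fluorescence`.
#' @export
gen_dose_response <- function(design) {
  if (!inherits(design, "dose_response_design")) {
    stop("`design` must be a dose_response_design", call. = FALSE)
  }
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      dose = design$doses)
  mu <- hill_eval(design$truth, grid$dose)
  with_seed(design$seed, {
    noise <- if (design$replicate_cv > 0) {
      rlnorm_median_cv(nrow(grid), 1, design$replicate_cv)
    } else rep(1, nrow(grid))
    data.frame(dose = grid$dose,
               replicate = paste0("day", grid$replicate),
               median_fluorescence = mu * noise)
  })
}

#' Design of a synthetic step ON/OFF timecourse experiment
#'
#' @param truth a [kinetic_params()] object: the generating rate constants
#'   and delay.
#' @param c_initial,c_final initial and final steady-state output levels
#'   (MEFL), both > 0.
#' @param sample_times sampling times in minutes, non-negative and strictly
#'   increasing.
#' @param n_replicates replicates per timepoint.
#' @param replicate_cv multiplicative lognormal noise CV on medians.
#' @param seed integer seed.
#' @return list of class `step_design`.
#' @export
step_design <- function(truth, c_initial, c_final,
                        sample_times = seq(0, 600, by = 25),
                        n_replicates = 3L, replicate_cv = 0.05, seed = 1L) {
  assert_kinetic_params(truth)
  if (c_initial <= 0 || c_final <= 0) stop("c_initial and c_final must be > 0", call. = FALSE)
  if (any(sample_times < 0) || any(diff(sample_times) <= 0)) {
    stop("sample_times must be non-negative and strictly increasing", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(truth = truth, c_initial = c_initial, c_final = c_final,
                 sample_times = sample_times,
                 n_replicates = as.integer(n_replicates),
                 replicate_cv = replicate_cv, seed = as.integer(seed)),
            class = "step_design")
}

#' Generate replicate medians from a step-response timecourse
#'
#' Noise-free medians are the mature-reporter state `G(t)` of the delayed
#' cascade ([closed_form_step()]) started at the `c_initial` steady state
#' and driven to `c_final`; multiplicative replicate noise as in
#' [gen_dose_response()].
#'
#' @param design a [step_design()].
#' @return data.frame with columns `time`, `replicate`,
#'   `median_fluorescence`.
#' @export
gen_step_experiment <- function(design) {
  if (!inherits(design, "step_design")) stop("`design` must be a step_design", call. = FALSE)
  traj <- closed_form_step(design$truth, design$c_initial, design$c_final,
                           design$sample_times)
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      i = seq_along(design$sample_times))
  mu <- traj$G[grid$i]
  with_seed(design$seed, {
    noise <- if (design$replicate_cv > 0) {
      rlnorm_median_cv(nrow(grid), 1, design$replicate_cv)
    } else rep(1, nrow(grid))
    data.frame(time = design$sample_times[grid$i],
               replicate = paste0("day", grid$replicate),
               median_fluorescence = mu * noise)
  })
}

#' Map calibrated events back to raw instrument units
#'
#' Applies the inverse of a power-law bead mapping
#' (`channel = gain * value^exponent`) so that synthetic MEFL-level events
#' can exercise the calibration stage of the pipeline.
#'
#' @param events a calibrated `event_table`.
#' @param channel_gain,exponent mapping parameters as in
#'   [gen_bead_sample()].
#' @return A raw `event_table` in arbitrary units.
#' @export
decalibrate_events <- function(events, channel_gain, exponent = 1) {
  assert_event_table(events)
  if (attr(events, "calibration_state") != "calibrated") {
    stop("events are already in raw units", call. = FALSE)
  }
  out <- as.data.frame(events)
  for (ch in attr(events, "channels")) {
    out[[ch]] <- channel_gain * out[[ch]]^exponent
  }
  event_table(out, sample_id = attr(events, "sample_id"),
              channels = attr(events, "channels"),
              units = "au", calibration_state = "raw",
              gated = attr(events, "gated"))
}
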