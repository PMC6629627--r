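#' Write a complete synthetic experiment to disk
#'
#' Materializes a dose-response or step design as the pipeline's on-disk
#' inputs: one raw event CSV per sample (reporter median from the design,
#' decalibrated through a known bead mapping), one reporter-free
#' autofluorescence control per day, one bead sample per day, and a YAML
#' manifest binding them together. The generating truth is returned so
#' end-to-end runs can be scored.
#'
#' @param design a [dose_response_design()] or [step_design()].
#' @param dir output directory (created if needed).
#' @param n_events events per cell sample.
#' @param autofluorescence_median autofluorescence level (MEFL) added to
#'   every cell sample and measured by the controls.
#' @param event_cv event-level lognormal CV.
#' @param channel_gain,exponent bead/channel mapping, see
#'   [gen_bead_sample()].
#' @param bead_values assigned MEFL values of the bead peaks.
#' @return list: `manifest_path`, `truth` (the design), `records` (the
#'   noise-free-level records used for sample medians).
#' @export
write_synthetic_experiment <- function(design, dir,
                                       n_events = 3000L,
                                       autofluorescence_median = 80,
                                       event_cv = 0.35,
                                       channel_gain = 0.05,
                                       exponent = 1,
                                       bead_values = c(792, 2079, 6588, 16471, 47497, 137049)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_dose <- inherits(design, "dose_response_design")
  if (!is_dose && !inherits(design, "step_design")) {
    stop("`design` must be a dose_response_design or step_design", call. = FALSE)
  }
  records <- if (is_dose) gen_dose_response(design) else gen_step_experiment(design)
  cond_col <- if (is_dose) "dose" else "time"
  days <- unique(records$replicate)
  seed0 <- design$seed

  beads <- list(); samples <- list(); k <- 0L
  for (d in seq_along(days)) {
    day <- days[d]
    bead_id <- paste0("beads_", day)
    bs <- gen_bead_sample(bead_values, channel_gain = channel_gain,
                          exponent = exponent, peak_cv = 0.04,
                          events_per_peak = 500L, seed = seed0 + 1000L + d)
    write_event_csv(bs$events, file.path(dir, paste0(bead_id, ".csv")))
    beads[[d]] <- list(id = bead_id, file = paste0(bead_id, ".csv"),
                       assigned_values = bead_values)

    ctrl_id <- paste0("ctrl_", day)
    ctrl <- gen_events(event_gen_spec(n_events, 0,
                                      event_cv = event_cv,
                                      autofluorescence_median = autofluorescence_median,
                                      seed = seed0 + 2000L + d),
                       sample_id = ctrl_id)
    write_event_csv(decalibrate_events(ctrl, channel_gain, exponent),
                    file.path(dir, paste0(ctrl_id, ".csv")))
    samples[[length(samples) + 1L]] <- list(id = ctrl_id,
                                            file = paste0(ctrl_id, ".csv"),
                                            is_control = TRUE, replicate = day,
                                            beads = bead_id)
    rows <- which(records$replicate == day)
    for (i in rows) {
      k <- k + 1L
      sid <- sprintf("s_%s_%s", format(records[[cond_col]][i]), day)
      ev <- gen_events(event_gen_spec(n_events, records$median_fluorescence[i],
                                      event_cv = event_cv,
                                      autofluorescence_median = autofluorescence_median,
                                      seed = seed0 + 3000L + k),
                       sample_id = sid)
      write_event_csv(decalibrate_events(ev, channel_gain, exponent),
                      file.path(dir, paste0(sid, ".csv")))
      entry <- list(id = sid, file = paste0(sid, ".csv"),
                    replicate = day, control = ctrl_id, beads = bead_id)
      entry[[cond_col]] <- records[[cond_col]][i]
      samples[[length(samples) + 1L]] <- entry
    }
  }
  manifest <- list(seed = seed0, gate_fraction = 0.5, channel = "fl1",
                   units = "MEFL", beads = beads, samples = samples)
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  list(manifest_path = manifest_path, truth = design, records = records)
}
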