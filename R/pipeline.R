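# Orchestration: events -> gated, calibrated medians -> replicate stats ->
# transfer-function / kinetic fits, driven by an experiment manifest.

# Process every sample in a manifest into per-sample summaries:
# gate -> MEFL calibration -> median -> same-day autofluorescence subtraction.
process_samples <- function(manifest, verbose = FALSE) {
  m <- validate_manifest(manifest)
  log_line <- function(...) if (verbose) message(sprintf(...))
  calibs <- list()
  for (b in m$beads %||% list()) {
    bev <- read_event_csv(resolve_sample_path(m, b$file), sample_id = b$id)
    calibs[[b$id]] <- fit_bead_calibration(bev, unlist(b$assigned_values),
                                           channel = m$channel)
    log_line("bead calibration '%s': slope %.3f intercept %.3f", b$id,
             calibs[[b$id]]$slope, calibs[[b$id]]$intercept)
  }
  one <- function(s) {
    ev <- read_event_csv(resolve_sample_path(m, s$file), sample_id = s$id)
    n_in <- nrow(ev)
    gated <- density_gate(ev, m$gate_fraction)
    if (attr(gated, "calibration_state") == "raw") {
      if (is.null(s$beads)) {
        stop(sprintf("sample '%s' is in raw units but has no bead calibration", s$id),
             call. = FALSE)
      }
      gated <- to_mefl(gated, calibs[[s$beads]], channel = m$channel, units = m$units)
    }
    cellf <- summarize_sample(gated, channel = m$channel)
    log_line("sample '%s': %d -> %d events, cell fluorescence %.4g %s",
             s$id, n_in, nrow(gated), cellf, m$units)
    data.frame(id = s$id,
               is_control = isTRUE(s$is_control),
               replicate = as.character(s$replicate),
               dose = if (is.null(s$dose)) NA_real_ else as.numeric(s$dose),
               time = if (is.null(s$time)) NA_real_ else as.numeric(s$time),
               control = s$control %||% NA_character_,
               gated_events = nrow(gated),
               cell_fluorescence = cellf,
               units = m$units)
  }
  summaries <- do.call(rbind, lapply(m$samples, one))
  ctrl <- summaries[summaries$is_control, ]
  summaries$reporter_fluorescence <- NA_real_
  for (i in which(!summaries$is_control)) {
    j <- match(summaries$control[i], ctrl$id)
    summaries$reporter_fluorescence[i] <- subtract_autofluorescence(
      summaries$cell_fluorescence[i], ctrl$cell_fluorescence[j])
  }
  summaries
}

report_provenance <- function(manifest) {
  list(manifest_hash = manifest_hash(manifest),
       seed = manifest$seed %||% NA,
       package = "optoflow",
       version = as.character(utils::packageVersion("optoflow")))
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$summaries, file.path(out_dir, "sample_summaries.csv"),
                   row.names = FALSE)
  report <- bundle[setdiff(names(bundle), "summaries")]
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Run the steady-state transfer-function analysis end to end
#'
#' Gates, calibrates and summarizes every sample in the manifest,
#' subtracts same-day autofluorescence, runs the detection test per dose,
#' and fits the Hill transfer function to the pooled replicate reporter
#' values.
#'
#' @param manifest an experiment manifest (list or
#'   [read_manifest()] result) whose samples carry a `dose` field.
#' @param out_dir optional directory; when given, writes
#'   `sample_summaries.csv` and `fit_report.json`.
#' @param verbose log per-stage progress.
#' @return list with `summaries` (per-sample data.frame), `detection`
#'   (per-dose [detect()] results), `fit` (a `fit_result`), `provenance`.
#' @export
run_transfer <- function(manifest, out_dir = NULL, verbose = FALSE) {
  m <- validate_manifest(manifest)
  summaries <- process_samples(m, verbose = verbose)
  meas <- summaries[!summaries$is_control, ]
  if (all(is.na(meas$dose))) stop("manifest samples carry no dose field", call. = FALSE)
  detection <- lapply(split(meas, meas$dose), function(d) {
    c(list(dose = d$dose[1]), unclass(detect(d$reporter_fluorescence)))
  })
  detected_doses <- vapply(detection, function(d) isTRUE(d$detected), logical(1))
  fit_data <- data.frame(x = meas$dose, y = meas$reporter_fluorescence,
                         replicate = meas$replicate)
  fit_data <- fit_data[fit_data$y > 0, ]
  fit <- fit_hill(fit_data)
  bundle <- list(summaries = summaries,
                 detection = unname(detection),
                 n_undetected_doses = sum(!detected_doses),
                 fit = serialize_fit(fit),
                 provenance = report_provenance(m))
  bundle$fit_object <- fit
  if (!is.null(out_dir)) {
    write_report_bundle(bundle[setdiff(names(bundle), "fit_object")], out_dir)
  }
  bundle
}

#' Run the step-response kinetic analysis end to end
#'
#' As [run_transfer()], but samples carry a `time` field; processing ends
#' in [fit_kinetics()] and a half-time report.
#'
#' @inheritParams run_transfer
#' @param direction `"on"` or `"off"`.
#' @param boundary a [hill_params()] (or list with `y0`, `dy`) supplying
#'   the steady-state endpoints of the step.
#' @return list with `summaries`, `fit` (a `fit_result` with
#'   `half_time`), `provenance`.
#' @export
run_kinetics <- function(manifest, direction = c("on", "off"), boundary,
                         out_dir = NULL, verbose = FALSE) {
  direction <- match.arg(direction)
  m <- validate_manifest(manifest)
  summaries <- process_samples(m, verbose = verbose)
  meas <- summaries[!summaries$is_control, ]
  if (all(is.na(meas$time))) stop("manifest samples carry no time field", call. = FALSE)
  tc <- data.frame(time = meas$time, replicate = meas$replicate,
                   y = meas$reporter_fluorescence)
  fit <- fit_kinetics(tc, direction = direction, boundary = boundary)
  bundle <- list(summaries = summaries,
                 fit = serialize_fit(fit),
                 half_time_min = fit$half_time,
                 provenance = report_provenance(m))
  bundle$fit_object <- fit
  if (!is.null(out_dir)) {
    write_report_bundle(bundle[setdiff(names(bundle), "fit_object")], out_dir)
  }
  bundle
}

serialize_fit <- function(fit) {
  est <- fit$estimates
  out <- list(estimates = unclass(est), se = as.list(fit$se),
              residual = fit$residual, converged = fit$converged,
              iterations = fit$iterations)
  if (!is.null(fit$symmetry)) {
    out$symmetry <- fit$symmetry
    out$estimates$kG <- out$estimates$kd  # running-text alias
    out$half_time_min <- fit$half_time
  }
  out
}

#' Batch recoding of FASTA records
#'
#' Reads ORF records from a FASTA file, recodes the first 15 codons of
#' each, writes the recoded sequences to FASTA and a TSV report with the
#' substitutions and window folding energies.
#'
#' @param fasta_in input FASTA of ORF sequences (DNA).
#' @param fasta_out output FASTA path for recoded sequences.
#' @param report_tsv output TSV path for the per-record report.
#' @param utr 5' UTR prepended to every record for the folding window
#'   (may be "").
#' @param backend folding backend, see [window_energy()].
#' @return Invisibly, the report data.frame (`id`, `n_substitutions`,
#'   `energy_before`, `energy_after`).
#' @export
run_recode <- function(fasta_in, fasta_out = NULL, report_tsv = NULL,
                       utr = "", backend = "nussinov") {
  seqs <- Biostrings::readDNAStringSet(fasta_in)
  recs <- lapply(as.character(seqs), function(s) recode_report(utr, s, backend = backend))
  report <- data.frame(
    id = names(seqs),
    n_substitutions = vapply(recs, function(r) nrow(r$substitutions), integer(1)),
    energy_before = vapply(recs, function(r) r$window_energy_before, numeric(1)),
    energy_after = vapply(recs, function(r) r$window_energy_after, numeric(1)))
  if (!is.null(fasta_out)) {
    out <- Biostrings::DNAStringSet(vapply(recs, function(r) r$recoded_sequence, character(1)))
    names(out) <- names(seqs)
    Biostrings::writeXStringSet(out, fasta_out)
  }
  if (!is.null(report_tsv)) {
    utils::write.table(report, report_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
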