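#' Experiment manifest
#'
#' A manifest binds event files to experimental conditions and declares
#' the per-day autofluorescence control and bead calibration sample every
#' measurement depends on. On disk it is a YAML document:
#'
#' ```yaml
#' seed: 7
#' gate_fraction: 0.5
#' channel: fl1
#' units: MEFL
#' beads:
#'   - id: beads_day1
#'     file: beads_day1.csv
#'     assigned_values: [792, 2079, 6588, 16471, 47497, 137049]
#' samples:
#'   - id: s_0.1_day1
#'     file: s_0.1_day1.csv
#'     dose: 0.1          # or `time: 40` for kinetic runs
#'     replicate: day1
#'     control: ctrl_day1
#'     beads: beads_day1
#'   - id: ctrl_day1
#'     file: ctrl_day1.csv
#'     is_control: true
#'     replicate: day1
#'     beads: beads_day1
#' ```
#'
#' @param path YAML file path.
#' @return list of class `experiment_manifest` (validated).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  m$base_dir <- dirname(normalizePath(path))
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest a manifest list (as from [read_manifest()] or built in
#'   code).
#' @export
validate_manifest <- function(manifest) {
  m <- manifest
  if (is.null(m$samples) || !length(m$samples)) stop("manifest has no samples", call. = FALSE)
  m$gate_fraction <- m$gate_fraction %||% 0.5
  if (m$gate_fraction <= 0 || m$gate_fraction > 1) {
    stop("gate_fraction must be in (0, 1]", call. = FALSE)
  }
  m$channel <- m$channel %||% "fl1"
  m$units <- m$units %||% "MEFL"
  bead_ids <- vapply(m$beads %||% list(), function(b) b$id, character(1))
  sample_ids <- vapply(m$samples, function(s) s$id, character(1))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in manifest", call. = FALSE)
  is_ctrl <- vapply(m$samples, function(s) isTRUE(s$is_control), logical(1))
  ctrl_ids <- sample_ids[is_ctrl]
  ctrl_day <- vapply(m$samples[is_ctrl], function(s) as.character(s$replicate), character(1))
  for (s in m$samples) {
    if (!is.null(s$beads) && !s$beads %in% bead_ids) {
      stop(sprintf("sample '%s' references unknown bead sample '%s'", s$id, s$beads),
           call. = FALSE)
    }
    if (!isTRUE(s$is_control)) {
      if (is.null(s$control)) {
        stop(sprintf("sample '%s' has no autofluorescence control", s$id), call. = FALSE)
      }
      i <- match(s$control, ctrl_ids)
      if (is.na(i)) {
        stop(sprintf("sample '%s' references unknown control '%s'", s$id, s$control),
             call. = FALSE)
      }
      if (!identical(as.character(s$replicate), ctrl_day[i])) {
        stop(sprintf("sample '%s' (day %s) is linked to control '%s' from a different day (%s)",
                     s$id, s$replicate, s$control, ctrl_day[i]), call. = FALSE)
      }
    }
  }
  class(m) <- c("experiment_manifest", "list")
  m
}

manifest_hash <- function(manifest) {
  f <- tempfile()
  on.exit(unlink(f))
  m <- unclass(manifest)
  m$base_dir <- NULL
  saveRDS(m, f, version = 2)  # scratch file only; hashed then removed
  unname(tools::md5sum(f))
}

resolve_sample_path <- function(manifest, file) {
  if (file.exists(file)) return(file)
  file.path(manifest$base_dir %||% ".", file)
}
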