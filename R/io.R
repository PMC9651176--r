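#' Write / read one trace as CSV plus JSON sidecar
#'
#' The on-disk contract for a single limb recording: a CSV with columns
#' `time_s`, `ppg_au`, `post_maneuver_flag` (0/1) and a JSON sidecar
#' (same path with extension `.json`) holding `patient_id`, `side`, the
#' protocol timing and, optionally, the ultrasound label and simulation
#' parameters.
#'
#' @param trace A `vppg_trace`.
#' @param path CSV path; the sidecar goes to `sub("\\.csv$", ".json", path)`.
#' @param us_positive Optional logical ultrasound label for the sidecar.
#' @param sim_params Optional [sim_params()] recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, us_positive = NULL, sim_params = NULL) {
  stopifnot(inherits(trace, "vppg_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(patient_id = trace$patient_id, side = trace$side,
               protocol = unclass(trace$protocol))
  if (!is.null(us_positive)) meta$us_positive <- us_positive
  if (!is.null(sim_params)) {
    meta$sim_params <- Filter(Negate(is.null), unclass(sim_params))
  }
  jsonlite::write_json(meta, trace_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

trace_sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_trace
#' @return For `read_trace()`, a `vppg_trace` (with attribute
#'   `us_positive` when present in the sidecar).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("read_trace: no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "ppg_au", "post_maneuver_flag")
  if (!all(need %in% names(df))) {
    stop("read_trace: CSV must have columns ", paste(need, collapse = ", "))
  }
  meta_path <- trace_sidecar_path(path)
  if (!file.exists(meta_path)) {
    stop("read_trace: missing sidecar ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  proto <- do.call(maneuver_protocol, meta$protocol)
  tr <- new_vppg_trace(patient_id = meta$patient_id, side = meta$side,
                       protocol = proto, time_s = df$time_s,
                       ppg_au = df$ppg_au,
                       post_maneuver = df$post_maneuver_flag != 0)
  if (!is.null(meta$us_positive)) attr(tr, "us_positive") <- meta$us_positive
  tr
}

#' Write a simulated cohort to a directory
#'
#' One CSV + JSON sidecar per limb, plus `manifest.csv` with one row per
#' limb (`trace_path`, `patient_id`, `side`, `us_positive`).
#'
#' @param cohort A `vppg_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vppg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(limb) {
    fname <- sprintf("%s_%s.csv", limb$trace$patient_id, limb$trace$side)
    write_trace(limb$trace, file.path(dir, fname),
                us_positive = limb$us_positive, sim_params = limb$params)
    data.frame(trace_path = fname, patient_id = limb$trace$patient_id,
               side = limb$trace$side, us_positive = limb$us_positive)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read / write a cohort manifest
#'
#' The manifest is the file-level unit of the pipeline: a CSV with header
#' `trace_path, patient_id, side, us_positive`, one row per limb.
#' Validation reports offending line numbers; `side` must be `left` or
#' `right` and `(patient_id, side)` must be unique.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with the four canonical columns (`us_positive`
#'   logical).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest: no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  validate_manifest(df)
}

validate_manifest <- function(df) {
  need <- c("trace_path", "patient_id", "side", "us_positive")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  df <- df[need]
  bad_side <- which(!df$side %in% c("left", "right"))
  if (length(bad_side)) {
    stop(sprintf("manifest line %s: unknown side %s",
                 paste(bad_side + 1, collapse = ", "),  # +1 for the header
                 paste(unique(df$side[bad_side]), collapse = ", ")))
  }
  key <- paste(df$patient_id, df$side)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("manifest line %s: duplicate (patient_id, side) %s",
                 paste(dup + 1, collapse = ", "),
                 paste(unique(key[dup]), collapse = "; ")))
  }
  up <- tolower(df$us_positive)
  if (!all(up %in% c("true", "false", "0", "1"))) {
    stop("manifest: us_positive must be TRUE/FALSE or 0/1")
  }
  df$us_positive <- up %in% c("true", "1")
  df
}

#' @rdname read_manifest
#' @param manifest A manifest data.frame.
#' @return For `write_manifest()`, `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
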