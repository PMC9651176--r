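#' Re-zero a trace on its rest-window baseline
#'
#' The device records ~2 s with the arms alongside the torso before the
#' maneuver; that window defines zero volume.  This shifts the whole trace
#' so the rest-window mean is exactly 0.  Idempotent.
#'
#' @param trace A `vppg_trace`.
#' @return The trace with a zero-mean rest window.
#' @export
zero_baseline <- function(trace) {
  stopifnot(inherits(trace, "vppg_trace"))
  rest <- trace$time_s < trace$protocol$rest_duration
  if (!any(rest)) stop("zero_baseline: rest window contains no samples")
  trace$ppg_au <- trace$ppg_au - mean(trace$ppg_au[rest])
  trace
}

#' Extract the emptying statistics of one trace
#'
#' Computes, after re-zeroing on the rest baseline:
#' * `ppg_max` — the maximal PPG over the Ca-Pra maneuver (from abduction
#'   onset to the end of Pra; post-maneuver samples, recorded while the
#'   arms are lowered, are discarded);
#' * `end_ca_ppg` — the PPG value at the end of the Ca phase, taken as the
#'   median of the final `end_window` seconds of Ca for noise robustness;
#' * `pct_ppgmax` — `100 * end_ca_ppg / ppg_max`, the normalized emptying
#'   statistic.  Because Pra reveals complete emptying, `pct_ppgmax <= 100`
#'   always; it is negative when persistent arterial inflow with arrested
#'   outflow swells the forearm beyond its resting volume, and can fall
#'   below -100.
#'
#' When `ppg_max <= 0` (no detectable emptying anywhere) the normalization
#' is undefined and the feature set is flagged invalid rather than
#' returning an unbounded ratio.
#'
#' @param trace A `vppg_trace`.
#' @param end_window Length (s) of the terminal Ca window whose median
#'   defines `end_ca_ppg`.
#' @return An object of class `limb_features`: list with `ppg_max`,
#'   `end_ca_ppg`, `pct_ppgmax`, `valid`, `reason`.
#' @export
extract_features <- function(trace, end_window = 1) {
  stopifnot(inherits(trace, "vppg_trace"))
  p <- trace$protocol
  trace <- zero_baseline(trace)
  t <- trace$time_s

  if (max(t) + 1 / p$sample_rate < p$ca_end) {
    stop("extract_features: trace ends before the Ca window")
  }

  maneuver <- t >= p$rest_duration & t < p$pra_end & !trace$post_maneuver
  end_ca <- t >= (p$ca_end - end_window) & t < p$ca_end
  if (!any(end_ca)) stop("extract_features: empty end-of-Ca window")

  ppg_max <- max(trace$ppg_au[maneuver])
  end_ca_ppg <- stats::median(trace$ppg_au[end_ca])

  if (ppg_max <= 0) {
    return(new_limb_features(ppg_max, end_ca_ppg, NA_real_,
                             valid = FALSE, reason = "nonpositive_ppgmax"))
  }
  new_limb_features(ppg_max, end_ca_ppg, 100 * end_ca_ppg / ppg_max,
                    valid = TRUE, reason = NA_character_)
}

new_limb_features <- function(ppg_max, end_ca_ppg, pct_ppgmax, valid, reason) {
  structure(
    list(ppg_max = ppg_max, end_ca_ppg = end_ca_ppg,
         pct_ppgmax = pct_ppgmax, valid = valid, reason = reason),
    class = "limb_features"
  )
}

#' @export
print.limb_features <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("PPGmax %.2f AU | End-Ca-PPG %.2f AU | %.1f %%PPGmax\n",
                x$ppg_max, x$end_ca_ppg, x$pct_ppgmax))
  } else {
    cat(sprintf("invalid limb features (%s)\n", x$reason))
  }
  invisible(x)
}

#' Feature table of a simulated cohort
#'
#' Runs [extract_features()] and [classify_pattern()] over every limb of a
#' [simulate_cohort()] result and returns one row per limb — the unit of
#' analysis for the ROC stage.
#'
#' @param cohort A `vppg_cohort`.
#' @param rules Classification thresholds, see [pattern_rules()].
#' @return A data.frame with columns `patient_id`, `side`, `ppg_max`,
#'   `end_ca_ppg`, `pct_ppgmax`, `pattern`, `valid`, `us_positive`.
#' @export
features_table <- function(cohort, rules = pattern_rules()) {
  stopifnot(inherits(cohort, "vppg_cohort"))
  rows <- lapply(cohort, function(limb) {
    f <- extract_features(limb$trace)
    lab <- classify_pattern(limb$trace, f, rules)
    data.frame(patient_id = limb$trace$patient_id,
               side = limb$trace$side,
               ppg_max = f$ppg_max, end_ca_ppg = f$end_ca_ppg,
               pct_ppgmax = f$pct_ppgmax,
               pattern = lab$label, valid = f$valid,
               us_positive = limb$us_positive)
  })
  do.call(rbind, rows)
}

#' Batch feature extraction from trace files on disk
#'
#' Reads every trace referenced by a manifest (see [read_manifest()]),
#' extracts features, and returns one row per readable limb.  Unreadable
#' or malformed trace files are reported as row-level errors and skipped;
#' the run continues.
#'
#' @param manifest A manifest data.frame (columns `trace_path`,
#'   `patient_id`, `side`, `us_positive`) or a path to a manifest CSV.
#' @param base_dir Directory against which relative `trace_path`s are
#'   resolved; defaults to the manifest's own directory when `manifest` is
#'   a path, else the working directory.
#' @param quiet Suppress per-row error messages.
#' @return A data.frame as in [features_table()] (without `pattern`), with
#'   attribute `errors`: a data.frame of skipped rows and reasons.
#' @export
batch_features <- function(manifest, base_dir = NULL, quiet = FALSE) {
  if (is.character(manifest) && length(manifest) == 1) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (!is.data.frame(manifest) || nrow(manifest) == 0) {
    stop("batch_features: empty or invalid manifest")
  }
  rows <- list(); errs <- list()
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$trace_path[i]
    full <- if (file.exists(path)) path else file.path(base_dir, path)
    res <- tryCatch({
      tr <- read_trace(full)
      tr$patient_id <- manifest$patient_id[i]
      tr$side <- manifest$side[i]
      f <- extract_features(tr)
      data.frame(patient_id = manifest$patient_id[i],
                 side = manifest$side[i],
                 ppg_max = f$ppg_max, end_ca_ppg = f$end_ca_ppg,
                 pct_ppgmax = f$pct_ppgmax, valid = f$valid,
                 us_positive = as.logical(manifest$us_positive[i]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!quiet) message(sprintf("batch_features: row %d (%s) skipped: %s",
                                  i, path, conditionMessage(res)))
      errs[[length(errs) + 1]] <- data.frame(row = i, trace_path = path,
                                             reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("batch_features: no readable rows in manifest")
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(), trace_path = character(),
               reason = character())
  out
}
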