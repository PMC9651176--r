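#' Thresholds for qualitative pattern classification
#'
#' All thresholds are relative to the trace's own `ppg_max`, which makes
#' the classification invariant to the per-limb optical gain.
#'
#' @param delta_rise Fraction of `ppg_max` by which the Pra phase must
#'   exceed `end_ca_ppg` to call emptying incomplete.  The default, 0.13,
#'   is one minus the 87 %PPGmax operating threshold expressed as a
#'   fraction, so the qualitative and quantitative criteria cohere.
#' @param delta_fall Fraction of `ppg_max` the signal must fall during Pra
#'   to call post-ischemic venodilation filling.
#' @param t_slow Seconds after abduction onset beyond which reaching 90%
#'   of the end-Ca level is called slowed outflow.
#' @return A list of class `pattern_rules`.
#' @export
pattern_rules <- function(delta_rise = 0.13, delta_fall = 0.10, t_slow = 20) {
  stopifnot(delta_rise > 0, delta_fall > 0, t_slow > 0)
  structure(list(delta_rise = delta_rise, delta_fall = delta_fall,
                 t_slow = t_slow), class = "pattern_rules")
}

#' Classify the qualitative Ca-Pra response morphology
#'
#' Rule-based labelling of a trace into one of five operational patterns
#' (plus `invalid`):
#'
#' 1. If the Pra phase rises above `end_ca_ppg` by more than
#'    `delta_rise * ppg_max`, emptying during Ca was incomplete —
#'    `refill_incomplete` when an early Ca local maximum also exceeds
#'    `end_ca_ppg` by the same margin (the limb emptied, then refilled
#'    from persistent inflow), otherwise `incomplete_emptying`.
#' 2. Otherwise, if the signal falls during Pra by more than
#'    `delta_fall * ppg_max` (maximum drawdown within the Pra window), the
#'    venodilated bed is refilling after ischemia — `venodilation_filling`.
#' 3. Otherwise emptying is complete: `slowed_outflow_complete` when the
#'    trace first reaches 90% of `end_ca_ppg` later than `t_slow` seconds
#'    after abduction, else `complete_emptying`.
#'
#' Incomplete emptying takes precedence over venodilation when both rules
#' fire, since residual volume is the primary clinical question.
#'
#' @param trace A `vppg_trace`.
#' @param features Optional pre-computed [extract_features()] result.
#' @param rules A [pattern_rules()] list.
#' @return An object of class `pattern_label`: `label` plus an `evidence`
#'   list (`pra_rise`, `ca_refill_drop`, `pra_drawdown`, `t90`).
#' @export
classify_pattern <- function(trace, features = NULL, rules = pattern_rules()) {
  stopifnot(inherits(trace, "vppg_trace"), inherits(rules, "pattern_rules"))
  if (is.null(features)) features <- extract_features(trace)
  stopifnot(inherits(features, "limb_features"))
  if (!features$valid) {
    return(new_pattern_label("invalid", list(pra_rise = NA_real_,
                                             ca_refill_drop = NA_real_,
                                             pra_drawdown = NA_real_,
                                             t90 = NA_real_)))
  }

  trace <- zero_baseline(trace)
  p <- trace$protocol
  t <- trace$time_s
  ppg <- trace$ppg_au
  ca <- t >= p$rest_duration & t < p$ca_end
  pra <- t >= p$ca_end & t < p$pra_end
  if (!any(pra)) stop("classify_pattern: trace has no Pra samples")

  ppg_max <- features$ppg_max
  end_ca <- features$end_ca_ppg

  pra_rise <- max(ppg[pra]) - end_ca
  ca_refill_drop <- max(ppg[ca]) - end_ca
  run_max <- cummax(ppg[pra])
  pra_drawdown <- max(run_max - ppg[pra])

  # time from abduction onset to first crossing of 90% of the end-Ca level
  target <- 0.9 * end_ca
  hit <- which(ca)[ppg[ca] >= target]
  t90 <- if (end_ca > 0 && length(hit)) t[hit[1]] - p$rest_duration else
    NA_real_

  ev <- list(pra_rise = pra_rise, ca_refill_drop = ca_refill_drop,
             pra_drawdown = pra_drawdown, t90 = t90)

  label <-
    if (pra_rise > rules$delta_rise * ppg_max) {
      if (ca_refill_drop > rules$delta_rise * ppg_max) "refill_incomplete"
      else "incomplete_emptying"
    } else if (pra_drawdown > rules$delta_fall * ppg_max) {
      "venodilation_filling"
    } else if (!is.na(t90) && t90 > rules$t_slow) {
      "slowed_outflow_complete"
    } else {
      "complete_emptying"
    }
  new_pattern_label(label, ev)
}

new_pattern_label <- function(label, evidence) {
  structure(list(label = label, evidence = evidence),
            class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("pattern: %s\n", x$label))
  if (!all(is.na(unlist(x$evidence)))) {
    ev <- x$evidence
    cat(sprintf("  Pra rise %.2f AU | Ca refill drop %.2f AU | Pra drawdown %.2f AU | t90 %s s\n",
                ev$pra_rise, ev$ca_refill_drop, ev$pra_drawdown,
                ifelse(is.na(ev$t90), "-", format(ev$t90))))
  }
  invisible(x)
}
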