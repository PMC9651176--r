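# build a trace directly from a sample vector (bypasses the simulator)
make_trace <- function(ppg, protocol = maneuver_protocol(),
                       patient_id = "T", side = "right") {
  t <- protocol_times(protocol)
  stopifnot(length(ppg) == length(t))
  vppg:::new_vppg_trace(patient_id = patient_id, side = side,
                        protocol = protocol, time_s = t, ppg_au = ppg,
                        post_maneuver = t >= protocol$pra_end)
}

# piecewise-constant sample vector by phase: rest / ca (with a terminal
# end-window value) / pra / post
phase_trace <- function(protocol = maneuver_protocol(), rest = 0, ca = 5,
                        end_ca = ca, pra = ca, post = 0) {
  t <- protocol_times(protocol)
  ppg <- numeric(length(t))
  ppg[t < protocol$rest_duration] <- rest
  in_ca <- t >= protocol$rest_duration & t < protocol$ca_end
  ppg[in_ca] <- ca
  ppg[t >= (protocol$ca_end - 1) & t < protocol$ca_end] <- end_ca
  ppg[t >= protocol$ca_end & t < protocol$pra_end] <- pra
  ppg[t >= protocol$pra_end] <- post
  make_trace(ppg, protocol)
}

# brute-force Mann-Whitney AUC under the low-positive orientation:
# P(pos < neg) + 0.5 P(pos == neg), enumerated over all pairs
mw_auc_bruteforce <- function(pos, neg) {
  mean(outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q)))
}

# trapezoidal area under an empirical ROC (independent of the rank route)
trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# the 848-limb default cohort feature table is used by several tests;
# simulate it once per test run
default_cohort_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- features_table(simulate_cohort(cohort_spec()))
    }
    cache
  }
})
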