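test_that("baseline zeroing subtracts the rest-window mean", {
  proto <- maneuver_protocol()
  # constant trace: everything collapses to zero
  tr <- zero_baseline(make_trace(rep(5, 240)))
  expect_equal(tr$ppg_au, rep(0, 240))

  # already zero-mean rest window: identity
  tr0 <- phase_trace(proto, rest = 0, ca = 3)
  expect_equal(zero_baseline(tr0)$ppg_au, tr0$ppg_au)

  # rest samples {1,1,3,3} (mean 2): a later sample of 10 becomes 8
  small <- maneuver_protocol(rest_duration = 1, ca_end = 2, pra_end = 3,
                             total_duration = 3, sample_rate = 4)
  ppg <- c(1, 1, 3, 3, rep(0, 7), 10)
  shifted <- zero_baseline(make_trace(ppg, small))
  expect_equal(shifted$ppg_au[12], 8)

  # idempotent
  noisy <- make_trace(rnorm(240, mean = 4), proto)
  once <- zero_baseline(noisy)
  expect_equal(zero_baseline(once)$ppg_au, once$ppg_au)
})

test_that("emptying statistics follow the %PPGmax definition", {
  # monotone rise then flat Pra: End-Ca equals the maximum -> 100
  f <- extract_features(phase_trace(ca = 9, end_ca = 9, pra = 9))
  expect_equal(f$pct_ppgmax, 100)
  expect_true(f$valid)

  # End-Ca 6 AU with a 9 AU maximum in Pra -> 66.7 at printed precision
  f2 <- extract_features(phase_trace(ca = 4, end_ca = 6, pra = 9))
  expect_equal(f2$ppg_max, 9)
  expect_equal(f2$end_ca_ppg, 6)
  expect_equal(round_half_up(f2$pct_ppgmax, 1), 66.7)

  # deep negative End-Ca against a small maximum: -575, beyond -100
  f3 <- extract_features(phase_trace(ca = 0.5, end_ca = -5.75, pra = 1.0))
  expect_equal(f3$pct_ppgmax, -575)

  # no detectable emptying anywhere: invalid rather than an infinite ratio
  f4 <- extract_features(phase_trace(ca = -2, end_ca = -2, pra = -1))
  expect_false(f4$valid)
  expect_equal(f4$reason, "nonpositive_ppgmax")
  expect_true(is.na(f4$pct_ppgmax))

  # a trace that stops before the Ca window is rejected
  stub <- maneuver_protocol(rest_duration = 1, ca_end = 20, pra_end = 25,
                            total_duration = 25, sample_rate = 4)
  short <- vppg:::new_vppg_trace("T", "right", maneuver_protocol(),
                                 time_s = protocol_times(stub),
                                 ppg_au = rep(0, 100),
                                 post_maneuver = rep(FALSE, 100))
  expect_error(extract_features(short), "ends before")
})

test_that("%PPGmax is invariant to the optical gain", {
  tr <- simulate_trace(sim_params(outflow_block = 0.7, noise_sd = 0.1,
                                  seed = 5, resolution = 0))
  base <- extract_features(tr)$pct_ppgmax
  for (g in c(0.2, 3, 41.5)) {
    scaled <- tr
    scaled$ppg_au <- tr$ppg_au * g
    expect_equal(extract_features(scaled)$pct_ppgmax, base,
                 tolerance = 1e-12)
  }
})

test_that("every valid limb satisfies pct_ppgmax <= 100", {
  ft <- default_cohort_features()
  expect_true(all(ft$pct_ppgmax[ft$valid] <= 100))
  expect_true(all(ft$ppg_max[ft$valid] >= ft$end_ca_ppg[ft$valid]))
})
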