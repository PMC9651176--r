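test_that("protocol validation enforces timing order and sampling", {
  expect_s3_class(maneuver_protocol(), "maneuver_protocol")
  expect_length(protocol_times(maneuver_protocol()), 240)
  expect_error(maneuver_protocol(sample_rate = 0), "sample_rate")
  expect_error(maneuver_protocol(rest_duration = 40), "rest_duration")
  expect_error(maneuver_protocol(pra_end = 70, total_duration = 60),
               "rest_duration < ca_end")
  expect_error(sim_params(outflow_block = 2), "outflow_block")
  expect_error(sim_params(inflow = Inf), "non-finite")
  expect_error(sim_params(outflow_rate = -1), ">= 0")
})

test_that("patent outflow empties fully during Ca and Pra adds nothing", {
  tr <- simulate_trace(sim_params())
  f <- extract_features(tr)
  expect_equal(f$pct_ppgmax, 100)

  # the Ca-window maximum already equals the whole-maneuver maximum
  t <- tr$time_s
  ca <- t >= 2 & t < 30
  maneuver <- t >= 2 & t < 45
  expect_equal(max(tr$ppg_au[ca]), max(tr$ppg_au[maneuver]))
})

test_that("arrested outflow with persistent inflow drives the trace negative", {
  tr <- simulate_trace(sim_params(outflow_block = 1))
  f <- extract_features(tr)
  expect_lt(f$end_ca_ppg, 0)          # forearm swells beyond resting volume
  t <- tr$time_s
  pra <- t >= 30 & t < 45
  expect_gt(max(tr$ppg_au[pra]), 0.8 * f$ppg_max)  # steep Pra emptying
})

test_that("simulator matches a hand-integrated Euler oracle on a coarse grid", {
  # 1 Hz grid, rest 1 s / Ca to 2 s / Pra to 3 s / stop 4 s, both flows
  # arrested in Ca, venodilation 2.  By hand (dt = 1, V0 = 1):
  #   t=0 rest:  dV = 0                                   -> V(1) = 1
  #   t=1 Ca:    dV = q*0 - k0*0*(V-0.1) = 0              -> V(2) = 1
  #   t=2 Pra:   q_h = 0.02*(1+6*1*e^0) = 0.14
  #              dV = 0.14 - 0.3*(1 - 0.1*(1+2*1)) = -0.07 -> V(3) = 0.93
  # PPG = 10*(1 - V) = (0, 0, 0, 0.7); rest mean already 0.
  proto <- maneuver_protocol(rest_duration = 1, ca_end = 2, pra_end = 3,
                             total_duration = 4, sample_rate = 1)
  tr <- simulate_trace(
    sim_params(outflow_block = 1, inflow_block = 1, venodilation = 2,
               resolution = 0),
    proto)
  expect_equal(tr$ppg_au, c(0, 0, 0, 0.7), tolerance = 1e-12)

  # same regime on the clinical grid: Ca flat at zero, Pra a monotone rise
  tr2 <- simulate_trace(
    sim_params(outflow_block = 1, inflow_block = 1, venodilation = 2,
               resolution = 0))
  ca <- tr2$time_s >= 2 & tr2$time_s < 30
  pra <- tr2$time_s >= 30 & tr2$time_s < 45
  expect_equal(max(abs(tr2$ppg_au[ca])), 0, tolerance = 1e-12)
  expect_true(all(diff(tr2$ppg_au[pra]) > 0))
})

test_that("emptying fraction is non-increasing in the outflow block", {
  pcts <- vapply(seq(0, 1, by = 0.1), function(cb) {
    extract_features(
      simulate_trace(sim_params(outflow_block = cb, resolution = 0))
    )$pct_ppgmax
  }, numeric(1))
  expect_true(all(diff(pcts) <= 1e-9))
})

test_that("identical seeds reproduce traces and cohorts bit-identically", {
  p <- sim_params(outflow_block = 0.5, noise_sd = 0.2, seed = 99L)
  expect_identical(simulate_trace(p)$ppg_au, simulate_trace(p)$ppg_au)

  spec <- cohort_spec(n_patients = 6,
                      side_status = c(right_only = 1, left_only = 1,
                                      bilateral = 1, none = 3),
                      seed = 11L)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(lapply(co1, function(l) l$trace$ppg_au),
                   lapply(co2, function(l) l$trace$ppg_au))
})

test_that("cohort generator reproduces the side-status marginals exactly", {
  co <- simulate_cohort(cohort_spec(n_patients = 20,
    side_status = c(right_only = 4, left_only = 3, bilateral = 5, none = 8),
    seed = 3))
  expect_length(co, 40)
  pos <- vapply(co, `[[`, logical(1), "us_positive")
  side <- vapply(co, function(l) l$trace$side, character(1))
  expect_equal(sum(pos & side == "right"), 4 + 5)
  expect_equal(sum(pos & side == "left"), 3 + 5)
  expect_equal(sum(pos), 4 + 3 + 2 * 5)

  none <- simulate_cohort(cohort_spec(n_patients = 5,
    side_status = c(right_only = 0, left_only = 0, bilateral = 0, none = 5),
    seed = 3))
  expect_equal(sum(vapply(none, `[[`, logical(1), "us_positive")), 0)

  expect_error(cohort_spec(n_patients = 10,
    side_status = c(right_only = 1, left_only = 1, bilateral = 1, none = 3)),
    "sum to")
})
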