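test_that("half-up rounding matches the printed-percentage convention", {
  expect_equal(round_half_up(2.25, 1), 2.3)   # base round() would give 2.2
  expect_equal(round_half_up(60.86956, 1), 60.9)
  expect_equal(round_half_up(-2.25, 1), -2.3) # away from zero
  expect_equal(percent_of(447, 848), 52.7)
  expect_equal(percent_of(65, 848), 7.7)
  expect_equal(percent_of(158, 848), 18.6)
  expect_error(percent_of(1, 0), "denominator")
})

test_that("cutoff tables count the 2x2 under the low-positive rule", {
  # all positives below, all negatives above: a perfect test
  score <- c(10, 30, 91, 99)
  label <- c(TRUE, TRUE, FALSE, FALSE)
  m <- confusion_metrics(table_at_cutoff(score, label, 87))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)

  # cutoff below every score: nothing called positive
  tab <- table_at_cutoff(score, label, 5)
  expect_equal(tab$tp + tab$fp, 0L)
  m2 <- confusion_metrics(tab)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_equal(tab$below_cutoff_fraction, 0)
})

test_that("the published marginals reconstruct a unique integer table", {
  r <- reconstruct_table(207, 641, 60.9, 47.6)
  expect_true(r$consistent)
  expect_true(r$unique)
  tab <- r$tables[[1]]
  expect_equal(c(tab$tp, tab$fn, tab$fp, tab$tn), c(126L, 81L, 336L, 305L))

  r2 <- reconstruct_table(10, 10, 100.0, 100.0)
  expect_true(r2$unique)
  expect_equal(c(r2$tables[[1]]$tp, r2$tables[[1]]$tn), c(10L, 10L))

  # no multiple of 10% rounds to 55.0: inconsistency is reported, not hidden
  r3 <- reconstruct_table(10, 10, 55.0, 50.0)
  expect_false(r3$consistent)
  expect_length(r3$tables, 0)
})

test_that("reconstruction round-trips exact tables", {
  set.seed(13)
  for (i in 1:20) {
    n_pos <- sample(50:400, 1); n_neg <- sample(50:800, 1)
    tp <- sample(0:n_pos, 1); tn <- sample(0:n_neg, 1)
    r <- reconstruct_table(n_pos, n_neg,
                           round_half_up(100 * tp / n_pos, 1),
                           round_half_up(100 * tn / n_neg, 1))
    expect_true(r$consistent)
    expect_true(tp %in% r$tp_candidates)
    expect_true(tn %in% r$tn_candidates)
    if (r$unique) {
      expect_equal(r$tables[[1]]$tp, tp)
      expect_equal(r$tables[[1]]$tn, tn)
    }
  }
})

test_that("predictive values respond to prevalence at fixed sens/spec", {
  # sens 0.8, spec 0.7 held exactly; prevalence swept upward
  ppv <- vapply(seq(0.1, 0.9, by = 0.1), function(prev) {
    n_pos <- round(1000 * prev); n_neg <- 1000 - n_pos
    tab <- new_confusion_table(tp = round(0.8 * n_pos),
                               fn = n_pos - round(0.8 * n_pos),
                               tn = round(0.7 * n_neg),
                               fp = n_neg - round(0.7 * n_neg))
    confusion_metrics(tab)$ppv
  }, numeric(1))
  expect_true(all(diff(ppv) > 0))
})
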