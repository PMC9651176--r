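test_that("ROC points match hand-counted 2x2 tables", {
  score <- c(10, 20, 90, 95)
  label <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- empirical_roc(score, label)

  # cutoff 95, rule "positive iff score < 95": tp = 2, fn = 0, fp = 1 (the
  # negative at 90), tn = 1 -> sens 1, spec 0.5
  p95 <- roc[roc$cutoff == 95, ]
  expect_equal(p95$sensitivity, 1)
  expect_equal(p95$specificity, 0.5)

  # cutoff 90 separates the classes perfectly
  p90 <- roc[roc$cutoff == 90, ]
  expect_equal(p90$sensitivity, 1)
  expect_equal(p90$specificity, 1)
  expect_equal(p90$distance, 0)
  best <- closest_corner_cutoff(roc)
  expect_equal(best$cutoff, 90)

  expect_equal(auc_with_se(score, label)$auc, 1)

  # the smallest score gives the all-negative endpoint, Inf the all-positive
  expect_equal(roc$sensitivity[roc$cutoff == 10], 0)
  expect_equal(roc$specificity[roc$cutoff == 10], 1)
  expect_equal(roc$sensitivity[is.infinite(roc$cutoff)], 1)
  expect_equal(roc$specificity[is.infinite(roc$cutoff)], 0)
})

test_that("AUC equals brute-force pair enumeration, including ties", {
  # interleaved scores: concordant pairs (1,2), (1,4), (3,4); discordant (3,2)
  expect_equal(mw_auc_bruteforce(c(1, 3), c(2, 4)), 0.75)
  expect_equal(auc_with_se(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE))$auc,
               0.75)

  set.seed(42)
  for (i in 1:25) {
    n_pos <- sample(1:15, 1); n_neg <- sample(1:15, 1)
    score <- sample(1:8, n_pos + n_neg, replace = TRUE)  # heavy ties
    label <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    expect_equal(auc_with_se(score, label)$auc,
                 mw_auc_bruteforce(score[label], score[!label]),
                 tolerance = 1e-12)
  }
})

test_that("trapezoidal area under the empirical ROC equals the rank AUC", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    score <- round(rnorm(n), 1)                       # some ties
    label <- c(TRUE, FALSE, runif(n - 2) < 0.5)       # both classes present
    expect_equal(trapezoid_auc(empirical_roc(score, label)),
                 auc_with_se(score, label)$auc, tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil and DeLong standard errors are sound", {
  # closed form at the reference cohort's operating figures: A = 0.589 with
  # 207 positives and 641 negatives gives SE 0.0233 (Q1 = A/(2-A),
  # Q2 = 2A^2/(1+A))
  hm_se <- function(A, n_pos, n_neg) {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    sqrt((A * (1 - A) + (n_pos - 1) * (q1 - A^2) +
            (n_neg - 1) * (q2 - A^2)) / (n_pos * n_neg))
  }
  expect_equal(hm_se(0.589, 207, 641), 0.023326, tolerance = 1e-4)

  set.seed(11)
  score <- c(rnorm(40, 0), rnorm(60, 1))
  label <- rep(c(TRUE, FALSE), c(40, 60))
  a <- auc_with_se(score, label)
  expect_equal(a$se, hm_se(a$auc, 40, 60), tolerance = 1e-12)
  expect_equal(a$z, (a$auc - 0.5) / a$se)
  expect_equal(a$p, 2 * pnorm(-abs(a$z)))

  # DeLong variant against pROC (cases score lower than controls here,
  # hence direction ">")
  skip_if_not_installed("pROC")
  d <- auc_with_se(score, label, method = "delong")
  pr <- pROC::roc(response = label, predictor = score, direction = ">",
                  levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(d$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(d$se^2, as.numeric(pROC::var(pr)), tolerance = 1e-10)
})

test_that("closest-corner selection agrees with exhaustive search", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    score <- round(rnorm(n), 1)
    label <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    roc <- empirical_roc(score, label)
    best <- closest_corner_cutoff(roc)
    expect_equal(best$distance, min(roc$distance), tolerance = 1e-15)
  }

  # ties resolved toward higher sensitivity: pos {1,2} / neg {2,3} puts
  # (sens, spec) = (0.5, 1) at cutoff 2 and (1, 0.5) at cutoff 3, both at
  # distance 0.5 from the corner
  roc2 <- empirical_roc(c(1, 2, 2, 3), c(TRUE, TRUE, FALSE, FALSE))
  best2 <- closest_corner_cutoff(roc2)
  expect_equal(best2$cutoff, 3)
  expect_equal(best2$sensitivity, 1)
})

test_that("AUC respects the standard invariances", {
  set.seed(31)
  score <- rnorm(50)
  label <- runif(50) < 0.4
  base <- auc_with_se(score, label)$auc

  # strictly monotone transforms leave the AUC unchanged
  for (f in list(function(x) 2 * x + 1, function(x) x^3,
                 function(x) exp(x))) {
    expect_equal(auc_with_se(f(score), label)$auc, base, tolerance = 1e-12)
  }

  # flipping the labels complements the AUC
  expect_equal(auc_with_se(score, !label)$auc, 1 - base, tolerance = 1e-12)

  # a new positive scoring below every negative never decreases the AUC
  for (i in 1:10) {
    s <- rnorm(20); l <- c(TRUE, FALSE, runif(18) < 0.5)
    before <- auc_with_se(s, l)$auc
    after <- auc_with_se(c(s, min(s[!l]) - 1), c(l, TRUE))$auc
    expect_gte(after, before - 1e-12)
  }

  # degenerate inputs
  expect_error(empirical_roc(c(1, 2), c(TRUE, TRUE)), "positive and one negative")
  same <- auc_with_se(rep(5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(same$auc, 0.5)
})
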