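#' Empirical ROC curve of a diagnostic score
#'
#' Builds the empirical ROC of a continuous score against a binary
#' reference by direct counting at every distinct observed score.  The
#' default orientation is `"lower_positive"`: a LOW score calls the test
#' positive (the convention for %PPGmax, where impaired emptying lowers
#' the score), with the cutoff rule "test positive iff score < cutoff".
#' Cutoffs are the observed values themselves (no mid-points), plus `Inf`
#' so the all-positive endpoint is always present; the all-negative
#' endpoint arises at the smallest observed score.
#'
#' Each point carries its Euclidean distance to the perfect corner
#' (sensitivity, specificity) = (1, 1), the quantity minimized by
#' [closest_corner_cutoff()].
#'
#' @param score Numeric vector of test scores (finite).
#' @param label Logical (or 0/1) vector: `TRUE` = reference positive.
#' @param orientation `"lower_positive"` (default) or `"higher_positive"`
#'   (test positive iff score > cutoff).
#' @return A data.frame of class `vppg_roc` with columns `cutoff`,
#'   `sensitivity`, `specificity`, `distance`, ordered by increasing
#'   sensitivity; attributes `orientation`, `n_pos`, `n_neg`.
#' @examples
#' r <- empirical_roc(c(10, 20, 90, 95), c(TRUE, TRUE, FALSE, FALSE))
#' closest_corner_cutoff(r)
#' @export
empirical_roc <- function(score, label,
                          orientation = c("lower_positive", "higher_positive")) {
  orientation <- match.arg(orientation)
  obs <- validate_observations(score, label)
  score <- obs$score; label <- obs$label
  n_pos <- sum(label); n_neg <- sum(!label)

  cutoffs <- sort(unique(score))
  if (orientation == "lower_positive") {
    cutoffs <- c(cutoffs, Inf)
    sens <- vapply(cutoffs, function(ct) sum(score[label] < ct), 0) / n_pos
    spec <- vapply(cutoffs, function(ct) sum(score[!label] >= ct), 0) / n_neg
  } else {
    cutoffs <- c(-Inf, cutoffs)
    sens <- vapply(cutoffs, function(ct) sum(score[label] > ct), 0) / n_pos
    spec <- vapply(cutoffs, function(ct) sum(score[!label] <= ct), 0) / n_neg
  }
  out <- data.frame(cutoff = cutoffs, sensitivity = sens, specificity = spec,
                    distance = sqrt((1 - sens)^2 + (1 - spec)^2))
  out <- out[order(out$sensitivity, -out$specificity), ]
  rownames(out) <- NULL
  structure(out, class = c("vppg_roc", "data.frame"),
            orientation = orientation, n_pos = n_pos, n_neg = n_neg)
}

validate_observations <- function(score, label) {
  if (is.numeric(label)) label <- label != 0
  if (!is.logical(label)) stop("labels must be logical or 0/1")
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  if (!length(score)) stop("no complete observations")
  if (!all(is.finite(score))) stop("scores must be finite")
  if (length(score) != length(label)) stop("score and label lengths differ")
  if (!any(label) || all(label)) {
    stop("ROC needs at least one positive and one negative observation")
  }
  list(score = score, label = label)
}

#' Area under the ROC curve with standard error
#'
#' The AUC is computed as the tie-corrected Mann-Whitney statistic: under
#' the low-positive orientation, the probability that a random positive
#' scores below a random negative, ties counting one half.  It equals the
#' trapezoidal area under [empirical_roc()].  The standard error follows
#' Hanley & McNeil (`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`), the nonparametric
#' default of the common clinical-statistics packages; `method = "delong"`
#' gives the DeLong covariance-based estimate instead.  `z` and the
#' two-sided `p` test the null AUC = 0.5 by normal approximation.
#'
#' @inheritParams empirical_roc
#' @param method `"hanley_mcneil"` (default) or `"delong"`.
#' @return An object of class `auc_result`: list with `auc`, `se`, `z`,
#'   `p`, `n_pos`, `n_neg`, `method`.
#' @export
auc_with_se <- function(score, label,
                        orientation = c("lower_positive", "higher_positive"),
                        method = c("hanley_mcneil", "delong")) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  obs <- validate_observations(score, label)
  score <- obs$score; label <- obs$label
  if (orientation == "lower_positive") score <- -score
  pos <- score[label]; neg <- score[!label]
  n_pos <- length(pos); n_neg <- length(neg)

  # Mann-Whitney via mid-ranks: AUC = P(pos > neg) + 0.5 P(pos == neg)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  se <- if (method == "hanley_mcneil") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
            (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  } else {
    # DeLong: placement values of each class against the other
    v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
    v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
    sqrt(stats::var(v10) / n_pos + stats::var(v01) / n_neg)
  }
  z <- if (se > 0) (auc - 0.5) / se else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(auc = auc, se = se, z = z, p = p,
                 n_pos = n_pos, n_neg = n_neg, method = method),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (SE %.3f, %s), z = %.2f, p = %.4g  [%d pos / %d neg]\n",
              x$auc, x$se, x$method, x$z, x$p, x$n_pos, x$n_neg))
  invisible(x)
}

#' Closest-to-corner optimal operating point
#'
#' Selects the ROC point minimizing the Euclidean distance to the perfect
#' (sensitivity, specificity) = (100%, 100%) corner — the optimal cutoff
#' under equal costs of false positives and false negatives.  Ties are
#' broken toward higher sensitivity, then lower cutoff.
#'
#' @param roc A `vppg_roc` data.frame from [empirical_roc()].
#' @return A one-row data.frame (the chosen `RocPoint`).
#' @export
closest_corner_cutoff <- function(roc) {
  stopifnot(inherits(roc, "vppg_roc"))
  if (nrow(roc) == 0) stop("closest_corner_cutoff: empty ROC")
  ord <- order(roc$distance, -roc$sensitivity, roc$cutoff)
  best <- ord[1]
  data.frame(cutoff = roc$cutoff[best],
             sensitivity = roc$sensitivity[best],
             specificity = roc$specificity[best],
             distance = roc$distance[best])
}
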