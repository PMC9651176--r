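#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used when clinical papers
#' print percentages to one decimal (base R's `round()` rounds half to
#' even, which would disagree on exact halves).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, printed-style
#'
#' `100 * k / n` rounded half-up to `digits` decimals — the form in which
#' cohort fractions are reported (e.g. 447 of 848 limbs -> 52.7).
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimals to keep.
#' @return Numeric percentage.
#' @export
percent_of <- function(k, n, digits = 1) {
  if (any(n <= 0)) stop("percent_of: denominator must be > 0")
  round_half_up(100 * k / n, digits)
}

#' Confusion table of a score at a cutoff
#'
#' Dichotomizes the score with the low-positive convention ("test positive
#' iff score < cutoff") and counts the 2x2 table against the reference
#' label.
#'
#' @param score Numeric test scores.
#' @param label Logical (or 0/1) reference: `TRUE` = condition present.
#' @param cutoff Decision threshold.
#' @param orientation `"lower_positive"` (default) or `"higher_positive"`.
#' @return An object of class `confusion_table`: counts `tp`, `fp`, `fn`,
#'   `tn` plus `below_cutoff_fraction`, with metrics via
#'   [confusion_metrics()].
#' @export
table_at_cutoff <- function(score, label, cutoff,
                            orientation = c("lower_positive",
                                            "higher_positive")) {
  orientation <- match.arg(orientation)
  if (is.numeric(label)) label <- label != 0
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  if (!length(score)) stop("table_at_cutoff: no observations")
  test_pos <- if (orientation == "lower_positive") score < cutoff else
    score > cutoff
  new_confusion_table(tp = sum(test_pos & label),
                      fp = sum(test_pos & !label),
                      fn = sum(!test_pos & label),
                      tn = sum(!test_pos & !label),
                      below_cutoff_fraction = mean(score < cutoff))
}

#' Build a confusion table from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @param below_cutoff_fraction Optional fraction of all scores below the
#'   cutoff (carried through by [table_at_cutoff()]).
#' @return An object of class `confusion_table`.
#' @export
new_confusion_table <- function(tp, fp, fn, tn,
                                below_cutoff_fraction = NA_real_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion_table: counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 below_cutoff_fraction = below_cutoff_fraction),
            class = "confusion_table")
}

#' Diagnostic accuracy metrics of a confusion table
#'
#' @param x A `confusion_table`.
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` (fractions in `[0, 1]`; `NaN` where a margin is empty).
#' @export
confusion_metrics <- function(x) {
  stopifnot(inherits(x, "confusion_table"))
  n <- x$tp + x$fp + x$fn + x$tn
  list(sensitivity = x$tp / (x$tp + x$fn),
       specificity = x$tn / (x$tn + x$fp),
       ppv = x$tp / (x$tp + x$fp),
       npv = x$tn / (x$tn + x$fn),
       accuracy = (x$tp + x$tn) / n)
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- confusion_metrics(x)
  cat(sprintf("2x2 table: TP %d | FP %d | FN %d | TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sens %.1f%% | spec %.1f%% | PPV %.1f%% | NPV %.1f%% | accuracy %.1f%%\n",
              100 * m$sensitivity, 100 * m$specificity, 100 * m$ppv,
              100 * m$npv, 100 * m$accuracy))
  if (!is.na(x$below_cutoff_fraction)) {
    cat(sprintf("  %.1f%% of scores below cutoff\n",
                100 * x$below_cutoff_fraction))
  }
  invisible(x)
}

#' Reconstruct an integer 2x2 table from rounded published marginals
#'
#' Publications usually print sensitivity and specificity rounded to one
#' decimal; with the class sizes known, the underlying integer table is
#' often uniquely determined.  This enumerates every `tp` in `[0, n_pos]`
#' and `tn` in `[0, n_neg]`, keeps those whose percentage rounds (half-up,
#' `digits` decimals) to the printed value, and returns the unique table
#' when exactly one candidate survives on each margin.  When several
#' survive, all candidate tables are returned so downstream metrics can be
#' reported as ranges; when none does, the printed values are mutually
#' inconsistent with the class sizes and an inconsistency report is
#' returned.
#'
#' @param n_pos,n_neg Number of reference-positive / -negative cases.
#' @param sens_printed,spec_printed Published sensitivity and specificity
#'   in percent, rounded to `digits` decimals.
#' @param digits Decimals of the published rounding.
#' @return An object of class `table_reconstruction`: list with
#'   `consistent`, `unique`, `tables` (list of `confusion_table`s,
#'   possibly empty), and the candidate `tp`/`tn` vectors.
#' @examples
#' r <- reconstruct_table(207, 641, 60.9, 47.6)
#' confusion_metrics(r$tables[[1]])
#' @export
reconstruct_table <- function(n_pos, n_neg, sens_printed, spec_printed,
                              digits = 1) {
  stopifnot(n_pos > 0, n_neg > 0)
  tol <- 10^(-digits) * 1e-6
  tp_cand <- which(abs(round_half_up(100 * (0:n_pos) / n_pos, digits) -
                         sens_printed) < tol) - 1L
  tn_cand <- which(abs(round_half_up(100 * (0:n_neg) / n_neg, digits) -
                         spec_printed) < tol) - 1L
  consistent <- length(tp_cand) > 0 && length(tn_cand) > 0
  tables <- list()
  if (consistent) {
    for (tp in tp_cand) for (tn in tn_cand) {
      tables[[length(tables) + 1]] <-
        new_confusion_table(tp = tp, fp = n_neg - tn,
                            fn = n_pos - tp, tn = tn)
    }
  }
  structure(list(consistent = consistent,
                 unique = length(tables) == 1,
                 tables = tables, tp_candidates = tp_cand,
                 tn_candidates = tn_cand,
                 n_pos = n_pos, n_neg = n_neg,
                 sens_printed = sens_printed, spec_printed = spec_printed),
            class = "table_reconstruction")
}

#' @export
print.table_reconstruction <- function(x, ...) {
  if (!x$consistent) {
    cat(sprintf(
      "inconsistent: no integer table on margins %d/%d yields %.1f%%/%.1f%%\n",
      x$n_pos, x$n_neg, x$sens_printed, x$spec_printed))
  } else if (x$unique) {
    cat("unique reconstruction:\n")
    print(x$tables[[1]])
  } else {
    cat(sprintf("%d candidate tables (tp in {%s}, tn in {%s})\n",
                length(x$tables), paste(x$tp_candidates, collapse = ", "),
                paste(x$tn_candidates, collapse = ", ")))
  }
  invisible(x)
}
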