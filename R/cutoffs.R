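#' Zero-false-positive-rate cutoff
#'
#' The cutoff selected at a specificity of 100% on the derivation sample:
#' `cutoff = max(good_values)` with the strict rule "marker > cutoff". By
#' construction no good-outcome subject is rule-positive, so the derivation
#' FPR is exactly 0; a poor-outcome subject whose value ties the cutoff is
#' rule-negative and counts against sensitivity.
#'
#' @param good_values Marker values of the good-outcome (negative) group.
#' @param poor_values Marker values of the poor-outcome (positive) group.
#' @return An object of class `adcr_zero_fpr`: list with `cutoff_value`,
#'   `rule` (display string), `derivation_sensitivity`.
#' @export
#' @examples
#' zero_fpr_cutoff(c(1, 2, 3), c(2.5, 4, 5))  # cutoff 3, sensitivity 2/3
zero_fpr_cutoff <- function(good_values, poor_values) {
  if (!length(good_values) || !length(poor_values))
    stop("both groups must be non-empty")
  cutoff <- max(good_values)
  structure(
    list(cutoff_value = cutoff,
         rule = sprintf("marker > %.1f", cutoff),
         derivation_sensitivity = mean(poor_values > cutoff)),
    class = "adcr_zero_fpr"
  )
}

#' @export
print.adcr_zero_fpr <- function(x, ...) {
  cat(sprintf("Zero-FPR rule: marker > %g (derivation sensitivity %.1f%%, specificity 100%%)\n",
              x$cutoff_value, 100 * x$derivation_sensitivity))
  invisible(x)
}

#' Confusion counts for a strict threshold rule
#'
#' Applies the rule "marker > cutoff" (positive prediction = poor outcome):
#' TP = poor & positive, FP = good & positive, FN = poor & negative,
#' TN = good & negative.
#'
#' @param values Marker values.
#' @param outcomes Outcome labels (`"good"`/`"poor"`, logical or 0/1 with
#'   1 = poor).
#' @param cutoff Rule cutoff c in "marker > c".
#' @return An object of class `adcr_confusion`: list with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_at_rule <- function(values, outcomes, cutoff) {
  pos <- as_positive(outcomes)
  stopifnot(length(values) == length(pos))
  pred <- values > cutoff
  structure(
    list(tp = sum(pos & pred), fp = sum(!pos & pred),
         fn = sum(pos & !pred), tn = sum(!pos & !pred)),
    class = "adcr_confusion"
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Interval from beta-distribution quantiles: the lower bound is 0 when no
#' successes are observed and the upper bound is 1 when all trials succeed.
#' At `successes = n` the lower bound has the closed form
#' `(alpha/2)^(1/n)`.
#'
#' @param successes,n Observed successes out of n trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)` on the proportion scale.
#' @export
#' @examples
#' clopper_pearson(86, 86)  # lower bound 0.958
#' clopper_pearson(0, 10)   # (0, 0.3085)
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("need 0 <= successes <= n")
  a <- 1 - level
  lo <- if (successes == 0) 0 else qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else qbeta(1 - a / 2, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

#' Diagnostic performance metrics with exact confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV (in percent) from confusion counts,
#' each with a Clopper-Pearson 95% CI. A metric with a zero denominator (e.g.
#' PPV when nothing is rule-positive) is reported as `NA`, never as 0.
#'
#' @param counts An [confusion_at_rule()] result, or a list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `adcr_performance`: data.frame with one row per
#'   metric and columns `metric`, `estimate`, `lo`, `hi` (percent).
#' @export
#' @examples
#' diagnostic_metrics(list(tp = 127, fp = 53, fn = 11, tn = 33))
diagnostic_metrics <- function(counts, level = 0.95) {
  with(counts, {
    if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
    one <- function(metric, x, n) {
      if (n == 0) return(data.frame(metric = metric, estimate = NA_real_,
                                    lo = NA_real_, hi = NA_real_))
      ci <- clopper_pearson(x, n, level)
      data.frame(metric = metric, estimate = 100 * x / n,
                 lo = 100 * ci[["lo"]], hi = 100 * ci[["hi"]])
    }
    out <- rbind(one("sensitivity", tp, tp + fn),
                 one("specificity", tn, tn + fp),
                 one("ppv", tp, tp + fp),
                 one("npv", tn, tn + fn))
    class(out) <- c("adcr_performance", "data.frame")
    out
  })
}

#' @export
print.adcr_performance <- function(x, ...) {
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, 1)
  df$ci <- ifelse(is.na(df$lo), "n/a",
                  sprintf("(%.1f-%.1f)", df$lo, df$hi))
  print(df[, c("metric", "estimate", "ci")], row.names = FALSE)
  invisible(x)
}
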