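#' Derive zero-FPR prognostic cutoffs from a derivation cohort
#'
#' The central fitting function: for every threshold x on the grid it takes
#' the per-subject ADC-R(x) values, computes the empirical AUC with its
#' DeLong variance and Wald CI, derives the zero-false-positive-rate cutoff
#' (the rule "ADC-R(x) > c" with c = max over good-outcome subjects),
#' evaluates sensitivity/specificity/PPV/NPV with exact Clopper-Pearson CIs at
#' that rule, and runs the paired DeLong test against the reference threshold
#' (the reference row itself is reported as `NA`, rendered "Reference").
#'
#' @param data Data.frame of per-subject profiles, e.g. from
#'   [quantify_manifest()] or [simulate.adcr_sim_spec()]: one `adcr_<x>`
#'   column per threshold plus an outcome column.
#' @param outcome Name of the outcome column (`"good"`/`"poor"`, logical or
#'   0/1 with 1 = poor).
#' @param reference Reference threshold x for the DeLong comparisons
#'   (default 600).
#' @param level Confidence level for all intervals (default 0.95).
#' @return An object of class `adcr_cutoffs` with components `table` (one row
#'   per threshold), `cutoffs` (named vector), `thresholds`, `reference`,
#'   `n_good`, `n_poor` and the per-group marker values (for plotting and
#'   validation). Methods: [print.adcr_cutoffs()], `summary`, `coef`
#'   (the cutoff vector), [predict.adcr_cutoffs()], `plot`.
#' @seealso [validate_cutoffs()], [run_study()]
#' @export
#' @examples
#' spec <- cohort_spec(30, 30, seed = 42)
#' prof <- simulate(spec, nsim = 1)
#' fit <- adcr_derive(prof)
#' fit
#' coef(fit)[["adcr_600"]]
adcr_derive <- function(data, outcome = "outcome", reference = 600,
                        level = 0.95) {
  cols <- grep("^adcr_[0-9.]+$", names(data), value = TRUE)
  if (!length(cols)) stop("no adcr_<x> profile columns found")
  thresholds <- as.numeric(sub("^adcr_", "", cols))
  o <- order(thresholds); thresholds <- thresholds[o]; cols <- cols[o]
  pos <- as_positive(data[[outcome]])
  if (!any(pos) || all(pos))
    stop("derivation cohort must contain both outcomes")
  if (!reference %in% thresholds)
    stop(sprintf("reference threshold %g is not on the grid", reference))
  good <- as.matrix(data[!pos, cols, drop = FALSE])
  poor <- as.matrix(data[pos, cols, drop = FALSE])
  ref_col <- cols[thresholds == reference]

  rows <- lapply(seq_along(cols), function(k) {
    g <- good[, k]; p <- poor[, k]
    auc <- empirical_auc(p, g)
    v <- delong_variance(p, g)
    ci <- auc_ci(auc, v, level)
    zf <- zero_fpr_cutoff(g, p)
    cm <- confusion_at_rule(c(g, p), rep(c(0, 1), c(length(g), length(p))),
                            zf$cutoff_value)
    met <- diagnostic_metrics(cm, level)
    dl_p <- if (cols[k] == ref_col) NA_real_ else
      delong_test(data[[cols[k]]], data[[ref_col]], pos)$p
    est <- function(mm) met$estimate[met$metric == mm]
    lo <- function(mm) met$lo[met$metric == mm]
    hi <- function(mm) met$hi[met$metric == mm]
    data.frame(
      threshold = thresholds[k], auc = auc, auc_var = v,
      auc_lo = ci[["lo"]], auc_hi = ci[["hi"]], band = auc_band(auc),
      cutoff = zf$cutoff_value,
      sensitivity = est("sensitivity"), sens_lo = lo("sensitivity"),
      sens_hi = hi("sensitivity"),
      specificity = est("specificity"), spec_lo = lo("specificity"),
      spec_hi = hi("specificity"),
      ppv = est("ppv"), ppv_lo = lo("ppv"), ppv_hi = hi("ppv"),
      npv = est("npv"), npv_lo = lo("npv"), npv_hi = hi("npv"),
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
      delong_p = dl_p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(
    list(table = tab,
         cutoffs = setNames(tab$cutoff, cols),
         thresholds = thresholds, reference = reference,
         n_good = nrow(good), n_poor = nrow(poor),
         values = list(good = good, poor = poor),
         level = level, call = match.call()),
    class = "adcr_cutoffs"
  )
}

#' @export
print.adcr_cutoffs <- function(x, ...) {
  cat(sprintf("Zero-FPR ADC-R cutoffs: derivation cohort n = %d (%d good / %d poor outcome)\n",
              x$n_good + x$n_poor, x$n_good, x$n_poor))
  cat(sprintf("Reference threshold: ADC-R(%g)\n\n", x$reference))
  t <- x$table
  df <- data.frame(
    threshold = sprintf("ADC-R(%g)", t$threshold),
    AUC = sprintf("%.3f (%.3f-%.3f)", t$auc, t$auc_lo, t$auc_hi),
    cutoff = sprintf("> %.1f", t$cutoff),
    sensitivity = sprintf("%.1f (%.1f-%.1f)", t$sensitivity, t$sens_lo, t$sens_hi),
    specificity = sprintf("%.1f (%.1f-%.1f)", t$specificity, t$spec_lo, t$spec_hi),
    p_vs_ref = ifelse(is.na(t$delong_p), "Reference",
                      ifelse(t$delong_p < 0.001, "< 0.001",
                             sprintf("%.3f", t$delong_p))))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.adcr_cutoffs <- function(object, ...) {
  best <- object$table[which.max(object$table$auc), ]
  cat(sprintf("Derivation cohort: %d good, %d poor outcome subjects\n",
              object$n_good, object$n_poor))
  cat(sprintf("Best performer: ADC-R(%g), AUC %.3f (%s), rule > %.1f, sensitivity %.1f%% at 100%% specificity\n",
              best$threshold, best$auc, best$band, best$cutoff,
              best$sensitivity))
  print(object)
  invisible(object$table)
}

#' @export
coef.adcr_cutoffs <- function(object, ...) object$cutoffs

#' Apply derived cutoff rules to new subjects
#'
#' @param object An [adcr_derive()] fit.
#' @param newdata Data.frame with the same `adcr_<x>` profile columns.
#' @param type `"class"` returns per-subject predicted outcomes
#'   (`"poor"`/`"good"`) for each threshold's frozen rule; `"metrics"`
#'   requires an outcome column in `newdata` and returns the validation table
#'   from [validate_cutoffs()].
#' @param thresholds Thresholds to use (default: all fitted).
#' @param outcome Outcome column name for `type = "metrics"`.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.adcr_cutoffs <- function(object, newdata, type = c("class", "metrics"),
                                 thresholds = object$thresholds,
                                 outcome = "outcome", ...) {
  type <- match.arg(type)
  cols <- profile_cols(thresholds)
  miss <- setdiff(cols, names(newdata))
  if (length(miss))
    stop("newdata lacks profile columns: ", paste(miss, collapse = ", "))
  if (type == "metrics")
    return(validate_cutoffs(object, newdata, thresholds = thresholds,
                            outcome = outcome))
  pred <- vapply(cols, function(cc)
    ifelse(newdata[[cc]] > object$cutoffs[[cc]], "poor", "good"),
    character(nrow(newdata)))
  pred <- matrix(pred, nrow = nrow(newdata),
                 dimnames = list(newdata$subject_id, cols))
  as.data.frame(pred, stringsAsFactors = FALSE)
}

#' Plot the empirical ROC curve for fitted thresholds
#'
#' @param x An [adcr_derive()] fit.
#' @param thresholds Thresholds to draw (default: the reference threshold).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.adcr_cutoffs <- function(x, thresholds = x$reference, ...) {
  cols <- profile_cols(thresholds)
  plot(c(0, 1), c(0, 1), type = "n", xlab = "False-positive rate",
       ylab = "True-positive rate", main = "Empirical ROC", ...)
  abline(0, 1, lty = 3, col = "grey")
  for (i in seq_along(cols)) {
    rc <- roc_curve(x$values$poor[, cols[i]], x$values$good[, cols[i]])
    lines(rc$fpr, rc$tpr, col = i + 1, lwd = 2)
  }
  legend("bottomright",
         legend = sprintf("ADC-R(%g): AUC %.3f", thresholds,
                          x$table$auc[match(thresholds, x$table$threshold)]),
         col = seq_along(cols) + 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Residual-style diagnostics: per-subject margin to the rule
#'
#' For each subject and threshold, the signed distance of the marker value to
#' the frozen cutoff (positive = rule-positive). Useful for spotting subjects
#' that sit on the decision boundary.
#'
#' @param object An [adcr_derive()] fit.
#' @param ... Unused.
#' @return Matrix (subjects x thresholds) of `value - cutoff`.
#' @export
residuals.adcr_cutoffs <- function(object, ...) {
  vals <- rbind(object$values$good, object$values$poor)
  sweep(vals, 2, object$cutoffs)
}
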