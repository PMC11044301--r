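#' Empirical AUC (Mann-Whitney form)
#'
#' The empirical area under the ROC curve: the mean over all (positive,
#' negative) pairs of the kernel that scores 1 when the positive value
#' exceeds the negative, 0.5 on a tie and 0 otherwise. Computed via midranks,
#' which is algebraically identical to the pairwise mean and to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param pos_values Marker values of the positive (poor-outcome) group.
#' @param neg_values Marker values of the negative (good-outcome) group.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' empirical_auc(c(3, 5), c(1, 4))  # 0.75
empirical_auc <- function(pos_values, neg_values) {
  m <- length(pos_values); n <- length(neg_values)
  if (m == 0 || n == 0) stop("both groups must be non-empty")
  r <- rank(c(pos_values, neg_values))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components: V10[i] = mean_j psi(pos_i, neg_j),
# V01[j] = mean_i psi(pos_i, neg_j), with the 1/0.5/0 kernel psi.
delong_components <- function(pos_values, neg_values) {
  psi <- outer(pos_values, neg_values,
               function(p, q) (p > q) + 0.5 * (p == q))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong variance of the empirical AUC
#'
#' Variance estimate from the structural components:
#' `var(V10)/m + var(V01)/n` with sample variances (n-1 denominators). As a
#' rank statistic it is invariant under strictly increasing transforms of the
#' marker.
#'
#' @inheritParams empirical_auc
#' @return Non-negative variance estimate.
#' @export
#' @examples
#' delong_variance(c(3, 5), c(1, 4))  # 0.125
delong_variance <- function(pos_values, neg_values) {
  m <- length(pos_values); n <- length(neg_values)
  if (m < 2 || n < 2) stop("DeLong variance needs >= 2 subjects per group")
  comp <- delong_components(pos_values, neg_values)
  var(comp$v10) / m + var(comp$v01) / n
}

#' DeLong test comparing two AUCs
#'
#' Paired design (both markers measured on the same subjects): the z statistic
#' uses the DeLong covariance from shared structural components,
#' `z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov)`. Unpaired design (two
#' independent cohorts): `z = (AUC_a - AUC_b) / sqrt(var_a + var_b)`. The
#' p-value is two-sided from the standard normal. A degenerate (zero)
#' variance denominator yields p = 1 when the AUC difference is 0 and an
#' error otherwise.
#'
#' @param marker_a,marker_b Marker values. In the paired design both are
#'   indexed by the same subjects and share `labels`; in the unpaired design
#'   `marker_b` belongs to a second cohort labelled by `labels_b`.
#' @param labels Binary outcome labels for `marker_a` (and for `marker_b`
#'   when paired): `"poor"`/`"good"`, logical, or 0/1 with 1 = positive.
#' @param labels_b Outcome labels for the second cohort (unpaired only).
#' @param design `"paired"` or `"unpaired"`; inferred from `labels_b` when
#'   missing.
#' @return An object of class `adcr_delong`: list with `auc_a`, `auc_b`, `z`,
#'   `p`, `design`.
#' @export
#' @examples
#' y <- rep(c(1, 0), each = 20)
#' a <- rnorm(40, y); b <- rnorm(40)
#' delong_test(a, b, y)
delong_test <- function(marker_a, marker_b, labels, labels_b = NULL,
                        design = if (is.null(labels_b)) "paired" else "unpaired") {
  design <- match.arg(design, c("paired", "unpaired"))
  pos <- as_positive(labels)
  if (design == "paired") {
    if (length(marker_a) != length(marker_b) ||
        length(marker_a) != length(pos))
      stop("paired design needs markers and labels on the same subjects")
    ca <- delong_components(marker_a[pos], marker_a[!pos])
    cb <- delong_components(marker_b[pos], marker_b[!pos])
    m <- sum(pos); n <- sum(!pos)
    if (m < 2 || n < 2) stop("DeLong test needs >= 2 subjects per group")
    v <- var(ca$v10) / m + var(ca$v01) / n +
         var(cb$v10) / m + var(cb$v01) / n -
         2 * (cov(ca$v10, cb$v10) / m + cov(ca$v01, cb$v01) / n)
  } else {
    if (is.null(labels_b)) stop("unpaired design needs labels_b")
    posb <- as_positive(labels_b)
    ca <- delong_components(marker_a[pos], marker_a[!pos])
    cb <- delong_components(marker_b[posb], marker_b[!posb])
    v <- delong_variance(marker_a[pos], marker_a[!pos]) +
         delong_variance(marker_b[posb], marker_b[!posb])
  }
  diff <- ca$auc - cb$auc
  if (v <= .Machine$double.eps) {
    if (abs(diff) < 1e-12) {
      z <- 0; p <- 1
    } else stop("degenerate variance: AUCs differ but estimated variance is 0")
  } else {
    z <- diff / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = p,
                 design = design),
            class = "adcr_delong")
}

#' @export
print.adcr_delong <- function(x, ...) {
  cat(sprintf("DeLong %s test: AUC %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$design, x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

# Coerce outcome labels to logical "is positive / poor outcome".
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  l <- tolower(as.character(labels))
  if (all(l %in% c("poor", "good"))) return(l == "poor")
  stop("labels must be logical, 0/1, or \"good\"/\"poor\"")
}

#' Wald confidence interval for an AUC
#'
#' Normal-approximation interval `auc +/- z * sqrt(variance)`, clipped to
#' \[0, 1\].
#'
#' @param auc Point estimate.
#' @param variance DeLong variance estimate (>= 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
#' @examples
#' auc_ci(0.8, 0.0025)  # (0.702, 0.898)
auc_ci <- function(auc, variance, level = 0.95) {
  stopifnot(variance >= 0)
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(variance)
  c(lo = max(0, auc - half), hi = min(1, auc + half))
}

#' Empirical ROC curve
#'
#' All operating points of the rule "marker > c" as c sweeps the observed
#' values; starts at (0, 0) and ends at (1, 1) with both coordinates
#' non-decreasing.
#'
#' @inheritParams empirical_auc
#' @return Data.frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(pos_values, neg_values) {
  if (!length(pos_values) || !length(neg_values))
    stop("both groups must be non-empty")
  cuts <- sort(unique(c(pos_values, neg_values)), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) mean(pos_values >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(neg_values >= c), numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Qualitative AUC performance band
#'
#' Maps an AUC to the conventional labels: 0.50-0.69 poor, 0.70-0.79 fair,
#' 0.80-0.89 good, 0.90-1.00 excellent; values below 0.50 are labelled
#' "worse than chance".
#'
#' @param auc AUC value(s) in \[0, 1\].
#' @return Character vector of labels.
#' @export
#' @examples
#' auc_band(c(0.49, 0.69, 0.79, 0.89, 0.909))
auc_band <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  out <- character(length(auc))
  out[auc < 0.5] <- "worse than chance"
  out[auc >= 0.5 & auc < 0.7] <- "poor"
  out[auc >= 0.7 & auc < 0.8] <- "fair"
  out[auc >= 0.8 & auc < 0.9] <- "good"
  out[auc >= 0.9] <- "excellent"
  out
}
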