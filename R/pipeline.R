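#' Study configuration
#'
#' Bundles the analysis settings of the derivation/validation design: the
#' 70/30 derivation split, the threshold grid and voxel filter, the DeLong
#' reference threshold and the significance level.
#'
#' @param split_fraction Fraction of unassigned subjects allocated to the
#'   derivation cohort (default 0.70).
#' @param split_seed Seed for the random split.
#' @param grid A [threshold_grid()].
#' @param filter A [voxel_filter()].
#' @param scale_factor Voxel value multiplier applied when loading maps.
#' @param reference_threshold Reference x for DeLong comparisons
#'   (default 600).
#' @param alpha Significance level (default 0.05).
#' @param stratified Stratify the split by outcome? Default `FALSE`
#'   (simple random split).
#' @param fallback_segmentation Allow threshold-based brain extraction when a
#'   subject has no mask? Default `FALSE`.
#' @return An object of class `adcr_config`.
#' @export
study_config <- function(split_fraction = 0.7, split_seed = 1L,
                         grid = threshold_grid(), filter = voxel_filter(),
                         scale_factor = 1, reference_threshold = 600,
                         alpha = 0.05, stratified = FALSE,
                         fallback_segmentation = FALSE) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)")
  structure(
    list(split_fraction = split_fraction, split_seed = as.integer(split_seed),
         grid = grid, filter = filter, scale_factor = scale_factor,
         reference_threshold = reference_threshold, alpha = alpha,
         stratified = stratified,
         fallback_segmentation = fallback_segmentation),
    class = "adcr_config"
  )
}

#' Read a study configuration from YAML
#'
#' Recognised keys: `split_fraction`, `split_seed`, `scale_factor`,
#' `reference_threshold`, `alpha`, `stratified`, `grid: {start, stop, step}`,
#' `filter: {lower, upper}`.
#'
#' @param path YAML file path.
#' @return An `adcr_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  filter <- if (is.null(y$filter)) voxel_filter() else
    voxel_filter(y$filter$lower %||% 200, y$filter$upper %||% 2000)
  grid <- if (is.null(y$grid)) threshold_grid(filter = filter) else
    threshold_grid(y$grid$start %||% 250, y$grid$stop %||% 1150,
                   y$grid$step %||% 50, filter = filter)
  study_config(
    split_fraction = y$split_fraction %||% 0.7,
    split_seed = y$split_seed %||% 1L,
    grid = grid, filter = filter,
    scale_factor = y$scale_factor %||% 1,
    reference_threshold = y$reference_threshold %||% 600,
    alpha = y$alpha %||% 0.05,
    stratified = isTRUE(y$stratified),
    fallback_segmentation = isTRUE(y$fallback_segmentation)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split unassigned subjects into derivation and internal-validation cohorts
#'
#' Simple random split: `round(n * split_fraction)` subjects to the
#' derivation cohort, the remainder to internal validation; deterministic
#' under `split_seed`. Rows already labelled (e.g. `external_validation`) are
#' left untouched. With `stratified = TRUE` the split is carried out within
#' each outcome group.
#'
#' @param subjects Data.frame with a `cohort` column (`"unassigned"` rows are
#'   split) and, for stratified splits, an `outcome` column.
#' @param config A [study_config()].
#' @return The data.frame with `cohort` filled in.
#' @export
split_cohort <- function(subjects, config = study_config()) {
  un <- which(subjects$cohort == "unassigned")
  n <- length(un)
  if (n < 10) stop("need at least 10 unassigned subjects to split")
  pick <- with_seed(config$split_seed, {
    if (config$stratified) {
      pos <- as_positive(subjects$outcome[un])
      c(sample(un[pos], round(sum(pos) * config$split_fraction)),
        sample(un[!pos], round(sum(!pos) * config$split_fraction)))
    } else {
      sample(un, round(n * config$split_fraction))
    }
  })
  subjects$cohort[un] <- "internal_validation"
  subjects$cohort[pick] <- "derivation"
  subjects
}

#' Derive the per-threshold cutoff table for a derivation cohort
#'
#' Convenience wrapper around [adcr_derive()] using the config's reference
#' threshold.
#'
#' @param derivation Data.frame of derivation-cohort profiles.
#' @param config A [study_config()].
#' @return An `adcr_cutoffs` fit.
#' @export
derive_cutoffs <- function(derivation, config = study_config()) {
  adcr_derive(derivation, reference = config$reference_threshold,
              level = 1 - config$alpha)
}

#' Apply frozen derivation cutoffs to a validation cohort
#'
#' Each rule "ADC-R(x) > c" derived on the derivation cohort is applied
#' unchanged; specificity may now fall below 100%. The cohort's own AUC (with
#' DeLong variance and CI) is also recomputed for cross-cohort comparisons.
#'
#' @param fit An [adcr_derive()] object.
#' @param cohort Data.frame of validation-cohort profiles (same grid).
#' @param thresholds Thresholds to validate (default: all fitted).
#' @param outcome Outcome column name.
#' @return Data.frame, one row per threshold: cutoff, confusion counts,
#'   metrics with exact CIs, AUC with CI.
#' @export
validate_cutoffs <- function(fit, cohort, thresholds = fit$thresholds,
                             outcome = "outcome") {
  cols <- profile_cols(thresholds)
  miss <- setdiff(cols, names(cohort))
  if (length(miss))
    stop("threshold grids mismatch; cohort lacks: ", paste(miss, collapse = ", "))
  pos <- as_positive(cohort[[outcome]])
  rows <- lapply(seq_along(cols), function(k) {
    vals <- cohort[[cols[k]]]
    cutoff <- fit$cutoffs[[cols[k]]]
    cm <- confusion_at_rule(vals, pos, cutoff)
    met <- diagnostic_metrics(cm, fit$level)
    auc <- empirical_auc(vals[pos], vals[!pos])
    v <- delong_variance(vals[pos], vals[!pos])
    ci <- auc_ci(auc, v, fit$level)
    est <- function(mm) met$estimate[met$metric == mm]
    lo <- function(mm) met$lo[met$metric == mm]
    hi <- function(mm) met$hi[met$metric == mm]
    data.frame(
      threshold = thresholds[k], cutoff = cutoff,
      auc = auc, auc_var = v, auc_lo = ci[["lo"]], auc_hi = ci[["hi"]],
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
      sensitivity = est("sensitivity"), sens_lo = lo("sensitivity"),
      sens_hi = hi("sensitivity"),
      specificity = est("specificity"), spec_lo = lo("specificity"),
      spec_hi = hi("specificity"),
      ppv = est("ppv"), ppv_lo = lo("ppv"), ppv_hi = hi("ppv"),
      npv = est("npv"), npv_lo = lo("npv"), npv_hi = hi("npv"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare a literature rule against the derived rule at one threshold
#'
#' Evaluates both the historical rule "ADC-R(x) > 10%" and the derived
#' zero-FPR rule in every cohort: confusion counts and metrics per
#' cohort-rule combination.
#'
#' @param cohorts Named list of profile data.frames (e.g. derivation,
#'   internal_validation, external_validation).
#' @param fit An [adcr_derive()] object supplying the derived cutoff.
#' @param x Threshold (default 650, the historical rule's threshold).
#' @param literature_cutoff The historical cutoff (default 10%).
#' @param outcome Outcome column name.
#' @return Data.frame, one row per cohort x rule.
#' @export
external_rule_comparison <- function(cohorts, fit, x = 650,
                                     literature_cutoff = 10,
                                     outcome = "outcome") {
  cc <- profile_cols(x)
  derived <- fit$cutoffs[[cc]]
  if (is.null(derived)) stop(sprintf("threshold %g not in fitted grid", x))
  rules <- c(literature = literature_cutoff, derived = derived)
  rows <- list()
  for (coh in names(cohorts)) {
    df <- cohorts[[coh]]
    if (!cc %in% names(df))
      stop(sprintf("cohort %s lacks column %s", coh, cc))
    pos <- as_positive(df[[outcome]])
    for (rn in names(rules)) {
      cm <- confusion_at_rule(df[[cc]], pos, rules[[rn]])
      met <- diagnostic_metrics(cm, fit$level)
      est <- function(mm) met$estimate[met$metric == mm]
      lo <- function(mm) met$lo[met$metric == mm]
      hi <- function(mm) met$hi[met$metric == mm]
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = coh, rule = sprintf("> %.1f%%", rules[[rn]]),
        rule_origin = rn, threshold = x,
        fp = cm$fp, fn = cm$fn, tp = cm$tp, tn = cm$tn,
        sensitivity = est("sensitivity"), sens_lo = lo("sensitivity"),
        sens_hi = hi("sensitivity"),
        specificity = est("specificity"), spec_lo = lo("specificity"),
        spec_hi = hi("specificity"),
        ppv = est("ppv"), npv = est("npv"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Baseline covariate comparison across cohorts
#'
#' Continuous covariates: median (IQR) per cohort, Kruskal-Wallis p across
#' the three cohorts, and Bonferroni-corrected pairwise Mann-Whitney flags
#' against the derivation cohort (threshold alpha/3). Categorical covariates:
#' count (%) per cohort with a chi-square or Fisher p. Missing covariate
#' columns are skipped with a logged warning.
#'
#' @param cohorts Named list of profile data.frames; must include
#'   `derivation`.
#' @param covariates Character vector of covariate column names.
#' @param alpha Family-wise significance level.
#' @return Data.frame, one row per covariate: per-cohort summaries, `p`,
#'   `test`, and pairwise flag columns.
#' @export
baseline_table <- function(cohorts,
                           covariates = c("age", "sex", "shockable_rhythm",
                                          "low_flow_min"),
                           alpha = 0.05) {
  stopifnot("derivation" %in% names(cohorts))
  others <- setdiff(names(cohorts), "derivation")
  rows <- list()
  for (cv in covariates) {
    present <- vapply(cohorts, function(d) cv %in% names(d), logical(1))
    if (!all(present)) {
      adcr_log(sprintf("covariate '%s' missing in cohort(s) %s; skipped",
                       cv, paste(names(cohorts)[!present], collapse = ", ")),
               level = "WARN")
      next
    }
    vals <- lapply(cohorts, function(d) d[[cv]])
    if (is.numeric(vals[[1]]) && length(unique(unlist(vals))) > 5) {
      summ <- vapply(vals, function(v)
        sprintf("%.1f (%.1f-%.1f)", median(v), quantile(v, 0.25),
                quantile(v, 0.75)), character(1))
      kw <- kruskal_wallis_with_posthoc(vals[c("derivation", others)], alpha)
      flags <- vapply(others, function(oth)
        mann_whitney(vals$derivation, vals[[oth]])$p < alpha / 3, logical(1))
      p <- kw$p; test <- "kruskal-wallis"
    } else {
      lev <- sort(unique(as.character(unlist(vals))))
      tab <- vapply(vals, function(v)
        as.numeric(table(factor(v, levels = lev))), numeric(length(lev)))
      tab <- matrix(tab, nrow = length(lev),
                    dimnames = list(lev, names(vals)))
      summ <- vapply(names(vals), function(coh)
        sprintf("%d (%.1f%%)", tab[length(lev), coh],
                100 * tab[length(lev), coh] / sum(tab[, coh])), character(1))
      ct <- categorical_tests(tab[, c("derivation", others), drop = FALSE])
      p <- ct$p; test <- ct$method
      flags <- setNames(rep(NA, length(others)), others)
    }
    row <- data.frame(covariate = cv, t(summ), p = p, test = test,
                      stringsAsFactors = FALSE)
    for (oth in others) row[[paste0("flag_", oth)]] <- flags[[oth]]
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Cross-cohort DeLong comparisons for a threshold range
#'
#' Unpaired DeLong tests of the same ADC-R(x) between the derivation cohort
#' and each validation cohort, for x from 450 to 650 by default.
#'
#' @param cohorts Named list of profile data.frames including `derivation`.
#' @param thresholds Thresholds to compare.
#' @param outcome Outcome column name.
#' @return Data.frame: threshold, comparison cohort, both AUCs, z, p.
#' @export
cross_cohort_delong <- function(cohorts, thresholds = seq(450, 650, 50),
                                outcome = "outcome") {
  others <- setdiff(names(cohorts), "derivation")
  rows <- list()
  for (x in thresholds) {
    cc <- profile_cols(x)
    der <- cohorts$derivation
    for (oth in others) {
      d2 <- cohorts[[oth]]
      dl <- delong_test(der[[cc]], d2[[cc]], der[[outcome]],
                        labels_b = d2[[outcome]], design = "unpaired")
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = x, cohort = oth, auc_derivation = dl$auc_a,
        auc_cohort = dl$auc_b, z = dl$z, p = dl$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full derivation / internal / external validation study
#'
#' End-to-end orchestration: quantify every manifest subject, split the
#' unassigned site 70/30 into derivation and internal-validation cohorts,
#' derive zero-FPR cutoffs per threshold, apply them frozen to both
#' validation cohorts, compare the historical "> 10%" rule against the
#' derived rule at x = 650, build the baseline covariate table and the
#' cross-cohort DeLong comparisons. All randomness comes from the config's
#' `split_seed`, so reruns are byte-identical.
#'
#' @param manifest Manifest CSV path or data.frame (see
#'   [quantify_manifest()]).
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, the report CSVs
#'   (`table1_baseline.csv`, `table2_derivation.csv`, `table3_applied.csv`,
#'   `table4_rules.csv`, `fig3_delong.csv`) and a `summary.txt` are written
#'   via [write_report()].
#' @param base_dir Base directory for relative manifest paths when `manifest`
#'   is a data.frame.
#' @return An object of class `adcr_study`: profiles, the `adcr_cutoffs` fit,
#'   per-cohort validation tables, the rule-comparison and baseline tables,
#'   cross-cohort DeLong results and cohort sizes.
#' @export
run_study <- function(manifest, config = study_config(), out_dir = NULL,
                      base_dir = NULL) {
  profiles <- quantify_manifest(manifest, config, base_dir = base_dir)
  profiles <- split_cohort(profiles, config)
  cohorts <- split(profiles, profiles$cohort)
  if (!"derivation" %in% names(cohorts))
    stop("no derivation cohort after splitting")
  adcr_log(sprintf("cohort sizes: %s",
                   paste(sprintf("%s=%d", names(cohorts),
                                 vapply(cohorts, nrow, integer(1))),
                         collapse = ", ")))
  fit <- derive_cutoffs(cohorts$derivation, config)
  val_names <- intersect(c("internal_validation", "external_validation"),
                         names(cohorts))
  applied <- lapply(cohorts[c("derivation", val_names)], function(coh)
    validate_cutoffs(fit, coh, thresholds = intersect(seq(450, 650, 50),
                                                      fit$thresholds)))
  table4 <- external_rule_comparison(cohorts[c("derivation", val_names)], fit)
  baseline <- baseline_table(cohorts)
  fig3 <- cross_cohort_delong(cohorts)
  study <- structure(
    list(profiles = profiles, fit = fit, applied = applied,
         table4 = table4, baseline = baseline, fig3 = fig3,
         sizes = vapply(cohorts, nrow, integer(1)), config = config),
    class = "adcr_study"
  )
  if (!is.null(out_dir)) write_report(study, out_dir)
  study
}

#' @export
print.adcr_study <- function(x, ...) {
  cat("ADC-R derivation / validation study\n")
  cat(sprintf("  cohorts: %s\n",
              paste(sprintf("%s n=%d", names(x$sizes), x$sizes),
                    collapse = ", ")))
  best <- x$fit$table[which.max(x$fit$table$auc), ]
  cat(sprintf("  best derivation performer: ADC-R(%g), AUC %.3f (%s), rule > %.1f\n",
              best$threshold, best$auc, best$band, best$cutoff))
  for (coh in names(x$applied)) {
    ref <- x$applied[[coh]]
    r <- ref[ref$threshold == x$config$reference_threshold, ]
    if (nrow(r))
      cat(sprintf("  %s at ADC-R(%g) > %.1f: sensitivity %.1f%%, specificity %.1f%%\n",
                  coh, r$threshold, r$cutoff, r$sensitivity, r$specificity))
  }
  invisible(x)
}

#' Write a study report as a set of CSV tables
#'
#' Writes `table1_baseline.csv`, `table2_derivation.csv`,
#' `table3_applied.csv`, `table4_rules.csv`, `fig3_delong.csv` and a
#' human-readable `summary.txt`. CSVs carry full-precision columns; display
#' rounding (AUC to 3, percentages to 1 decimal) happens only in the summary.
#'
#' @param study An [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$baseline, file.path(out_dir, "table1_baseline.csv"),
            row.names = FALSE)
  write.csv(study$fit$table, file.path(out_dir, "table2_derivation.csv"),
            row.names = FALSE)
  applied <- do.call(rbind, lapply(names(study$applied), function(coh)
    cbind(cohort = coh, study$applied[[coh]])))
  write.csv(applied, file.path(out_dir, "table3_applied.csv"),
            row.names = FALSE)
  write.csv(study$table4, file.path(out_dir, "table4_rules.csv"),
            row.names = FALSE)
  write.csv(study$fig3, file.path(out_dir, "fig3_delong.csv"),
            row.names = FALSE)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(study)
  print(study$fit)
  invisible(out_dir)
}
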