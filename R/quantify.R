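#' Analysable-voxel filter
#'
#' Voxels with ADC below `lower` or above `upper` (1e-6 mm^2/s) are excluded
#' from analysis to suppress artefact, noise and free-fluid contributions.
#' Both interval ends are treated as closed: values exactly at 200 or 2000 are
#' kept. The source phrasing excludes values "above 2000 and below 200"
#' without fixing the boundary itself; for continuous data the choice is
#' measure-zero but is pinned down here for reproducibility.
#'
#' @param lower,upper Bounds in 1e-6 mm^2/s (defaults 200 and 2000).
#' @return An object of class `adcr_filter`.
#' @export
voxel_filter <- function(lower = 200, upper = 2000) {
  if (lower >= upper) stop("filter lower bound must be < upper bound")
  structure(list(lower = lower, upper = upper), class = "adcr_filter")
}

#' Threshold grid for ADC-R(x)
#'
#' The analysis thresholds x: by default every 50 units from 250 to 1150
#' (19 interior thresholds of the 200-1200 range). Each threshold must lie
#' strictly above the filter's lower bound and at or below its upper bound.
#'
#' @param start,stop,step Grid construction parameters (1e-6 mm^2/s).
#' @param thresholds Explicit thresholds, overriding start/stop/step.
#' @param filter A [voxel_filter()] used to validate range.
#' @return An object of class `adcr_grid` with element `thresholds`.
#' @export
threshold_grid <- function(start = 250, stop = 1150, step = 50,
                           thresholds = NULL, filter = voxel_filter()) {
  if (is.null(thresholds)) thresholds <- seq(start, stop, by = step)
  thresholds <- as.numeric(thresholds)
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (any(thresholds <= filter$lower | thresholds > filter$upper))
    stop(sprintf("thresholds must lie in (%g, %g]", filter$lower, filter$upper))
  structure(list(thresholds = thresholds), class = "adcr_grid")
}

#' Column names used for ADC-R(x) values in profile tables
#'
#' @param thresholds Numeric thresholds.
#' @return Character vector like `"adcr_600"`.
#' @export
profile_cols <- function(thresholds) sprintf("adcr_%g", thresholds)

#' Load an ADC volume (and optional brain mask) from NIfTI
#'
#' @param path Path to a 3-D NIfTI ADC map.
#' @param scale_factor Multiplier applied to voxel values; use `1e6` for maps
#'   stored in mm^2/s to obtain the package's working units of 1e-6 mm^2/s.
#' @param mask_path Optional path to a NIfTI binary mask of identical shape.
#' @return An object of class `adcr_volume`: list with `voxels` (3-D array),
#'   `pixdim` (voxel size, mm) and `mask` (3-D logical array or `NULL`).
#' @export
load_adc_volume <- function(path, scale_factor = 1, mask_path = NULL) {
  if (!file.exists(path)) stop(sprintf("ADC volume not found: %s", path))
  img <- RNifti::readNifti(path)
  vox <- as.array(img) * scale_factor
  if (length(dim(vox)) != 3L)
    stop(sprintf("expected a 3-D volume, got %d dimensions in %s",
                 length(dim(vox)), path))
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) stop(sprintf("mask not found: %s", mask_path))
    m <- as.array(RNifti::readNifti(mask_path))
    if (!identical(dim(m), dim(vox)))
      stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                   paste(dim(m), collapse = "x"),
                   paste(dim(vox), collapse = "x")))
    mask <- m != 0
  }
  structure(list(voxels = vox, pixdim = RNifti::pixdim(img)[1:3], mask = mask),
            class = "adcr_volume")
}

#' Extract the brain voxel values from an ADC volume
#'
#' With a mask, returns the in-mask voxel values. Without a mask and with
#' `fallback_segmentation = TRUE`, returns voxels in (0, 3500\] — a crude
#' positivity-threshold brain proxy that is NOT equivalent to skull-stripping
#' and should only be used when no extraction mask is available.
#'
#' @param vol An [load_adc_volume()] result (or a compatible list).
#' @param fallback_segmentation Allow the threshold-based fallback when no
#'   mask is present? Default `FALSE`.
#' @return Numeric vector of brain ADC values.
#' @export
extract_brain_values <- function(vol, fallback_segmentation = FALSE) {
  if (!is.null(vol$mask)) {
    if (!any(vol$mask)) stop("empty brain mask")
    return(vol$voxels[vol$mask])
  }
  if (!fallback_segmentation)
    stop("no brain mask present and fallback segmentation disabled")
  v <- vol$voxels
  v[v > 0 & v <= 3500]
}

#' The ADC-R(x) voxel-fraction statistic
#'
#' ADC-R(x) is the percentage of analysable brain voxels whose ADC lies in
#' \[200, x\]:
#' `100 * #\{v : lower <= v <= x\} / #\{v : lower <= v <= upper\}`.
#' Counts are integer voxel counts; there is no interpolation. Non-finite
#' values are counted as excluded, never silently dropped.
#'
#' @param values Numeric vector of brain ADC values (1e-6 mm^2/s).
#' @param x Threshold in 1e-6 mm^2/s, inside `(filter$lower, filter$upper]`.
#' @param filter A [voxel_filter()].
#' @return ADC-R(x) in percent.
#' @export
#' @examples
#' adc_r(c(100, 250, 400, 650, 900, 1500, 2100), 600)  # 40%
adc_r <- function(values, x, filter = voxel_filter()) {
  if (length(x) != 1L || x <= filter$lower || x > filter$upper)
    stop(sprintf("threshold x must lie in (%g, %g]", filter$lower, filter$upper))
  keep <- is.finite(values) & values >= filter$lower & values <= filter$upper
  den <- sum(keep)
  if (den == 0) stop("no analysable voxels")
  100 * sum(values[keep] <= x) / den
}

#' Per-subject ADC-R profile over a threshold grid
#'
#' Computes ADC-R(x) at every grid threshold with one shared denominator (the
#' analysable voxel count), plus the exclusion tallies. Non-finite in-mask
#' values count towards `excluded_low`.
#'
#' @param values Numeric vector of brain ADC values.
#' @param grid A [threshold_grid()].
#' @param filter A [voxel_filter()].
#' @return An object of class `adcr_profile`: list with `values` (named
#'   vector, percent per threshold), `thresholds`, `denominator_count`,
#'   `excluded_low`, `excluded_high`.
#' @export
adc_r_profile <- function(values, grid = threshold_grid(),
                          filter = voxel_filter()) {
  finite <- is.finite(values)
  keep <- finite & values >= filter$lower & values <= filter$upper
  den <- sum(keep)
  if (den == 0) stop("no analysable voxels")
  kept <- values[keep]
  pr <- vapply(grid$thresholds, function(x) 100 * sum(kept <= x) / den,
               numeric(1))
  names(pr) <- profile_cols(grid$thresholds)
  structure(
    list(values = pr, thresholds = grid$thresholds,
         denominator_count = den,
         excluded_low = sum(!finite | (finite & values < filter$lower)),
         excluded_high = sum(finite & values > filter$upper)),
    class = "adcr_profile"
  )
}

#' @export
print.adcr_profile <- function(x, ...) {
  cat(sprintf("ADC-R profile over %d thresholds (%g..%g); %d analysable voxels (%d low / %d high excluded)\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              x$denominator_count, x$excluded_low, x$excluded_high))
  print(round(x$values, 1))
  invisible(x)
}

#' Quantify every subject in a cohort manifest
#'
#' Reads each subject's ADC volume and mask, extracts the brain values and
#' computes the ADC-R profile. Image paths are resolved relative to the
#' manifest's directory. Subjects with missing CPC are dropped with a logged
#' count. Any per-subject failure aborts with the subject id in the message.
#'
#' @param manifest Path to a manifest CSV (columns `subject_id, adc_path,
#'   mask_path, outcome_cpc, cohort`, extra columns carried through) or an
#'   equivalent data.frame (paths then resolved against `base_dir`).
#' @param config A [study_config()] (supplies grid, filter, scale factor).
#' @param base_dir Directory against which relative paths resolve when
#'   `manifest` is a data.frame.
#' @return Data.frame with one row per subject: id, cohort, `cpc`, `outcome`
#'   (`"good"`/`"poor"`), one `adcr_<x>` column per threshold, exclusion
#'   tallies, and any covariate columns from the manifest.
#' @export
quantify_manifest <- function(manifest, config = study_config(),
                              base_dir = NULL) {
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  req <- c("subject_id", "adc_path", "mask_path", "outcome_cpc", "cohort")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stop("manifest lacks required columns: ", paste(miss, collapse = ", "))
  has_cpc <- !is.na(manifest$outcome_cpc)
  if (any(!has_cpc)) {
    adcr_log(sprintf("excluding %d subject(s) with missing CPC", sum(!has_cpc)))
    manifest <- manifest[has_cpc, , drop = FALSE]
  }
  grid <- config$grid; filter <- config$filter
  prof <- matrix(NA_real_, nrow(manifest), length(grid$thresholds))
  extra <- matrix(NA_integer_, nrow(manifest), 3,
                  dimnames = list(NULL, c("denominator_count",
                                          "excluded_low", "excluded_high")))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    p <- tryCatch({
      vol <- load_adc_volume(
        file.path(base_dir, manifest$adc_path[i]),
        scale_factor = config$scale_factor,
        mask_path = if (is.na(manifest$mask_path[i]) || manifest$mask_path[i] == "")
          NULL else file.path(base_dir, manifest$mask_path[i]))
      vals <- extract_brain_values(vol, fallback_segmentation = config$fallback_segmentation)
      adc_r_profile(vals, grid, filter)
    }, error = function(e)
      stop(sprintf("quantification failed for subject %s: %s",
                   sid, conditionMessage(e)), call. = FALSE))
    prof[i, ] <- p$values
    extra[i, ] <- c(p$denominator_count, p$excluded_low, p$excluded_high)
  }
  colnames(prof) <- profile_cols(grid$thresholds)
  cpc <- as.integer(manifest$outcome_cpc)
  out <- data.frame(subject_id = manifest$subject_id,
                    cohort = manifest$cohort,
                    cpc = cpc,
                    outcome = ifelse(cpc >= 3, "poor", "good"),
                    stringsAsFactors = FALSE)
  covar <- setdiff(names(manifest), c(req, "outcome_cpc"))
  cbind(out, as.data.frame(prof), as.data.frame(extra),
        manifest[, covar, drop = FALSE])
}
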