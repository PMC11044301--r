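#' Generate a synthetic ADC cohort on disk
#'
#' Writes one NIfTI ADC volume and one binary brain mask per subject, plus a
#' cohort manifest CSV with columns `subject_id, adc_path, mask_path,
#' outcome_cpc, cohort` (paths relative to the manifest). Good-outcome
#' subjects get a CPC drawn from \{1, 2\}, poor-outcome subjects from
#' \{3, 4, 5\}. Optional demographic covariates (age, sex, shockable rhythm,
#' low-flow time) are appended so baseline-comparison tables can be exercised;
#' they are drawn independently of outcome. The ground-truth lesion fraction
#' is recorded per subject. Output is byte-identical across runs with the same
#' spec.
#'
#' @param spec An [cohort_spec()] object.
#' @param out_dir Writable output directory (created if needed).
#' @param cohort_label Cohort label written to every manifest row
#'   (`"unassigned"` for a site that will be split 70/30 downstream,
#'   `"external_validation"` for an external site).
#' @param prefix Subject-id prefix.
#' @param covariates Append synthetic demographics? Default `TRUE`.
#' @return The manifest as a data.frame (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
#' @examples
#' \donttest{
#' spec <- cohort_spec(3, 5, volume_shape = c(10, 10, 8), seed = 7)
#' man <- generate_cohort(spec, tempfile("cohort"))
#' table(man$outcome_cpc >= 3)
#' }
generate_cohort <- function(spec, out_dir, cohort_label = "unassigned",
                            prefix = "S", covariates = TRUE) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  outcomes <- rep(c("good", "poor"), c(spec$n_good, spec$n_poor))
  n <- length(outcomes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("%s%04d", prefix, i)
    sampled <- sample_subject_voxels(spec, outcomes[i], i)
    vol <- render_volume(sampled, spec, i)
    adc_rel <- file.path("images", paste0(sid, "_adc.nii.gz"))
    mask_rel <- file.path("images", paste0(sid, "_mask.nii.gz"))
    ok <- tryCatch({
      write_nifti_volume(vol$image, spec$voxel_size, file.path(out_dir, adc_rel))
      write_nifti_volume(vol$mask, spec$voxel_size, file.path(out_dir, mask_rel))
      TRUE
    }, error = function(e)
      stop(sprintf("failed writing subject %s under %s: %s",
                   sid, out_dir, conditionMessage(e))))
    demo <- with_rng_state(subject_stream(spec$seed, i, part = 3L), {
      cpc <- if (outcomes[i] == "good") sample(1:2, 1) else sample(3:5, 1)
      list(cpc = cpc,
           age = round(min(max(rnorm(1, 58, 14), 18), 95)),
           sex = sample(c("male", "female"), 1, prob = c(0.73, 0.27)),
           shockable_rhythm = sample(c(1L, 0L), 1, prob = c(0.38, 0.62)),
           low_flow_min = round(exp(rnorm(1, log(21), 0.6)), 1))
    })
    rows[[i]] <- data.frame(
      subject_id = sid, adc_path = adc_rel, mask_path = mask_rel,
      outcome_cpc = demo$cpc, cohort = cohort_label,
      lesion_fraction = sampled$f,
      age = demo$age, sex = demo$sex,
      shockable_rhythm = demo$shockable_rhythm,
      low_flow_min = demo$low_flow_min,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!covariates)
    manifest <- manifest[, c("subject_id", "adc_path", "mask_path",
                             "outcome_cpc", "cohort", "lesion_fraction")]
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
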