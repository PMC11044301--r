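test_that("degenerate mixtures produce single-component samples", {
  gp <- list(good = outcome_group_params(csf_fraction = 0, fixed_f = 0),
             poor = outcome_group_params(csf_fraction = 0, fixed_f = 0))
  spec <- small_spec(group_params = gp)
  s <- sample_subject_voxels(spec, "good", 1)
  expect_equal(s$f, 0)
  expect_true(all(s$class == "parenchyma"))
  tm <- spec$tissue_models$parenchyma
  expect_true(all(s$values >= tm$truncation[1] & s$values <= tm$truncation[2]))
})

test_that("sampled values respect truncation bounds for every tissue", {
  spec <- small_spec(seed = 3)
  s <- sample_subject_voxels(spec, "poor", 2)
  for (cls in levels(s$class)) {
    tm <- spec$tissue_models[[cls]]
    v <- s$values[s$class == cls]
    expect_true(all(v >= tm$truncation[1] & v <= tm$truncation[2]))
  }
})

test_that("fixed 50% lesion burden puts half the mass below 600 (binomial bound)", {
  tm <- list(parenchyma = tissue_model("parenchyma", 800, 1, c(795, 805)),
             csf = tissue_model("csf", 2600, 400, c(1800, 3500)),
             lesion = tissue_model("lesion", 450, 1, c(445, 455)))
  gp <- list(good = outcome_group_params(csf_fraction = 0, fixed_f = 0.5),
             poor = outcome_group_params(csf_fraction = 0, fixed_f = 0.5))
  spec <- cohort_spec(1, 1, volume_shape = c(20, 20, 14),
                      tissue_models = tm, group_params = gp, seed = 9)
  s <- sample_subject_voxels(spec, "poor", 1)
  frac <- mean(s$values < 600)
  se <- sqrt(0.25 / length(s$values))
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("sampling is deterministic under a fixed seed and independent of call order", {
  spec <- small_spec(seed = 7)
  a <- sample_subject_voxels(spec, "poor", 4)
  b <- sample_subject_voxels(spec, "poor", 4)
  expect_identical(a, b)
  # another subject's draw in between must not perturb subject 4's stream
  invisible(sample_subject_voxels(spec, "good", 2))
  expect_identical(sample_subject_voxels(spec, "poor", 4), a)
})

test_that("analytic ADC-R oracle hits its closed-form anchors", {
  spec <- small_spec()
  f <- 0.25
  expect_equal(expected_adc_r(spec, f, 2000), 100)
  expect_equal(expected_adc_r(spec, f, 200), 0)
  expect_error(expected_adc_r(spec, f, 2100), "threshold")
  # lesion entirely below 600, parenchyma entirely above, no CSF, f = 0.5
  tm <- list(parenchyma = tissue_model("parenchyma", 800, 50, c(650, 1200)),
             csf = tissue_model("csf", 2600, 400, c(1800, 3500)),
             lesion = tissue_model("lesion", 450, 30, c(350, 550)))
  gp <- list(good = outcome_group_params(csf_fraction = 0, fixed_f = 0.5),
             poor = outcome_group_params(csf_fraction = 0, fixed_f = 0.5))
  spec2 <- small_spec(tissue_models = tm, group_params = gp)
  expect_equal(expected_adc_r(spec2, 0.5, 600), 50)
})

test_that("rendering conserves the voxel multiset and is spatially irrelevant to ADC-R", {
  spec <- small_spec(seed = 21)
  s <- sample_subject_voxels(spec, "poor", 3)
  vol <- render_volume(s, spec, 3)
  expect_equal(sum(vol$mask), length(s$values))   # count conservation
  inmask <- vol$image[vol$mask == 1]
  expect_equal(sort(inmask), sort(s$values))      # multiset conservation
  for (x in c(400, 600, 900))
    expect_identical(adc_r(inmask, x), adc_r(s$values, x))
  # out-of-mask voxels are zero
  expect_true(all(vol$image[vol$mask == 0] == 0))
})

test_that("lesion voxels form contiguous blobs, not salt-and-pepper", {
  # value-disjoint tissue models so lesion voxels are identifiable by value
  tm <- list(parenchyma = tissue_model("parenchyma", 800, 100, c(400, 1400)),
             csf = tissue_model("csf", 2600, 400, c(1800, 3500)),
             lesion = tissue_model("lesion", 300, 60, c(210, 390)))
  gp <- list(good = outcome_group_params(fixed_f = 0.2),
             poor = outcome_group_params(fixed_f = 0.2))
  spec <- small_spec(group_params = gp, tissue_models = tm, seed = 5)
  s <- sample_subject_voxels(spec, "poor", 1)
  vol <- render_volume(s, spec, 1)
  les <- vol$mask == 1 & vol$image >= 210 & vol$image <= 390
  # a blobby lesion has most lesion voxels adjacent to another lesion voxel
  idx <- which(les, arr.ind = TRUE)
  skip_if(nrow(idx) < 20)
  has_neighbour <- vapply(seq_len(nrow(idx)), function(i) {
    d <- abs(sweep(idx, 2, idx[i, ]))
    any(rowSums(d) == 1)
  }, logical(1))
  expect_gt(mean(has_neighbour), 0.9)
})

test_that("rendered volumes survive a NIfTI round trip with identical histograms", {
  spec <- small_spec(seed = 13)
  s <- sample_subject_voxels(spec, "good", 1)
  vol <- render_volume(s, spec, 1)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol$image, spec$voxel_size, f)
  back <- RNifti::readNifti(f)
  expect_identical(as.vector(as.array(back)), as.vector(vol$image))
})

test_that("generate_cohort writes a complete, reproducible manifest", {
  spec <- small_spec(3, 5, seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  man <- generate_cohort(spec, d1)
  expect_equal(nrow(man), 8)
  expect_equal(sum(man$outcome_cpc >= 3), 5)
  expect_true(all(man$outcome_cpc[man$outcome_cpc < 3] %in% 1:2))
  expect_true(all(file.exists(file.path(d1, man$adc_path))))
  expect_true(all(file.exists(file.path(d1, man$mask_path))))
  generate_cohort(spec, d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
})

test_that("empirical profiles of generated subjects agree with the analytic oracle", {
  spec <- small_spec(4, 4, seed = 29, shape = c(20, 20, 14))
  d <- withr::local_tempdir()
  man <- generate_cohort(spec, d)
  prof <- quantify_manifest(file.path(d, "manifest.csv"))
  grid <- threshold_grid()
  for (i in seq_len(nrow(man))) {
    outc <- ifelse(man$outcome_cpc[i] >= 3, "poor", "good")
    expected <- expected_adc_r(spec, man$lesion_fraction[i],
                               grid$thresholds, outcome = outc)
    got <- as.numeric(prof[i, profile_cols(grid$thresholds)])
    p <- expected / 100
    se <- 100 * sqrt(pmax(p * (1 - p), 1e-12) / prof$denominator_count[i])
    expect_true(all(abs(got - expected) <= 4 * se + 1e-9),
                info = sprintf("subject %d", i))
  }
})

test_that("expected AUC is monotone in the poor-group burden gap", {
  # common random numbers: per-subject streams depend only on (seed, index),
  # and burden draws are quantile transforms, so increasing the poor-group
  # mean burden increases every poor subject's expected ADC-R(600)
  spec0 <- small_spec(30, 30, seed = 31)
  good_f <- vapply(1:30, function(i)
    sample_subject_voxels(spec0, "good", i)$f, numeric(1))
  aucs <- vapply(c(10, 14, 20, 30), function(b2) {
    gp <- list(good = outcome_group_params(2, 60),
               poor = outcome_group_params(4, b2))
    spec <- small_spec(30, 30, seed = 31, group_params = gp)
    poor_f <- vapply(31:60, function(i)
      sample_subject_voxels(spec, "poor", i)$f, numeric(1))
    empirical_auc(vapply(poor_f, function(f) expected_adc_r(spec, f, 600),
                         numeric(1)),
                  vapply(good_f, function(f) expected_adc_r(spec, f, 600),
                         numeric(1)))
  }, numeric(1))
  # larger shape2 means smaller mean burden: AUC must be non-increasing
  expect_true(all(diff(aucs) <= 1e-12))
})

test_that("cohort spec validates its invariants and round-trips through YAML", {
  expect_error(cohort_spec(0, 0), "n_good")
  expect_error(cohort_spec(2, 2, volume_shape = c(4, 10, 10)), "volume_shape")
  expect_error(outcome_group_params(csf_fraction = 0.5), "csf_fraction")
  expect_error(
    cohort_spec(1, 1, group_params = list(
      good = outcome_group_params(csf_fraction = 0.3, fixed_f = 0.8),
      poor = outcome_group_params())),
    "negative|fixed_f")
  spec <- small_spec(3, 4, seed = 99)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, f)
  expect_equal(read_cohort_spec(f), spec, ignore_attr = TRUE)
})
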