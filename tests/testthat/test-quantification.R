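test_that("ADC-R matches the hand-counted example and its edge cases", {
  vals <- c(100, 250, 400, 650, 900, 1500, 2100)
  expect_equal(adc_r(vals, 600), 40)        # numerator {250,400} / denominator of 5
  expect_equal(adc_r(vals, 2000), 100)
  expect_error(adc_r(rep(2500, 4), 600), "no analysable voxels")
  expect_error(adc_r(vals, 200), "threshold")
  # boundary values exactly at 200 and 2000 are kept (closed intervals)
  expect_equal(adc_r(c(200, 2000), 600), 50)
})

test_that("ADC-R equals a brute-force count oracle on integer multisets", {
  set.seed(42)
  filter <- voxel_filter()
  for (rep in 1:25) {
    vals <- sample(0:2500, 40, replace = TRUE)
    x <- sample(seq(250, 1150, 50), 1)
    den <- 0; num <- 0
    for (v in vals) {
      if (v >= 200 && v <= 2000) {
        den <- den + 1
        if (v <= x) num <- num + 1
      }
    }
    if (den == 0) {
      expect_error(adc_r(vals, x), "no analysable voxels")
    } else {
      expect_identical(adc_r(vals, x), 100 * num / den)
    }
  }
})

test_that("profiles have 19 default thresholds, are monotone and share one denominator", {
  set.seed(7)
  vals <- c(rnorm(300, 500, 150), rnorm(500, 900, 200), rnorm(50, 2600, 300))
  p <- adc_r_profile(vals)
  expect_length(p$values, 19)
  expect_identical(p$thresholds, seq(250, 1150, 50))
  expect_true(all(diff(p$values) >= 0))
  expect_true(all(p$values >= 0 & p$values <= 100))
  expect_equal(p$denominator_count + p$excluded_low + p$excluded_high,
               length(vals))
})

test_that("values entirely above the grid give an all-zero profile", {
  p <- adc_r_profile(runif(100, 1200, 2000))
  expect_true(all(p$values == 0))
})

test_that("non-finite in-mask values are tallied as excluded, never dropped silently", {
  vals <- c(500, 700, NA, NaN, Inf, -50, 2500)
  p <- adc_r_profile(vals)
  expect_equal(p$denominator_count, 2)
  expect_equal(p$excluded_low, 4)   # NA, NaN, Inf(non-finite), -50; Inf counted low
  expect_equal(p$excluded_high, 1)
})

test_that("ADC-R is invariant under spatial permutation of in-mask voxels", {
  set.seed(11)
  vals <- rnorm(500, 800, 300)
  p1 <- adc_r_profile(vals)
  p2 <- adc_r_profile(sample(vals))
  expect_identical(p1$values, p2$values)
})

test_that("volumes load with scaling and masks of wrong shape are refused", {
  d <- withr::local_tempdir()
  arr <- array(8e-4, dim = c(10, 10, 6))   # stored in mm^2/s
  write_nifti_volume(arr, c(2, 2, 2), file.path(d, "adc.nii.gz"))
  vol <- load_adc_volume(file.path(d, "adc.nii.gz"), scale_factor = 1e6)
  expect_equal(unname(vol$voxels[1, 1, 1]), 800)
  write_nifti_volume(array(1, dim = c(9, 10, 6)), c(2, 2, 2),
                     file.path(d, "mask.nii.gz"))
  expect_error(
    load_adc_volume(file.path(d, "adc.nii.gz"),
                    mask_path = file.path(d, "mask.nii.gz")),
    "9x10x6.*10x10x6")
  expect_error(load_adc_volume(file.path(d, "nope.nii.gz")), "not found")
})

test_that("brain extraction uses the mask, falls back only when allowed", {
  vol <- list(voxels = array(c(500, 800, 4000, -10), c(2, 2, 1)),
              mask = array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)))
  expect_equal(sort(extract_brain_values(vol)), c(500, 800))
  vol_nm <- list(voxels = vol$voxels, mask = NULL)
  expect_error(extract_brain_values(vol_nm), "fallback")
  # fallback keeps (0, 3500] only
  expect_equal(sort(extract_brain_values(vol_nm, fallback_segmentation = TRUE)),
               c(500, 800))
  vol_empty <- list(voxels = vol$voxels,
                    mask = array(FALSE, c(2, 2, 1)))
  expect_error(extract_brain_values(vol_empty), "empty brain mask")
})

test_that("all-ones mask returns every voxel", {
  vox <- array(rnorm(27, 800, 100), c(3, 3, 3))
  vol <- list(voxels = vox, mask = array(TRUE, c(3, 3, 3)))
  expect_equal(sort(extract_brain_values(vol)), sort(as.vector(vox)))
})

test_that("threshold grid and filter validate their invariants", {
  expect_error(threshold_grid(thresholds = c(300, 300, 400)), "increasing")
  expect_error(threshold_grid(thresholds = c(150, 300)), "thresholds")
  expect_error(threshold_grid(thresholds = 2100), "thresholds")
  expect_error(voxel_filter(2000, 200), "lower")
  g <- threshold_grid()
  expect_equal(g$thresholds, seq(250, 1150, 50))
})

test_that("quantified synthetic subjects round-trip the generator multiset", {
  spec <- small_spec(1, 1, seed = 51)
  d <- withr::local_tempdir()
  man <- generate_cohort(spec, d)
  vol <- load_adc_volume(file.path(d, man$adc_path[1]),
                         mask_path = file.path(d, man$mask_path[1]))
  vals <- extract_brain_values(vol)
  s <- sample_subject_voxels(spec, ifelse(man$outcome_cpc[1] >= 3, "poor", "good"), 1)
  expect_equal(sort(vals), sort(s$values))
})
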