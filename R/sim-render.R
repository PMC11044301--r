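#' Render sampled voxel values into a spatial ADC volume
#'
#' Places the sampled value multiset inside the spec's ellipsoidal brain mask:
#' CSF values fill a central (ventricle-like) region, lesion values form 1-5
#' contiguous ellipsoidal blobs, parenchyma fills the remainder; voxels
#' outside the mask are 0. The in-mask value multiset of the rendered volume
#' equals the input multiset exactly, so any voxel-count statistic is
#' unchanged by the spatial arrangement.
#'
#' @param sampled Output of [sample_subject_voxels()].
#' @param spec The [cohort_spec()] used to sample.
#' @param subject_index The subject's RNG stream counter (blob geometry is
#'   drawn from a sub-stream so it is reproducible per subject).
#' @return List with `image` and `mask` (3-D arrays matching
#'   `spec$volume_shape`).
#' @export
render_volume <- function(sampled, spec, subject_index = 1L) {
  mask <- brain_mask_array(spec)
  n_mask <- sum(mask)
  if (length(sampled$values) != n_mask)
    stop(sprintf("value multiset size (%d) does not match in-mask capacity (%d)",
                 length(sampled$values), n_mask))
  d <- spec$volume_shape
  idx <- which(mask, arr.ind = TRUE)      # in-mask voxel coordinates
  ctr <- (d + 1) / 2
  counts <- table(sampled$class)
  n_les <- counts[["lesion"]]; n_csf <- counts[["csf"]]

  # CSF: the n_csf voxels closest to the volume centre (ventricle proxy)
  d_ctr <- sqrt(rowSums((sweep(idx, 2, ctr))^2))
  ord_ctr <- order(d_ctr)
  csf_rows <- if (n_csf > 0) ord_ctr[seq_len(n_csf)] else integer(0)
  free_rows <- setdiff(seq_len(nrow(idx)), csf_rows)

  # Lesion: 1-5 ellipsoidal blobs grown around random centres in free tissue
  les_rows <- integer(0)
  if (n_les > 0) {
    blob <- with_rng_state(subject_stream(spec$seed, subject_index, part = 2L), {
      k <- sample(1:5, 1)
      centres <- idx[sample(free_rows, min(k, length(free_rows))), , drop = FALSE]
      axes <- matrix(runif(3 * nrow(centres), 0.5, 2), ncol = 3)
      list(centres = centres, axes = axes)
    })
    dmin <- rep(Inf, length(free_rows))
    for (b in seq_len(nrow(blob$centres))) {
      db <- sqrt(rowSums(sweep(idx[free_rows, , drop = FALSE], 2,
                               blob$centres[b, ])^2 /
                         matrix(blob$axes[b, ]^2, length(free_rows), 3,
                                byrow = TRUE)))
      dmin <- pmin(dmin, db)
    }
    les_rows <- free_rows[order(dmin)[seq_len(n_les)]]
  }
  par_rows <- setdiff(free_rows, les_rows)

  img <- array(0, dim = d)
  put <- function(rows, vals) {
    if (length(rows)) img[idx[rows, , drop = FALSE]] <<- vals
  }
  put(les_rows, sampled$values[sampled$class == "lesion"])
  put(csf_rows, sampled$values[sampled$class == "csf"])
  put(par_rows, sampled$values[sampled$class == "parenchyma"])
  list(image = img, mask = array(as.numeric(mask), dim = d))
}

#' Write a 3-D array as a NIfTI-1 volume
#'
#' Uses double-precision on-disk storage so voxel values round-trip exactly.
#'
#' @param arr 3-D numeric array.
#' @param voxel_size Numeric 3-vector, mm per axis.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(arr, voxel_size, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
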