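#' Specification of a synthetic ADC cohort
#'
#' Bundles everything needed to generate a reproducible synthetic cohort:
#' group sizes, the voxel grid, the three tissue models, the per-group lesion
#' burden distributions and a master seed. All generator output is a pure
#' function of this object.
#'
#' @param n_good,n_poor Number of subjects with good (CPC 1-2) and poor
#'   (CPC 3-5) 6-month outcome.
#' @param volume_shape Integer 3-vector of voxel counts per axis (each >= 8).
#' @param voxel_size Numeric 3-vector, mm per axis.
#' @param tissue_models Named list with elements `parenchyma`, `csf`,
#'   `lesion`, each a [tissue_model()].
#' @param group_params Named list with elements `good` and `poor`, each an
#'   [outcome_group_params()].
#' @param seed Master integer seed; per-subject streams are derived from it by
#'   counter, so a subject's image never depends on cohort composition order.
#' @return An object of class `adcr_sim_spec`.
#' @seealso [generate_cohort()], [simulate.adcr_sim_spec()], [expected_adc_r()]
#' @export
#' @examples
#' spec <- cohort_spec(n_good = 3, n_poor = 5, seed = 1)
#' spec
cohort_spec <- function(n_good, n_poor,
                        volume_shape = c(32L, 32L, 20L),
                        voxel_size = c(7.5, 7.5, 6),
                        tissue_models = default_tissue_models(),
                        group_params = default_group_params(),
                        seed = 1L) {
  n_good <- as.integer(n_good); n_poor <- as.integer(n_poor)
  if (n_good < 0 || n_poor < 0 || n_good + n_poor < 1)
    stop("need n_good >= 0, n_poor >= 0 and n_good + n_poor >= 1")
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L))
    stop("volume_shape must be 3 entries, each >= 8")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  stopifnot(all(c("parenchyma", "csf", "lesion") %in% names(tissue_models)))
  stopifnot(all(c("good", "poor") %in% names(group_params)))
  for (m in tissue_models[c("parenchyma", "csf", "lesion")])
    if (!inherits(m, "adcr_tissue_model")) stop("tissue_models entries must be tissue_model()")
  for (g in group_params[c("good", "poor")]) {
    if (!inherits(g, "adcr_group_params")) stop("group_params entries must be outcome_group_params()")
    # mixture weights (f, csf, 1 - f - csf) must never go negative
    if (!is.null(g$fixed_f) && g$fixed_f + g$csf_fraction > 1)
      stop("mixture weights can be negative: fixed_f + csf_fraction > 1")
  }
  structure(
    list(n_good = n_good, n_poor = n_poor,
         volume_shape = volume_shape, voxel_size = as.numeric(voxel_size),
         tissue_models = tissue_models[c("parenchyma", "csf", "lesion")],
         group_params = group_params[c("good", "poor")],
         seed = as.integer(seed)),
    class = "adcr_sim_spec"
  )
}

#' @export
print.adcr_sim_spec <- function(x, ...) {
  cat("Synthetic ADC cohort specification\n")
  cat(sprintf("  subjects: %d good + %d poor outcome\n", x$n_good, x$n_poor))
  cat(sprintf("  grid: %s voxels @ %s mm (%d in brain mask)\n",
              paste(x$volume_shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              sum(brain_mask_array(x))))
  for (m in x$tissue_models)
    cat(sprintf("  %-10s N(%g, %g) truncated [%g, %g]\n", m$name,
                m$mean_adc, m$sd_adc, m$truncation[1], m$truncation[2]))
  for (g in names(x$group_params)) {
    gp <- x$group_params[[g]]
    if (is.null(gp$fixed_f))
      cat(sprintf("  %s burden ~ Beta(%g, %g), CSF fraction %g\n",
                  g, gp$shape1, gp$shape2, gp$csf_fraction))
    else
      cat(sprintf("  %s burden fixed at %g, CSF fraction %g\n",
                  g, gp$fixed_f, gp$csf_fraction))
  }
  cat(sprintf("  master seed: %d\n", x$seed))
  invisible(x)
}

#' Read or write a cohort specification as YAML
#'
#' @param spec An `adcr_sim_spec`.
#' @param path File path.
#' @return `read_cohort_spec()` returns an `adcr_sim_spec`;
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "adcr_sim_spec"))
  tm <- lapply(spec$tissue_models, function(m)
    list(mean_adc = m$mean_adc, sd_adc = m$sd_adc,
         truncation = m$truncation))
  gp <- lapply(spec$group_params, function(g)
    list(shape1 = g$shape1, shape2 = g$shape2,
         csf_fraction = g$csf_fraction, fixed_f = g$fixed_f))
  yaml::write_yaml(
    list(n_good = spec$n_good, n_poor = spec$n_poor,
         volume_shape = spec$volume_shape, voxel_size = spec$voxel_size,
         tissue_models = tm, group_params = gp, seed = spec$seed),
    path
  )
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  tm <- lapply(names(y$tissue_models), function(nm) {
    m <- y$tissue_models[[nm]]
    tissue_model(nm, m$mean_adc, m$sd_adc, unlist(m$truncation))
  })
  names(tm) <- names(y$tissue_models)
  gp <- lapply(y$group_params, function(g)
    outcome_group_params(g$shape1, g$shape2, g$csf_fraction,
                         fixed_f = g$fixed_f))
  cohort_spec(y$n_good, y$n_poor, unlist(y$volume_shape),
              unlist(y$voxel_size), tm, gp, y$seed)
}
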