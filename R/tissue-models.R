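#' Truncated-normal tissue model for synthetic ADC volumes
#'
#' Describes the ADC distribution of one tissue class as a normal distribution
#' truncated to a physiological range. All values are in units of
#' 1e-6 mm^2/s.
#'
#' @param name One of `"parenchyma"`, `"csf"`, `"lesion"`.
#' @param mean_adc,sd_adc Mean and standard deviation of the untruncated
#'   normal.
#' @param truncation Length-2 numeric `c(low, high)`; sampled values always
#'   fall inside this interval.
#' @return An object of class `adcr_tissue_model`.
#' @seealso [default_tissue_models()]
#' @export
#' @examples
#' tissue_model("lesion", 450, 90, c(200, 700))
tissue_model <- function(name, mean_adc, sd_adc, truncation) {
  name <- match.arg(name, c("parenchyma", "csf", "lesion"))
  stopifnot(is.numeric(mean_adc), length(mean_adc) == 1L,
            is.numeric(sd_adc), length(sd_adc) == 1L,
            is.numeric(truncation), length(truncation) == 2L)
  if (sd_adc <= 0) stop("sd_adc must be > 0")
  if (truncation[1] >= truncation[2]) stop("truncation low must be < high")
  structure(
    list(name = name, mean_adc = mean_adc, sd_adc = sd_adc,
         truncation = as.numeric(truncation)),
    class = "adcr_tissue_model"
  )
}

#' Default tissue models for the three-class ADC phantom
#'
#' Parenchyma N(800, 100) truncated to \[400, 1400\]; CSF N(2600, 400)
#' truncated to \[1800, 3500\], so part of the CSF mass is removed by the
#' 2000 upper analysis bound as it is on real maps; hypoxic-ischaemic lesion
#' N(450, 90) truncated to \[200, 700\], consistent with the clinically
#' meaningful 450-650 band of reduced diffusion.
#'
#' @return Named list of three [tissue_model()] objects.
#' @export
default_tissue_models <- function() {
  list(
    parenchyma = tissue_model("parenchyma", 800, 100, c(400, 1400)),
    csf        = tissue_model("csf", 2600, 400, c(1800, 3500)),
    lesion     = tissue_model("lesion", 450, 90, c(200, 700))
  )
}

# CDF of the truncated normal at q (vectorised in q).
ptrunc_model <- function(q, model) {
  a <- model$truncation[1]; b <- model$truncation[2]
  za <- pnorm(a, model$mean_adc, model$sd_adc)
  zb <- pnorm(b, model$mean_adc, model$sd_adc)
  p <- (pnorm(pmin(pmax(q, a), b), model$mean_adc, model$sd_adc) - za) / (zb - za)
  pmin(pmax(p, 0), 1)
}

# P(value in [lo, hi]) under the truncated normal.
mass_in <- function(model, lo, hi) {
  ptrunc_model(hi, model) - ptrunc_model(lo, model)
}

# Inverse-CDF sampler for the truncated normal; uses the current RNG stream.
rtrunc_model <- function(n, model) {
  a <- model$truncation[1]; b <- model$truncation[2]
  za <- pnorm(a, model$mean_adc, model$sd_adc)
  zb <- pnorm(b, model$mean_adc, model$sd_adc)
  qnorm(za + runif(n) * (zb - za), model$mean_adc, model$sd_adc)
}

#' Outcome-group parameters for the synthetic cohort
#'
#' Encodes how heavily a subject's brain is affected by hypoxic-ischaemic
#' injury: the per-subject lesion burden f (fraction of in-mask voxels that
#' are lesion) is drawn from a Beta distribution, truncated so the mixture
#' weights (f, csf_fraction, 1 - f - csf_fraction) are always valid. The poor
#' outcome group carries a much heavier burden than the good outcome group.
#'
#' @param shape1,shape2 Beta shape parameters for the lesion-burden
#'   distribution. Ignored when `fixed_f` is given.
#' @param csf_fraction Fixed fraction of in-mask voxels that are CSF; must lie
#'   in \[0, 0.3\].
#' @param fixed_f Optional degenerate burden: every subject gets exactly this
#'   lesion fraction (used for analytic checks).
#' @return An object of class `adcr_group_params`.
#' @export
#' @examples
#' outcome_group_params(2, 60)          # good outcome: mean burden ~3%
#' outcome_group_params(4, 8)           # poor outcome: mean burden ~33%
outcome_group_params <- function(shape1 = 2, shape2 = 60, csf_fraction = 0.1,
                                 fixed_f = NULL) {
  stopifnot(csf_fraction >= 0, csf_fraction <= 0.3)
  if (!is.null(fixed_f)) {
    stopifnot(fixed_f >= 0, fixed_f <= 1 - csf_fraction)
  } else {
    stopifnot(shape1 > 0, shape2 > 0)
  }
  structure(
    list(shape1 = shape1, shape2 = shape2, csf_fraction = csf_fraction,
         fixed_f = fixed_f),
    class = "adcr_group_params"
  )
}

#' @rdname outcome_group_params
#' @export
default_group_params <- function() {
  list(
    good = outcome_group_params(2, 60, csf_fraction = 0.1),
    poor = outcome_group_params(4, 8, csf_fraction = 0.1)
  )
}

# Draw one lesion fraction for a subject: Beta truncated to
# [0, 1 - csf_fraction] via the quantile transform (monotone in the underlying
# uniform, which keeps couplings across parameter settings monotone).
draw_lesion_fraction <- function(gp) {
  if (!is.null(gp$fixed_f)) return(gp$fixed_f)
  cap <- pbeta(1 - gp$csf_fraction, gp$shape1, gp$shape2)
  qbeta(runif(1) * cap, gp$shape1, gp$shape2)
}
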