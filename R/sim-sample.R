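# Ellipsoidal brain mask on the spec's grid: semi-axes 0.45 * shape, centred.
# Deterministic in the spec, so the in-mask voxel count (and hence the
# per-subject sample size N) is fixed across subjects.
brain_mask_array <- function(spec) {
  d <- spec$volume_shape
  ctr <- (d + 1) / 2
  ax <- 0.45 * d
  i <- (seq_len(d[1]) - ctr[1]) / ax[1]
  j <- (seq_len(d[2]) - ctr[2]) / ax[2]
  k <- (seq_len(d[3]) - ctr[3]) / ax[3]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  array(r2 <= 1, dim = d)
}

#' Sample one subject's in-mask ADC voxel values
#'
#' Draws the subject's lesion burden f from the outcome group's distribution,
#' then N in-mask voxel values i.i.d. from the three-component truncated-normal
#' mixture with weights (f, csf_fraction, 1 - f - csf_fraction) for
#' (lesion, CSF, parenchyma). N is the in-mask voxel count of the spec's
#' ellipsoidal brain mask. The draw is a pure function of
#' `(spec, outcome, subject_index)`.
#'
#' @param spec An [cohort_spec()] object.
#' @param outcome `"good"` or `"poor"`.
#' @param subject_index Integer counter identifying the subject's RNG stream.
#' @return List with `values` (numeric vector of ADC values, 1e-6 mm^2/s),
#'   `class` (factor: lesion/csf/parenchyma per value), `f` (the ground-truth
#'   lesion fraction) and `n` (number of values).
#' @export
#' @examples
#' spec <- cohort_spec(1, 1, volume_shape = c(10, 10, 8))
#' s <- sample_subject_voxels(spec, "poor", 1)
#' s$f; length(s$values)
sample_subject_voxels <- function(spec, outcome, subject_index = 1L) {
  outcome <- match.arg(outcome, c("good", "poor"))
  gp <- spec$group_params[[outcome]]
  n <- sum(brain_mask_array(spec))
  with_rng_state(subject_stream(spec$seed, subject_index), {
    f <- draw_lesion_fraction(gp)
    w <- c(lesion = f, csf = gp$csf_fraction,
           parenchyma = 1 - f - gp$csf_fraction)
    if (any(w < 0)) stop("mixture weights can be negative")
    counts <- as.vector(rmultinom(1, n, w))
    names(counts) <- names(w)
    vals <- c(
      rtrunc_model(counts["lesion"], spec$tissue_models$lesion),
      rtrunc_model(counts["csf"], spec$tissue_models$csf),
      rtrunc_model(counts["parenchyma"], spec$tissue_models$parenchyma)
    )
    cls <- factor(rep(c("lesion", "csf", "parenchyma"), counts),
                  levels = c("lesion", "csf", "parenchyma"))
    list(values = vals, class = cls, f = f, n = n)
  })
}

#' Analytic ADC-R(x) under the synthetic mixture
#'
#' Closed-form oracle for the generator: the expected ADC-R(x) of a subject
#' with lesion fraction `f`, computed from truncated-normal CDFs as
#' 100 * P(ADC in \[200, x\]) / P(ADC in \[200, 2000\]) under the
#' three-component mixture. Generated subjects' empirical profiles converge to
#' this value as the voxel count grows.
#'
#' @param spec An [cohort_spec()] object.
#' @param f Lesion fraction in \[0, 1 - csf_fraction\].
#' @param x Threshold(s) in 1e-6 mm^2/s, each inside \[200, 2000\].
#' @param outcome Which group's `csf_fraction` to use (default `"poor"`; both
#'   defaults share it).
#' @param filter A [voxel_filter()] giving the analysable-range bounds.
#' @return Expected ADC-R(x) in percent (vectorised over `x`).
#' @export
#' @examples
#' spec <- cohort_spec(1, 1)
#' expected_adc_r(spec, f = 0.33, x = 600)
expected_adc_r <- function(spec, f, x, outcome = "poor",
                           filter = voxel_filter()) {
  gp <- spec$group_params[[match.arg(outcome, c("good", "poor"))]]
  if (any(x < filter$lower | x > filter$upper))
    stop(sprintf("threshold x must lie in [%g, %g]", filter$lower, filter$upper))
  csf <- gp$csf_fraction
  if (f < 0 || f + csf > 1) stop("lesion fraction incompatible with mixture weights")
  w <- c(lesion = f, csf = csf, parenchyma = 1 - f - csf)
  num <- den <- 0
  for (nm in names(w)) {
    m <- spec$tissue_models[[nm]]
    num <- num + w[[nm]] * mass_in(m, filter$lower, x)
    den <- den + w[[nm]] * mass_in(m, filter$lower, filter$upper)
  }
  as.numeric(100 * num / den)
}

#' Simulate per-subject ADC-R profiles without rendering volumes
#'
#' Profile-level simulation: for each subject, draws the lesion burden, the
#' analysable voxel count D ~ Binomial(N, P(in filter)), and the joint voxel
#' counts below each grid threshold by sequential conditional binomials over
#' the grid bins. For a voxel-count statistic this is distributionally
#' identical to rendering the voxels and quantifying them, at a small fraction
#' of the cost; it is used for large repeated-simulation studies (e.g. DeLong
#' calibration).
#'
#' @param object An [cohort_spec()] object.
#' @param nsim Number of cohorts to simulate.
#' @param seed Master seed (defaults to the spec's seed); cohort `s` uses
#'   stream offsets so cohorts are independent.
#' @param grid A [threshold_grid()].
#' @param filter A [voxel_filter()].
#' @param ... Unused.
#' @return A data.frame (one row per subject, stacked over simulations) with
#'   columns `sim`, `subject_id`, `outcome`, `lesion_fraction`,
#'   `denominator_count` and one `adcr_<x>` column per threshold.
#' @export
#' @examples
#' spec <- cohort_spec(5, 5)
#' sim <- simulate(spec, nsim = 1)
#' sim[, c("outcome", "lesion_fraction", "adcr_600")]
simulate.adcr_sim_spec <- function(object, nsim = 1, seed = NULL,
                                   grid = threshold_grid(),
                                   filter = voxel_filter(), ...) {
  spec <- object
  if (is.null(seed)) seed <- spec$seed
  n_mask <- sum(brain_mask_array(spec))
  xs <- grid$thresholds
  outcomes <- rep(c("good", "poor"), c(spec$n_good, spec$n_poor))
  n_sub <- length(outcomes)
  # per-tissue masses below each threshold / within the filter (shared)
  tm <- spec$tissue_models
  m_le <- lapply(tm, function(m) mass_in(m, filter$lower, xs))
  m_in <- lapply(tm, function(m) mass_in(m, filter$lower, filter$upper))
  out <- vector("list", nsim)
  stream <- cmrg_state(seed)   # advanced once per subject, in counter order
  for (s in seq_len(nsim)) {
    prof <- matrix(NA_real_, n_sub, length(xs))
    fs <- numeric(n_sub); dens <- integer(n_sub)
    for (i in seq_len(n_sub)) {
      gp <- spec$group_params[[outcomes[i]]]
      stream <- parallel::nextRNGStream(stream)
      res <- with_rng_state(stream, {
        f <- draw_lesion_fraction(gp)
        w <- c(lesion = f, csf = gp$csf_fraction,
               parenchyma = 1 - f - gp$csf_fraction)
        p_den <- sum(vapply(names(w), function(nm) w[[nm]] * m_in[[nm]],
                            numeric(1)))
        p_le <- (w[["lesion"]] * m_le$lesion + w[["csf"]] * m_le$csf +
                 w[["parenchyma"]] * m_le$parenchyma) / p_den
        d <- qbinom(runif(1), n_mask, p_den)
        if (d < 1) d <- 1L
        # counts below successive thresholds: conditional binomials over bins
        cnt <- numeric(length(xs))
        prev_cnt <- 0; prev_p <- 0
        u <- runif(length(xs))
        for (k in seq_along(xs)) {
          pk <- p_le[k]
          cond <- if (1 - prev_p <= 0) 0 else (pk - prev_p) / (1 - prev_p)
          cond <- min(max(cond, 0), 1)
          add <- qbinom(u[k], d - prev_cnt, cond)
          cnt[k] <- prev_cnt + add
          prev_cnt <- cnt[k]; prev_p <- pk
        }
        list(f = f, d = d, prof = 100 * cnt / d)
      })
      fs[i] <- res$f; dens[i] <- res$d; prof[i, ] <- res$prof
    }
    df <- data.frame(sim = s,
                     subject_id = sprintf("S%04d", seq_len(n_sub)),
                     outcome = outcomes,
                     lesion_fraction = fs,
                     denominator_count = dens,
                     stringsAsFactors = FALSE)
    colnames(prof) <- profile_cols(xs)
    out[[s]] <- cbind(df, as.data.frame(prof))
  }
  do.call(rbind, out)
}
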