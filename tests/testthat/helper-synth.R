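# Shared fixtures for the synthetic-cohort tests: small grids keep the suite
# fast while leaving enough voxels for binomial bounds to bite.

small_spec <- function(n_good = 5, n_poor = 5, seed = 1,
                       shape = c(14, 14, 10), ...) {
  cohort_spec(n_good, n_poor, volume_shape = shape, seed = seed, ...)
}

# moderate group separation: AUC well inside (0.5, 1), used wherever a
# degenerate (perfectly separating) marker would make the check vacuous
moderate_groups <- function() {
  list(good = outcome_group_params(2, 60),
       poor = outcome_group_params(2.5, 30))
}

# brute-force pairwise AUC oracle (independent of the rank-based path)
auc_bruteforce <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

grid600 <- function() threshold_grid(thresholds = 600)
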