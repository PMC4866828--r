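# Shared synthetic cohort at the fitted human group means, and its
# hierarchical fit. Built lazily and cached so several tests can assert
# different properties of the same (expensive) fit.
#
# The cohort is moment-matched (center = TRUE): the realized transformed
# parameter means equal the group means exactly, so recovery error reflects
# estimation, not the sampling noise of a 14-subject draw. Fits use all 162
# trials per subject.

.cohort_cache <- new.env(parent = emptyenv())

cohort_spec_fitted <- function(n_subjects = 14) {
  population_spec(make_model("boosted_full"), fitted_group_means(), sd = 0.1,
                  n_subjects = n_subjects)
}

cohort_trials_fitted <- function() {
  if (is.null(.cohort_cache$trials)) {
    .cohort_cache$trials <- simulate_cohort(
      cohort_spec_fitted(), builtin_design("exp1"), seed = 101, center = TRUE)
  }
  .cohort_cache$trials
}

cohort_fit_fitted <- function() {
  if (is.null(.cohort_cache$fit)) {
    .cohort_cache$fit <- em_fit(
      cohort_trials_fitted(), make_model("boosted_full"),
      settings = em_settings(max_iter = 250, tol = 1e-4, n_restarts = 3,
                             accel = 1.8),
      seed = 101)
  }
  .cohort_cache$fit
}
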