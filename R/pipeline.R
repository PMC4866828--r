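#' Pipeline runs: simulate, fit, compare, phase, recover
#'
#' These functions tie the package's stages into reproducible file-based
#' runs: each writes its artifacts plus a `manifest.json` recording the
#' configuration, seed and package version. Every stochastic step derives
#' its seed deterministically from the run seed, so identical
#' configurations yield identical artifacts.
#'
#' @name pipeline
NULL

write_manifest <- function(out_dir, command, config) {
  manifest <- list(
    command = command,
    config = config,
    package = "savouR",
    version = as.character(utils::packageVersion("savouR")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' @describeIn pipeline Simulate a cohort and write `trials.csv` plus the
#'   ground-truth population as `truth.json`.
#' @param design Design name (see [builtin_design()]) or an
#'   `experiment_design`.
#' @param spec A [population_spec()].
#' @param seed Integer run seed.
#' @param out_dir Output directory (created if needed).
#' @param center Passed to [sample_population()].
#' @return `run_simulate()`: invisibly, the trial table (with truth
#'   attribute).
#' @export
run_simulate <- function(spec, design, seed, out_dir, center = FALSE) {
  if (is.character(design)) design <- builtin_design(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- simulate_cohort(spec, design, seed = seed, center = center)
  write_trials(trials, file.path(out_dir, "trials.csv"))
  truth <- attr(trials, "truth")
  jsonlite::write_json(
    list(model = spec$model$name,
         group_mu = as.list(spec$mu),
         group_sd = as.list(spec$sd),
         subjects = lapply(seq_len(nrow(truth)), function(i) {
           c(list(subject_id = truth$subject_id[i]),
             unclass(truth$params[[i]]))
         })),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "simulate",
                 list(design = attr(design, "name"), seed = seed,
                      n_subjects = spec$n_subjects, model = spec$model$name,
                      center = center))
  invisible(trials)
}

#' @describeIn pipeline Fit one model to a trials CSV (or tibble) and write
#'   `fit.json`.
#' @param data Path to a trials CSV, or a trial tibble.
#' @param model Model name or [make_model()] specification.
#' @param balance Equalize per-delay trial counts before fitting.
#' @param settings An [em_settings()] list.
#' @return `run_fit()`: invisibly, the `anticipation_fit`.
#' @export
run_fit <- function(data, model, seed, out_dir, balance = FALSE,
                    settings = em_settings()) {
  if (is.character(data)) data <- read_trials(data)
  validate_trials(data)
  if (is.character(model)) model <- make_model(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (balance) data <- balance_trials(data, seed = child_seed(seed, "balance"))
  fit <- em_fit(data, model, settings = settings, seed = seed)
  est <- tidy(fit)
  jsonlite::write_json(
    list(model = model$name,
         converged = fit$converged,
         em_iterations = fit$n_em_iterations,
         group_mean_natural = stats::setNames(as.list(est$estimate), est$term),
         group_mean_transformed = stats::setNames(as.list(est$transformed_mean),
                                                  est$transformed_term),
         group_sd_transformed = stats::setNames(as.list(est$transformed_sd),
                                                est$transformed_term),
         subject_map = lapply(seq_along(fit$subject_ids), function(i) {
           c(list(subject_id = fit$subject_ids[i]),
             as.list(fit$posteriors[[i]]$m))
         })),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "fit",
                 list(model = model$name, seed = seed, balance = balance,
                      n_subjects = length(fit$subject_ids)))
  invisible(fit)
}

#' @describeIn pipeline Fit several models and write the iBIC comparison
#'   table as `comparison.csv`.
#' @param models Named list of models (default [model_zoo()]).
#' @param K Monte-Carlo draws for [ibic()].
#' @return `run_compare()`: invisibly, the comparison tibble.
#' @export
run_compare <- function(data, seed, out_dir, models = model_zoo(),
                        balance = FALSE, settings = em_settings(), K = 1e4) {
  if (is.character(data)) data <- read_trials(data)
  validate_trials(data)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (balance) data <- balance_trials(data, seed = child_seed(seed, "balance"))
  comparison <- compare_models(data, models, settings = settings, K = K,
                               seed = seed)
  readr::write_csv(tibble::as_tibble(comparison),
                   file.path(out_dir, "comparison.csv"))
  write_manifest(out_dir, "compare",
                 list(models = names(models), seed = seed, K = K,
                      balance = balance))
  invisible(comparison)
}

#' @describeIn pipeline Compute an observing-preference phase diagram and
#'   write it as sign/mask CSV matrices.
#' @param params An [anticipation_params()].
#' @param p_noinfo,gamma_T Grids for [phase_diagram()].
#' @return `run_phase()`: invisibly, the phase tibble.
#' @export
run_phase <- function(params, p_noinfo, gamma_T, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phase <- phase_diagram(params, p_noinfo = p_noinfo, gamma_T = gamma_T)
  write_phase_diagram(phase, file.path(out_dir, "phase"))
  write_manifest(out_dir, "phase",
                 list(p_noinfo = range(p_noinfo), gamma_T = range(gamma_T),
                      gamma = params$gamma, nu = params$nu,
                      eta0 = params$eta0, boost = params$boost$kind))
  invisible(phase)
}

#' @describeIn pipeline Simulate at known parameters, refit, and write a
#'   truth-vs-estimate recovery report (`recovery.csv`).
#' @return `run_recover()`: invisibly, the recovery tibble with columns
#'   `term`, `truth`, `estimate`, `std.error`, `z` (on the transformed
#'   scale).
#' @export
run_recover <- function(spec, design, seed, out_dir,
                        settings = em_settings(), balance = FALSE,
                        center = TRUE) {
  if (is.character(design)) design <- builtin_design(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- simulate_cohort(spec, design, seed = child_seed(seed, "sim"),
                            center = center)
  fit_data <- if (balance) {
    balance_trials(trials, seed = child_seed(seed, "balance"))
  } else trials
  fit <- em_fit(fit_data, spec$model, settings = settings,
                seed = child_seed(seed, "fit"))
  est <- tidy(fit)
  report <- tibble::tibble(
    term = est$term,
    truth_transformed = unname(spec$mu),
    estimate_transformed = est$transformed_mean,
    std.error = est$std.error,
    z = (est$transformed_mean - unname(spec$mu)) / est$std.error,
    truth = vapply(seq_along(est$term), function(j) {
      natural_scale(spec$model$transforms[j], spec$mu[j])
    }, numeric(1)),
    estimate = est$estimate)
  readr::write_csv(report, file.path(out_dir, "recovery.csv"))
  write_manifest(out_dir, "recover",
                 list(design = attr(design, "name"), seed = seed,
                      model = spec$model$name, n_subjects = spec$n_subjects,
                      balance = balance, center = center))
  attr(report, "fit") <- fit
  invisible(report)
}
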