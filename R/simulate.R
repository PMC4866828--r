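#' Built-in experimental designs
#'
#' Trial schedules of the human advance-information experiments:
#' \describe{
#'   \item{exp1}{four fixed-order blocks with delays 2.5, 7.5, 20 and 40 s
#'     and 90, 36, 18 and 18 trials (162 total) — time per condition is
#'     roughly equalized.}
#'   \item{exp1_control}{delays reordered (2.5, 40, 20, 7.5 s) plus a fifth
#'     2.5 s block of 36 trials repeating the first condition.}
#'   \item{exp2}{25 trials, 5 per delay in \{1, 5, 10, 20, 40\} s, delay
#'     order randomized trial-by-trial.}
#' }
#' All designs deliver reward with probability 0.5.
#'
#' @param name Design name.
#' @return An object of class `experiment_design`: a tibble with columns
#'   `block_index`, `delay_s`, `n_trials`, plus attributes `randomized` and
#'   `p_reward`.
#' @examples
#' builtin_design("exp1")
#' @export
builtin_design <- function(name = c("exp1", "exp1_control", "exp2")) {
  name <- match.arg(name)
  design <- switch(name,
    exp1 = tibble::tibble(
      block_index = 1:4,
      delay_s = c(2.5, 7.5, 20, 40),
      n_trials = c(90L, 36L, 18L, 18L)),
    exp1_control = tibble::tibble(
      block_index = 1:5,
      delay_s = c(2.5, 40, 20, 7.5, 2.5),
      n_trials = c(90L, 18L, 18L, 36L, 36L)),
    exp2 = tibble::tibble(
      block_index = 1L,
      delay_s = c(1, 5, 10, 20, 40),
      n_trials = rep(5L, 5)))
  structure(design, name = name, randomized = (name == "exp2"),
            p_reward = 0.5,
            class = c("experiment_design", class(design)))
}

#' Population specification for synthetic cohorts
#'
#' Subjects' (transformed) parameters are treated as draws from a diagonal
#' Gaussian on the unconstrained scale used for fitting, matching the
#' hierarchical random-effects assumption.
#'
#' @param model An [make_model()] specification.
#' @param mu Group means: either a [trial_params()] (natural scale,
#'   transformed internally) or a numeric vector on the transformed scale.
#' @param sd Between-subject standard deviations on the transformed scale;
#'   a single value is recycled across parameters. For log-transformed
#'   rates a transformed-scale sd of 0.1 corresponds to a ~10%
#'   coefficient of variation on the natural scale.
#' @param n_subjects Number of subjects.
#' @return An object of class `population_spec`.
#' @examples
#' population_spec(make_model("boosted_full"), fitted_group_means(), sd = 0.1,
#'                 n_subjects = 14)
#' @export
population_spec <- function(model, mu, sd, n_subjects) {
  stopifnot(inherits(model, "anticipation_model"))
  if (inherits(mu, "trial_params")) mu <- par_transform(model, mu)
  stopifnot(length(mu) == model$n_params)
  sd <- rep_len(sd, model$n_params)
  stopifnot(length(sd) == model$n_params, all(sd >= 0), n_subjects >= 1)
  structure(list(model = model, mu = stats::setNames(mu, model$par_names),
                 sd = stats::setNames(sd, model$par_names),
                 n_subjects = as.integer(n_subjects)),
            class = "population_spec")
}

#' Draw a synthetic subject population
#'
#' Samples per-subject transformed parameter vectors from the diagonal
#' group Gaussian and maps them back to the natural scale. With
#' `center = TRUE` the realized draws are shifted (and, when possible,
#' rescaled) so their empirical mean matches the group mean exactly —
#' useful in recovery studies, where it removes the sampling noise of a
#' small cohort from the recovery error.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @param center Moment-match the realized transformed draws to `mu`.
#' @return A tibble with one row per subject: `subject_id`, the transformed
#'   parameters (columns named as `spec$model$par_names`), and a list
#'   column `params` of [trial_params()] objects.
#' @export
sample_population <- function(spec, seed = 1, center = FALSE) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  n <- spec$n_subjects
  k <- spec$model$n_params
  draws <- matrix(stats::rnorm(n * k), n, k) %*% diag(spec$sd, k)
  draws <- sweep(draws, 2, spec$mu, "+")
  if (center && n > 1) {
    draws <- sweep(draws, 2, colMeans(draws) - spec$mu, "-")
  }
  colnames(draws) <- spec$model$par_names
  out <- tibble::as_tibble(draws)
  out$subject_id <- sprintf("S%02d", seq_len(n))
  out$params <- lapply(seq_len(n), function(i) {
    par_untransform(spec$model, draws[i, ])
  })
  dplyr::relocate(out, "subject_id")
}

#' Simulate one subject's session
#'
#' Runs the trial model forward under a design: on each trial the choice is
#' sampled from the softmax of the current learned values; for informative
#' choices a reward cue appears with the design's reward probability and
#' fully determines the outcome; for uninformative choices no cue is shown
#' and the outcome is drawn directly. The experienced outcome value then
#' updates the chosen target. One seeded generator drives choice then
#' outcome draws, in that order, trial by trial.
#'
#' In blocked designs a single pair of target values is learned across the
#' whole session (target colors persist across blocks). In randomized
#' designs the delay is announced at the start of each trial, so a separate
#' value pair is learned per delay condition (`per_delay`); otherwise the
#' model could express no delay-dependent preference at all when delays are
#' interleaved.
#'
#' @param params A [trial_params()] (the generating truth).
#' @param design An [builtin_design()] (or a compatible tibble).
#' @param model An [make_model()] specification run forward.
#' @param seed Integer seed (`NULL` continues the current RNG stream).
#' @param subject_id Identifier stored in the records.
#' @param per_delay Learn separate target values per delay condition;
#'   defaults to the design's `randomized` attribute.
#' @return A tibble of trial records (see [validate_trials()]).
#' @examples
#' simulate_subject(fitted_group_means(), builtin_design("exp2"), seed = 1)
#' @export
simulate_subject <- function(params, design, model = make_model("boosted_full"),
                             seed = NULL, subject_id = "S01",
                             per_delay = NULL) {
  stopifnot(inherits(params, "trial_params"))
  if (!is.null(seed)) set.seed(seed)
  per_delay <- per_delay %||% isTRUE(attr(design, "randomized"))
  p_reward <- attr(design, "p_reward") %||% 0.5
  delays <- rep(design$delay_s, design$n_trials)
  blocks <- rep(design$block_index, design$n_trials)
  if (isTRUE(attr(design, "randomized"))) {
    ord <- sample.int(length(delays))
    delays <- delays[ord]
    blocks <- blocks[ord]
  }
  n <- length(delays)

  # precompute outcome values per unique delay and event type
  u <- sort(unique(delays))
  d_idx <- match(delays, u)
  V_tab <- rbind(
    info_reward = outcome_value(params, model, "info", "reward", u),
    info_noreward = outcome_value(params, model, "info", "noreward", u),
    noinfo_reward = outcome_value(params, model, "noinfo", "reward", u),
    noinfo_noreward = outcome_value(params, model, "noinfo", "noreward", u))

  alpha <- params$alpha
  sigma <- params$sigma
  n_states <- if (per_delay) length(u) else 1L
  s_idx <- if (per_delay) d_idx else rep(1L, n)
  q_i <- numeric(n_states); q_n <- numeric(n_states)
  choice <- character(n); cue <- character(n); outcome <- character(n)
  for (t in seq_len(n)) {
    s <- s_idx[t]
    p_info <- stats::plogis((q_i[s] - q_n[s]) / sigma)
    info <- stats::runif(1) < p_info
    rewarded <- stats::runif(1) < p_reward
    if (info) {
      choice[t] <- "info"
      cue[t] <- if (rewarded) "reward_cue" else "noreward_cue"
    } else {
      choice[t] <- "noinfo"
      cue[t] <- "none"
    }
    outcome[t] <- if (rewarded) "reward" else "noreward"
    V <- V_tab[paste(choice[t], outcome[t], sep = "_"), d_idx[t]]
    if (info) {
      q_i[s] <- q_i[s] + alpha * (V - q_i[s])
    } else {
      q_n[s] <- q_n[s] + alpha * (V - q_n[s])
    }
  }

  tibble::tibble(subject_id = subject_id,
                 trial_index = seq_len(n),
                 block_index = blocks,
                 delay_s = delays,
                 choice = choice, cue = cue, outcome = outcome)
}

#' Simulate a cohort of subjects with known ground truth
#'
#' Draws a population with [sample_population()] and simulates each subject
#' under the design. Per-subject seeds are derived deterministically from
#' `seed`.
#'
#' @param spec A [population_spec()].
#' @param design An [builtin_design()].
#' @param seed Integer seed.
#' @param center Passed to [sample_population()].
#' @return A tibble of trial records for all subjects, with the drawn
#'   population attached as attribute `"truth"`.
#' @export
simulate_cohort <- function(spec, design, seed = 1, center = FALSE) {
  pop <- sample_population(spec, seed = seed, center = center)
  trials <- purrr::map_dfr(seq_len(nrow(pop)), function(i) {
    simulate_subject(pop$params[[i]], design, model = spec$model,
                     seed = child_seed(seed, paste0("subject", i)),
                     subject_id = pop$subject_id[i])
  })
  attr(trials, "truth") <- pop
  trials
}

.trial_columns <- c("subject_id", "trial_index", "block_index", "delay_s",
                    "choice", "cue", "outcome")

#' Validate a table of trial records
#'
#' Checks the trial-record contract: required columns; `choice` in
#' \{info, noinfo\}; `cue` in \{reward_cue, noreward_cue, none\}; `outcome`
#' in \{reward, noreward\}; informative choices carry a cue; a reward cue
#' is always followed by reward (and a no-reward cue never is).
#'
#' @param data A data frame of trial records.
#' @param single_subject Require exactly one subject.
#' @return Invisibly, `data`; aborts with a `savouR_validation_error`
#'   listing the offending columns or rows otherwise.
#' @export
validate_trials <- function(data, single_subject = FALSE) {
  missing <- setdiff(.trial_columns, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("trial table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "savouR_validation_error")
  }
  problems <- character(0)
  if (!all(data$choice %in% c("info", "noinfo"))) {
    problems <- c(problems, "choice must be 'info' or 'noinfo'")
  }
  if (!all(data$cue %in% c("reward_cue", "noreward_cue", "none"))) {
    problems <- c(problems, "cue must be 'reward_cue', 'noreward_cue' or 'none'")
  }
  if (!all(data$outcome %in% c("reward", "noreward"))) {
    problems <- c(problems, "outcome must be 'reward' or 'noreward'")
  }
  if (length(problems) == 0) {
    bad_info <- which(data$choice == "info" & data$cue == "none")
    bad_cue <- which((data$cue == "reward_cue" & data$outcome != "reward") |
                       (data$cue == "noreward_cue" & data$outcome != "noreward"))
    if (length(bad_info) > 0) {
      problems <- c(problems, paste0("informative choices without a cue in rows: ",
                                     paste(utils::head(bad_info, 5), collapse = ", ")))
    }
    if (length(bad_cue) > 0) {
      problems <- c(problems, paste0("cue/outcome mismatch in rows: ",
                                     paste(utils::head(bad_cue, 5), collapse = ", ")))
    }
  }
  if (single_subject && length(unique(data$subject_id)) != 1) {
    problems <- c(problems, "expected records from a single subject")
  }
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid trial records:\n- ",
                        paste(problems, collapse = "\n- ")),
                 class = "savouR_validation_error")
  }
  invisible(data)
}

#' Read and write trial-record CSV files
#'
#' The interchange dialect is comma-separated UTF-8 with a header row and
#' the columns `subject_id, trial_index, block_index, delay_s, choice, cue,
#' outcome`.
#'
#' @param data A validated trial table.
#' @param file Path to a CSV file.
#' @return `write_trials()` invisibly returns `file`; `read_trials()`
#'   returns a validated tibble.
#' @export
write_trials <- function(data, file) {
  validate_trials(data)
  readr::write_csv(data[.trial_columns], file)
  invisible(file)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  data <- readr::read_csv(file, show_col_types = FALSE)
  validate_trials(data)
  data$subject_id <- as.character(data$subject_id)
  data$trial_index <- as.integer(data$trial_index)
  data$block_index <- as.integer(data$block_index)
  data$delay_s <- as.numeric(data$delay_s)
  data
}

#' Plot choice fractions by delay
#'
#' Empirical fraction of informative choices per delay condition, averaged
#' over subjects, with standard errors over subjects.
#'
#' @param data A trial table (possibly many subjects).
#' @return A ggplot object.
#' @export
plot_choice_fractions <- function(data) {
  validate_trials(data)
  per_subj <- data |>
    dplyr::group_by(.data$subject_id, .data$delay_s) |>
    dplyr::summarise(frac = mean(.data$choice == "info"), .groups = "drop")
  summ <- per_subj |>
    dplyr::group_by(.data$delay_s) |>
    dplyr::summarise(mean = mean(.data$frac),
                     se = stats::sd(.data$frac) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$delay_s, .data$mean)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "delay (s)", y = "fraction choosing info") +
    ggplot2::theme_minimal()
}
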