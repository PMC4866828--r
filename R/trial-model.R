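#' Trial-by-trial model parameters for the human advance-information task
#'
#' Natural-scale parameters of the learning model: on each trial the chosen
#' target's value moves towards the experienced outcome value `V` by a
#' fraction `alpha` (delta rule), and choices are a softmax of the learned
#' value difference. The outcome value combines anticipation and discounted
#' outcome, \eqn{V = \eta_{S_i} A_i + B_i}, with \eqn{i = +} (reward) or
#' \eqn{-} (no reward). Savouring and dread may grow at different rates
#' (`nu_plus`, `nu_minus`) but share a discount rate; the no-reward outcome
#' value `r_minus` is sign-unconstrained (its negativity is an empirical
#' finding, not an assumption). In the fitted convention the boost gain and
#' softmax temperature are fixed at 1, since only `c R/sigma` is
#' identifiable.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param r_plus Reward outcome value \eqn{R_+}.
#' @param r_minus No-reward outcome value \eqn{R_-} (any sign).
#' @param gamma Shared discount rate (1/s); used when `gamma_plus`/
#'   `gamma_minus` are not given separately.
#' @param gamma_plus,gamma_minus Outcome-specific discount rates (1/s).
#' @param nu_plus,nu_minus Anticipation growth rates for savouring and
#'   dread (1/s); 0 disables anticipation of that outcome.
#' @param eta0 Baseline anticipation weight (0 in the boosted models, where
#'   it cancels from the value difference).
#' @param c Boost gain applied on informative-cue trials (fixed 1 for
#'   fitting).
#' @param sigma Softmax temperature (fixed 1 for fitting).
#' @return An object of class `trial_params` (a named list).
#' @examples
#' fitted_group_means()
#' @export
trial_params <- function(alpha = 0.17, r_plus = 0.85, r_minus = -0.84,
                         gamma = 0.041, gamma_plus = gamma,
                         gamma_minus = gamma,
                         nu_plus = 0.082, nu_minus = 0.41,
                         eta0 = 0, c = 1, sigma = 1) {
  if (alpha < 0 || alpha > 1) {
    rlang::abort("`alpha` must lie in [0, 1]", class = "savouR_domain_error")
  }
  if (any(c(gamma_plus, gamma_minus, nu_plus, nu_minus) < 0) || eta0 < 0) {
    rlang::abort("rates and `eta0` must be non-negative",
                 class = "savouR_domain_error")
  }
  structure(list(alpha = alpha, r_plus = r_plus, r_minus = r_minus,
                 gamma_plus = gamma_plus, gamma_minus = gamma_minus,
                 nu_plus = nu_plus, nu_minus = nu_minus,
                 eta0 = eta0, c = c, sigma = sigma),
            class = "trial_params")
}

#' Group-mean parameters estimated for the human experiment
#'
#' The hierarchical group means for the full boosted model: learning rate
#' 0.17, reward value 0.85, no-reward value -0.84, discount rate 0.041 /s,
#' savouring rate 0.082 /s and dread rate 0.41 /s (savouring unfolds on a
#' slower timescale than dread).
#'
#' @return A [trial_params()] object.
#' @export
fitted_group_means <- function() {
  trial_params(alpha = 0.17, r_plus = 0.85, r_minus = -0.84, gamma = 0.041,
               nu_plus = 0.082, nu_minus = 0.41)
}

# canonical natural-parameter order used internally
.full_par_names <- c("alpha", "r_plus", "r_minus", "gamma_plus", "gamma_minus",
                     "nu_plus", "nu_minus", "eta0", "c", "sigma")

#' Construct a model specification from the comparison zoo
#'
#' The six candidate models differ in which components of the outcome value
#' are active:
#' \describe{
#'   \item{q_learning}{plain delta-rule learning of undiscounted outcome
#'     values; free: alpha, R+, R- (3).}
#'   \item{q_learning_discount}{adds outcome-specific exponential
#'     discounting, no anticipation; free: alpha, R+, R-, gamma+, gamma- (5).}
#'   \item{anticipation_no_boost}{anticipation with a free constant weight
#'     eta0 but no RPE boosting; free: alpha, R+, R-, gamma, nu+, nu-,
#'     eta0 (7).}
#'   \item{boosted_no_rminus}{boosted anticipation with the no-reward
#'     outcome forced to zero; free: alpha, R+, gamma+, nu+ (4).}
#'   \item{boosted_no_discount}{boosted anticipation without temporal
#'     discounting; free: alpha, R+, R-, nu+, nu- (5).}
#'   \item{boosted_full}{the full boosted-anticipation model; free: alpha,
#'     R+, R-, gamma (shared), nu+, nu- (6).}
#' }
#' `boosted_asymmetric` (boost gains differing for positive and negative
#' RPEs) is available as a named variant: with `eta0 = 0` the asymmetric
#' gains are absorbed into R+ and R-, so its likelihood coincides with
#' `boosted_full`; the asymmetry is read off the fitted R+/R- ratio.
#'
#' @param name Model name.
#' @return An object of class `anticipation_model` with elements `name`,
#'   `par_names` (transformed scale), `n_params`, and transform closures.
#' @examples
#' make_model("boosted_full")$n_params
#' @export
make_model <- function(name = c("boosted_full", "q_learning",
                                "q_learning_discount", "anticipation_no_boost",
                                "boosted_no_rminus", "boosted_no_discount",
                                "boosted_asymmetric")) {
  name <- match.arg(name)
  spec <- switch(name,
    q_learning = list(
      free = c("alpha", "r_plus", "r_minus"),
      fixed = list(gamma_plus = 0, gamma_minus = 0, nu_plus = 0,
                   nu_minus = 0, eta0 = 0, c = 0, sigma = 1)),
    q_learning_discount = list(
      free = c("alpha", "r_plus", "r_minus", "gamma_plus", "gamma_minus"),
      fixed = list(nu_plus = 0, nu_minus = 0, eta0 = 0, c = 0, sigma = 1)),
    anticipation_no_boost = list(
      free = c("alpha", "r_plus", "r_minus", "gamma", "nu_plus", "nu_minus",
               "eta0"),
      fixed = list(c = 0, sigma = 1)),
    boosted_no_rminus = list(
      free = c("alpha", "r_plus", "gamma", "nu_plus"),
      fixed = list(r_minus = 0, nu_minus = 0, eta0 = 0, c = 1, sigma = 1)),
    boosted_no_discount = list(
      free = c("alpha", "r_plus", "r_minus", "nu_plus", "nu_minus"),
      fixed = list(gamma_plus = 0, gamma_minus = 0, eta0 = 0, c = 1,
                   sigma = 1)),
    boosted_full = ,
    boosted_asymmetric = list(
      free = c("alpha", "r_plus", "r_minus", "gamma", "nu_plus", "nu_minus"),
      fixed = list(eta0 = 0, c = 1, sigma = 1)))

  transform_of <- function(par) {
    switch(par,
      alpha = "logit",
      r_plus = , r_minus = "identity",
      "log")
  }
  transforms <- vapply(spec$free, transform_of, character(1))
  par_names <- ifelse(transforms == "logit", paste0("logit_", spec$free),
               ifelse(transforms == "log", paste0("log_", spec$free),
                      spec$free))

  structure(list(name = name, free = spec$free, fixed = spec$fixed,
                 transforms = transforms, par_names = unname(par_names),
                 n_params = length(spec$free)),
            class = "anticipation_model")
}

#' @export
print.anticipation_model <- function(x, ...) {
  cat("<anticipation_model> ", x$name, " (", x$n_params,
      " free parameters: ", paste(x$free, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' The six-model comparison zoo
#'
#' @return A named list of [make_model()] specifications in the order of
#'   increasing structure.
#' @export
model_zoo <- function() {
  names <- c("q_learning", "q_learning_discount", "anticipation_no_boost",
             "boosted_no_rminus", "boosted_no_discount", "boosted_full")
  stats::setNames(lapply(names, make_model), names)
}

#' Map transformed parameters to the natural scale (and back)
#'
#' Fitting is done on an unconstrained transformed scale: logit for the
#' learning rate, log for rates and `eta0`, identity for the
#' sign-unconstrained outcome values.
#'
#' @param model An [make_model()] specification.
#' @param theta Numeric vector on the transformed scale.
#' @return `par_untransform()`: a [trial_params()] object;
#'   `par_transform()`: the transformed numeric vector.
#' @export
par_untransform <- function(model, theta) {
  stopifnot(length(theta) == model$n_params)
  theta <- unname(theta)
  nat <- stats::setNames(as.list(theta), model$free)
  for (j in seq_along(model$free)) {
    nat[[j]] <- switch(model$transforms[[j]],
                       logit = stats::plogis(theta[j]),
                       log = exp(theta[j]),
                       theta[j])
  }
  if ("gamma" %in% names(nat)) {
    nat$gamma_plus <- nat$gamma
    nat$gamma_minus <- nat$gamma
    nat$gamma <- NULL
  }
  nat <- c(nat, model$fixed)
  do.call(trial_params, nat[intersect(.full_par_names, names(nat))])
}

#' @rdname par_untransform
#' @param params A [trial_params()] object (natural scale).
#' @export
par_transform <- function(model, params) {
  vapply(seq_along(model$free), function(j) {
    par <- model$free[[j]]
    value <- if (par == "gamma") params$gamma_plus else params[[par]]
    switch(model$transforms[[j]],
           logit = stats::qlogis(value),
           log = log(value),
           value)
  }, numeric(1)) |> stats::setNames(model$par_names)
}

#' Experienced value of a trial outcome
#'
#' The value learned from a trial is \eqn{V = \eta_{S_i} A_i + B_i}, where
#' the outcome index is + for reward and - for no reward, and the
#' anticipation weight is boosted on informative-cue trials (the cue evokes
#' a non-zero RPE) but not on the uninformative path:
#' \eqn{\eta = \eta_0 + c} after an informative cue, \eqn{\eta = \eta_0}
#' otherwise.
#'
#' @param params A [trial_params()].
#' @param model An [make_model()] specification (controls which components
#'   are active); defaults to the full boosted model.
#' @param choice Character vector, `"info"` or `"noinfo"`.
#' @param outcome Character vector, `"reward"` or `"noreward"`.
#' @param T Delay (s).
#' @return Numeric vector of outcome values.
#' @examples
#' outcome_value(fitted_group_means(), choice = "info", outcome = "reward", T = 20)
#' @export
outcome_value <- function(params, model = make_model("boosted_full"),
                          choice, outcome, T) {
  n <- max(length(choice), length(outcome), length(T))
  choice <- rep_len(choice, n); outcome <- rep_len(outcome, n)
  T <- rep_len(T, n)
  bad <- !(choice %in% c("info", "noinfo")) |
    !(outcome %in% c("reward", "noreward"))
  if (any(bad)) {
    rlang::abort("invalid (choice, outcome) event",
                 class = "savouR_domain_error")
  }
  plus <- outcome == "reward"
  R <- ifelse(plus, params$r_plus, params$r_minus)
  nu <- ifelse(plus, params$nu_plus, params$nu_minus)
  gam <- ifelse(plus, params$gamma_plus, params$gamma_minus)
  eta <- params$eta0 + params$c * (choice == "info")
  A <- numeric(n)
  has_ant <- nu > 0
  if (any(has_ant)) {
    A[has_ant] <- integrated_anticipation(R[has_ant], nu[has_ant],
                                          gam[has_ant], T[has_ant])
  }
  B <- R * exp(-gam * T)
  eta * A + B
}

#' Delta-rule update of the learned target values
#'
#' @param q_info,q_noinfo Current learned values.
#' @param choice `"info"` or `"noinfo"` (scalar).
#' @param V Experienced outcome value.
#' @param alpha Learning rate in \[0, 1\].
#' @return A named numeric vector `c(q_info, q_noinfo)`.
#' @export
q_update <- function(q_info, q_noinfo, choice, V, alpha) {
  if (alpha < 0 || alpha > 1) {
    rlang::abort("`alpha` must lie in [0, 1]", class = "savouR_domain_error")
  }
  if (choice == "info") {
    q_info <- q_info + alpha * (V - q_info)
  } else {
    q_noinfo <- q_noinfo + alpha * (V - q_noinfo)
  }
  c(q_info = unname(q_info), q_noinfo = unname(q_noinfo))
}

#' Probability of choosing the informative target
#'
#' Softmax on the learned value difference,
#' \eqn{P(\mathrm{info}) = 1/(1 + e^{-(Q_{info} - Q_{noinfo})/\sigma})}.
#'
#' @inheritParams q_update
#' @param sigma Softmax temperature, > 0.
#' @return Probability of the informative choice.
#' @export
trial_choice_prob <- function(q_info, q_noinfo, sigma = 1) {
  choice_probability(q_info, q_noinfo, sigma)
}

# Fast closure over one subject's trials: returns function(theta) -> loglik
# on the transformed scale. Exploits the small number of unique delays.
# `per_delay` learns a separate value pair per (announced) delay condition.
make_loglik_fn <- function(data, model, per_delay = FALSE) {
  n <- nrow(data)
  choice_info <- data$choice == "info"
  plus <- data$outcome == "reward"
  delays <- sort(unique(data$delay_s))
  d_idx <- match(data$delay_s, delays)
  s_idx <- if (per_delay) d_idx else rep(1L, n)
  n_states <- if (per_delay) length(delays) else 1L
  is_info <- as.numeric(choice_info)

  function(theta) {
    p <- par_untransform(model, theta)
    # outcome values per (delay, outcome-sign, path)
    A_p <- if (p$nu_plus > 0) {
      integrated_anticipation(p$r_plus, p$nu_plus, p$gamma_plus, delays)
    } else numeric(length(delays))
    A_m <- if (p$nu_minus > 0) {
      integrated_anticipation(p$r_minus, p$nu_minus, p$gamma_minus, delays)
    } else numeric(length(delays))
    B_p <- p$r_plus * exp(-p$gamma_plus * delays)
    B_m <- p$r_minus * exp(-p$gamma_minus * delays)
    eta <- p$eta0 + p$c * is_info
    V <- ifelse(plus, eta * A_p[d_idx] + B_p[d_idx],
                eta * A_m[d_idx] + B_m[d_idx])
    alpha <- p$alpha
    q_i <- numeric(n_states); q_n <- numeric(n_states)
    dq <- numeric(n)
    for (t in seq_len(n)) {
      s <- s_idx[t]
      dq[t] <- q_i[s] - q_n[s]
      if (choice_info[t]) {
        q_i[s] <- q_i[s] + alpha * (V[t] - q_i[s])
      } else {
        q_n[s] <- q_n[s] + alpha * (V[t] - q_n[s])
      }
    }
    x <- ifelse(choice_info, dq, -dq) / p$sigma
    sum(stats::plogis(x, log.p = TRUE))
  }
}

#' Log-likelihood of one subject's session under a trial model
#'
#' Composes the delta-rule value updates and softmax choice rule over an
#' ordered session; target values start at zero and are not reset between
#' blocks. With `per_delay = TRUE` a separate value pair is learned per
#' delay condition, appropriate for randomized designs where the delay is
#' announced before each choice.
#'
#' @param data Trial records for a single subject (see [validate_trials()]);
#'   ordered by `trial_index`.
#' @param params A [trial_params()].
#' @param model An [make_model()] specification.
#' @param per_delay Learn separate value pairs per delay condition.
#' @return The total log-likelihood (scalar, <= 0).
#' @examples
#' d <- simulate_subject(fitted_group_means(), builtin_design("exp2"),
#'                       seed = 1)
#' session_loglik(d, fitted_group_means(), per_delay = TRUE)
#' @export
session_loglik <- function(data, params, model = make_model("boosted_full"),
                           per_delay = FALSE) {
  validate_trials(data, single_subject = TRUE)
  data <- dplyr::arrange(data, .data$trial_index)
  fn <- make_loglik_fn(data, model, per_delay = per_delay)
  fn(par_transform(model, params))
}
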