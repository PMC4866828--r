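#' Specify how the anticipation weight responds to reward prediction errors
#'
#' The weight \eqn{\eta} placed on anticipatory utility is hypothesised to be
#' boosted by the absolute reward prediction error (RPE) evoked by the
#' outcome-predictive cue. Three functional forms are supported, together
#' with `"none"` (constant weight):
#' \describe{
#'   \item{linear}{\eqn{\eta = \eta_0 + c\,|\delta_{pe}|}}
#'   \item{tanh}{\eqn{\eta = \eta_0 + c_1 \tanh(c_2 |\delta_{pe}|)}}
#'   \item{step}{\eqn{\eta = \eta_0 + c\,\theta(|\delta_{pe}|)} with
#'     \eqn{\theta(x) = 1} for \eqn{x > 0}, else 0}
#' }
#' The linear form is the small-RPE approximation of the tanh form; the step
#' form is its large-\eqn{c_2} limit.
#'
#' @param kind One of `"linear"`, `"tanh"`, `"step"`, `"none"`.
#' @param c Gain (dimensionless); used by the linear and step forms.
#' @param c1 Amplitude of the tanh form (dimensionless).
#' @param c2 Slope of the tanh form (dimensionless, > 0).
#' @return An object of class `boost_spec`.
#' @examples
#' boost_spec("linear", c = 3)
#' boost_spec("tanh", c1 = 1, c2 = 3)
#' @export
boost_spec <- function(kind = c("none", "linear", "tanh", "step"),
                       c = 0, c1 = 0, c2 = 1) {
  kind <- match.arg(kind)
  if (c < 0 || c1 < 0) {
    rlang::abort("boost gains `c` and `c1` must be non-negative",
                 class = "savouR_config_error")
  }
  if (c2 <= 0) {
    rlang::abort("tanh slope `c2` must be positive",
                 class = "savouR_config_error")
  }
  if (kind == "none") {
    c <- 0
    c1 <- 0
  }
  structure(list(kind = kind, c = c, c1 = c1, c2 = c2),
            class = "boost_spec")
}

#' @export
print.boost_spec <- function(x, ...) {
  gain <- switch(x$kind,
    none = "eta = eta0",
    linear = sprintf("eta = eta0 + %g * |rpe|", x$c),
    step = sprintf("eta = eta0 + %g * theta(|rpe|)", x$c),
    tanh = sprintf("eta = eta0 + %g * tanh(%g * |rpe|)", x$c1, x$c2)
  )
  cat("<boost_spec> ", gain, "\n", sep = "")
  invisible(x)
}

#' Parameters of the anticipation valuation model
#'
#' Bundles the quantities needed to value a reward-predictive cue: the reward
#' magnitude `R`, the anticipation growth rate `nu` (how steeply savouring or
#' dread rises towards delivery), the exponential discount rate `gamma`, the
#' baseline anticipation weight `eta0`, the RPE-boosting rule, and the
#' softmax temperature `sigma` used when values are mapped to choices.
#'
#' All rates are per second and delays are in seconds.
#'
#' @param R Reward magnitude (utility units); may be negative for aversive
#'   outcomes (dread).
#' @param nu Anticipation growth rate \eqn{\nu} (1/s), > 0.
#' @param gamma Discount rate \eqn{\gamma} (1/s), >= 0.
#' @param eta0 Baseline anticipation weight \eqn{\eta_0}, >= 0.
#' @param boost A [boost_spec()].
#' @param sigma Softmax temperature (utility units), > 0.
#' @return An object of class `anticipation_params`.
#' @examples
#' anticipation_params(R = 1, nu = 0.5, gamma = 0.1, eta0 = 1,
#'                     boost = boost_spec("linear", c = 5))
#' @export
anticipation_params <- function(R = 1, nu = 0.5, gamma = 0.1, eta0 = 0,
                                boost = boost_spec("none"), sigma = 1) {
  stopifnot(inherits(boost, "boost_spec"))
  if (nu <= 0) {
    rlang::abort("anticipation rate `nu` must be positive",
                 class = "savouR_domain_error")
  }
  if (gamma < 0) {
    rlang::abort("discount rate `gamma` must be non-negative",
                 class = "savouR_domain_error")
  }
  if (sigma <= 0) {
    rlang::abort("softmax temperature `sigma` must be positive",
                 class = "savouR_domain_error")
  }
  if (eta0 < 0) {
    rlang::abort("baseline weight `eta0` must be non-negative",
                 class = "savouR_domain_error")
  }
  structure(list(R = R, nu = nu, gamma = gamma, eta0 = eta0,
                 boost = boost, sigma = sigma),
            class = "anticipation_params")
}

#' @export
print.anticipation_params <- function(x, ...) {
  cat(sprintf(
    "<anticipation_params> R=%g, nu=%g /s, gamma=%g /s, eta0=%g, sigma=%g\n",
    x$R, x$nu, x$gamma, x$eta0, x$sigma))
  print(x$boost)
  invisible(x)
}

# relative tolerance below which nu and gamma are treated as equal and the
# removable singularity is replaced by its analytic limit
.nu_gamma_tol <- 1e-9

#' Integrated discounted anticipation of a delayed reward
#'
#' While waiting a delay `T` for a reward of magnitude `R`, anticipation is
#' worth \eqn{a(t) = R e^{-\nu (T - t)}} at time \eqn{t}; its discounted
#' integral over the wait is
#' \deqn{A = \frac{R}{\nu - \gamma}\left(e^{-\gamma T} - e^{-\nu T}\right).}
#' At \eqn{\nu = \gamma} the removable singularity is replaced by the limit
#' \eqn{R\,T\,e^{-\gamma T}} (applied when
#' \eqn{|\nu - \gamma| < 10^{-9} \max(\nu, \gamma)}).
#'
#' @param R Reward magnitude.
#' @param nu Anticipation growth rate (1/s), > 0.
#' @param gamma Discount rate (1/s), >= 0.
#' @param T Delay between cue and delivery (s), >= 0.
#' @return The integrated discounted anticipation `A` (utility units),
#'   vectorised over the inputs.
#' @examples
#' integrated_anticipation(1, nu = 0.5, gamma = 0.1, T = 2.25)
#' @export
integrated_anticipation <- function(R, nu, gamma, T) {
  n <- max(length(R), length(nu), length(gamma), length(T))
  R <- rep_len(R, n); nu <- rep_len(nu, n)
  gamma <- rep_len(gamma, n); T <- rep_len(T, n)
  if (any(T < 0)) {
    rlang::abort("delay `T` must be non-negative", class = "savouR_domain_error")
  }
  if (any(nu <= 0)) {
    rlang::abort("anticipation rate `nu` must be positive",
                 class = "savouR_domain_error")
  }
  if (any(gamma < 0)) {
    rlang::abort("discount rate `gamma` must be non-negative",
                 class = "savouR_domain_error")
  }
  degenerate <- abs(nu - gamma) < .nu_gamma_tol * pmax(nu, gamma)
  out <- numeric(n)
  out[degenerate] <- R[degenerate] * T[degenerate] *
    exp(-gamma[degenerate] * T[degenerate])
  i <- !degenerate
  out[i] <- R[i] / (nu[i] - gamma[i]) * (exp(-gamma[i] * T[i]) - exp(-nu[i] * T[i]))
  out
}

#' Discounted value of a delayed reward
#'
#' The conventional temporal-difference contribution of the reward itself:
#' \eqn{B = R e^{-\gamma T}}.
#'
#' @inheritParams integrated_anticipation
#' @return The discounted reward `B`, vectorised.
#' @examples
#' discounted_reward(1, gamma = 0.1, T = 2.25)
#' @export
discounted_reward <- function(R, gamma, T) {
  if (any(T < 0)) {
    rlang::abort("delay `T` must be non-negative", class = "savouR_domain_error")
  }
  if (any(gamma < 0)) {
    rlang::abort("discount rate `gamma` must be non-negative",
                 class = "savouR_domain_error")
  }
  R * exp(-gamma * T)
}

# RPEs below this magnitude are treated as exactly zero (a fully predicted
# cue must not be boosted through floating-point dust)
.rpe_zero_tol <- 1e-12

#' Realized anticipation weight under RPE boosting
#'
#' Applies a [boost_spec()] to the absolute RPE: boosting always uses
#' \eqn{|\delta_{pe}|}, so unexpected bad news boosts dread just as
#' unexpected good news boosts savouring. The step function takes
#' \eqn{\theta(0) = 0}: a fully predicted cue is never boosted, and RPE
#' magnitudes below 1e-12 are treated as zero.
#'
#' @param eta0 Baseline weight.
#' @param boost A [boost_spec()].
#' @param delta_pe Reward prediction error at the cue (may be negative).
#' @return The realized weight \eqn{\eta}, vectorised over `delta_pe`.
#' @examples
#' boost_weight(0.3, boost_spec("linear", c = 3), delta_pe = -0.5)
#' @export
boost_weight <- function(eta0, boost, delta_pe) {
  stopifnot(inherits(boost, "boost_spec"))
  a <- abs(delta_pe)
  a[a < .rpe_zero_tol] <- 0
  switch(boost$kind,
    none = rep_len(eta0, length(a)) + 0 * a,
    linear = eta0 + boost$c * a,
    tanh = eta0 + boost$c1 * tanh(boost$c2 * a),
    step = eta0 + boost$c * as.numeric(a > 0),
    rlang::abort("unknown boost kind", class = "savouR_config_error")
  )
}

#' Total value of a reward-predictive cue
#'
#' Assembles the cue value
#' \deqn{Q = \eta A + B}
#' from the integrated discounted anticipation `A` and the discounted reward
#' `B`, at a given realized anticipation weight `eta`. As a function of the
#' delay, \eqn{Q(0) = R}, and for \eqn{R > 0}, \eqn{\eta > \gamma/\nu}-type
#' regimes the value rises to an interior maximum above `R` before
#' discounting pulls it back to zero — the inverted-U signature of
#' anticipatory utility.
#'
#' @param params An [anticipation_params()].
#' @param T Delay (s); may be a vector.
#' @param eta Realized anticipation weight; defaults to `params$eta0`.
#' @return A tibble with columns `T`, `A`, `B`, `eta`, `Q`.
#' @examples
#' p <- anticipation_params(R = 1, nu = 0.5, gamma = 0.1)
#' cue_value(p, T = c(0, 2, 10), eta = 1)
#' @export
cue_value <- function(params, T, eta = NULL) {
  stopifnot(inherits(params, "anticipation_params"))
  eta <- eta %||% params$eta0
  A <- integrated_anticipation(params$R, params$nu, params$gamma, T)
  B <- discounted_reward(params$R, params$gamma, T)
  tibble::tibble(T = T, A = A, B = B, eta = eta, Q = eta * A + B)
}

#' Softmax (logistic) choice probability
#'
#' Probability of choosing option x over option y given their values:
#' \deqn{P(x) = \frac{1}{1 + e^{-(Q_x - Q_y)/\sigma}}.}
#'
#' @param q_x,q_y Option values.
#' @param sigma Temperature, > 0.
#' @return Choice probability, vectorised.
#' @examples
#' choice_probability(1, 0, sigma = 1)
#' @export
choice_probability <- function(q_x, q_y, sigma) {
  if (any(sigma <= 0)) {
    rlang::abort("softmax temperature `sigma` must be positive",
                 class = "savouR_domain_error")
  }
  stats::plogis((q_x - q_y) / sigma)
}

#' Plot the cue value as a function of delay
#'
#' Draws the inverted-U value curve \eqn{Q(T) = \eta A(T) + B(T)} together
#' with its anticipation and discounted-reward components.
#'
#' @param params An [anticipation_params()].
#' @param T_max Largest delay to plot (s).
#' @param eta Realized anticipation weight; defaults to `params$eta0`.
#' @param n Number of grid points.
#' @return A ggplot object.
#' @export
plot_cue_value <- function(params, T_max = 60, eta = NULL, n = 200) {
  values <- cue_value(params, T = seq(0, T_max, length.out = n), eta = eta)
  long <- tidyr::pivot_longer(
    dplyr::mutate(values, anticipation = .data$eta * .data$A,
                  reward = .data$B, total = .data$Q),
    c("anticipation", "reward", "total"),
    names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$T, .data$value,
                                     linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "delay T (s)", y = "value",
                  title = "Cue value under anticipatory utility") +
    ggplot2::theme_minimal()
}
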