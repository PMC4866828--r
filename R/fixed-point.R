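#' Self-consistency problem for the boosted RPE
#'
#' Because the RPE at a predictive cue boosts the anticipation weight, which
#' raises the cue value, which in turn determines the RPE, the equilibrium
#' RPE solves a self-consistency equation. For tasks where the RPE is a
#' linear combination of cue values this takes the form
#' \deqn{\delta_{pe} = \alpha\,g(|\delta_{pe}|) + \beta}
#' where `slope` \eqn{\alpha} and `intercept` \eqn{\beta} are fixed by the
#' task, and \eqn{g} is the identity (linear/step boosting) or
#' \eqn{\tanh(c_2 \cdot)} (tanh boosting).
#'
#' @param slope Coefficient \eqn{\alpha} on the boosted term (dimensionless).
#' @param intercept Constant \eqn{\beta} (utility units).
#' @param boost A [boost_spec()] selecting the ansatz that closes the loop.
#' @return An object of class `selfconsistency`.
#' @seealso [solve_selfconsistent()]
#' @export
selfconsistency <- function(slope, intercept, boost = boost_spec("linear", c = 1)) {
  stopifnot(inherits(boost, "boost_spec"))
  if (boost$kind == "none") {
    rlang::abort("a self-consistency problem requires a boosting ansatz",
                 class = "savouR_config_error")
  }
  structure(list(slope = slope, intercept = intercept, boost = boost),
            class = "selfconsistency")
}

#' Solve a boosted-RPE self-consistency problem
#'
#' For the linear ansatz with positive intercept the solution is the closed
#' form \eqn{\delta_{pe} = \beta / (1 - \alpha)}, which exists only when
#' \eqn{\alpha < 1}: with \eqn{\alpha > 1} and \eqn{\beta > 0} the linear
#' boosting is unbounded and no finite equilibrium exists. The tanh ansatz is
#' bounded, so a root always exists and is found by bracketed bisection. The
#' step ansatz yields \eqn{\delta = \alpha + \beta} when that is consistent
#' with a non-zero RPE, else \eqn{\beta}.
#'
#' Non-existence is reported as a result (`exists = FALSE`), not an error,
#' so that parameter sweeps can mask unstable cells.
#'
#' @param problem A [selfconsistency()] object.
#' @param tol Bisection tolerance for the tanh ansatz.
#' @return A tibble with columns `delta_pe`, `exists`, `stability_margin`
#'   (\eqn{1 - \alpha} times the local boost slope; positive on the stable
#'   region) and `residual`.
#' @examples
#' solve_selfconsistent(selfconsistency(0.5, 1))
#' solve_selfconsistent(selfconsistency(2, 0.5, boost_spec("tanh", c1 = 1, c2 = 1)))
#' @export
solve_selfconsistent <- function(problem, tol = 1e-12) {
  stopifnot(inherits(problem, "selfconsistency"))
  a <- problem$slope
  b <- problem$intercept
  kind <- problem$boost$kind

  if (kind %in% c("linear", "step")) {
    if (kind == "step") {
      # theta(|delta|) is 0 or 1; the boosted branch is consistent
      # whenever alpha + beta is non-zero
      d <- a + b
      delta <- if (abs(d) > .rpe_zero_tol) d else b
      resid <- delta - (a * as.numeric(abs(delta) > .rpe_zero_tol) + b)
      return(tibble::tibble(delta_pe = delta, exists = TRUE,
                            stability_margin = 1, residual = abs(resid)))
    }
    # linear: delta = a*|delta| + b
    if (b >= 0) {
      if (a < 1) {
        delta <- b / (1 - a)
        return(tibble::tibble(delta_pe = delta, exists = TRUE,
                              stability_margin = 1 - a,
                              residual = abs(delta - (a * abs(delta) + b))))
      }
      return(tibble::tibble(delta_pe = NA_real_, exists = FALSE,
                            stability_margin = 1 - a, residual = NA_real_))
    }
    # negative intercept: a negative solution delta = -|delta| path,
    # |delta| = -b/(1+a) always exists for a > -1
    delta <- b / (1 + a)
    return(tibble::tibble(delta_pe = delta, exists = TRUE,
                          stability_margin = 1 + a,
                          residual = abs(delta - (a * abs(delta) + b))))
  }

  if (kind == "tanh") {
    c2 <- problem$boost$c2
    f <- function(d) d - (a * tanh(c2 * abs(d)) + b)
    # a root is bracketed within |d| <= |a| + |b| + 1 since tanh is bounded
    hi <- abs(a) + abs(b) + 1
    lo <- -hi
    while (f(lo) > 0 || f(hi) < 0) {   # defensive growth; f is increasing at its ends
      lo <- 2 * lo; hi <- 2 * hi
      if (hi > 1e12) {
        rlang::abort("failed to bracket the tanh self-consistency root",
                     class = "savouR_config_error")
      }
    }
    root <- stats::uniroot(f, c(lo, hi), tol = tol)$root
    slope_at <- a * c2 * sign(root) * (1 - tanh(c2 * abs(root))^2)
    return(tibble::tibble(delta_pe = root, exists = TRUE,
                          stability_margin = 1 - slope_at,
                          residual = abs(f(root))))
  }

  rlang::abort("unknown boost kind", class = "savouR_config_error")
}

#' Self-consistently boosted value of a reward-predictive cue
#'
#' In a task where the chosen target is followed by the rewarded cue with
#' probability `p_cue` (and by an unrewarded cue worth zero otherwise), the
#' cue's RPE is \eqn{\delta_{pe} = (1 - p_{cue})\,Q_{S+}}, and the boosted
#' value under the linear ansatz has the closed form
#' \deqn{Q_{S+} = \frac{\eta_0 A + B}{1 - (1 - p_{cue})\,c\,A},}
#' valid on the stable region \eqn{(1 - p_{cue})\,c\,A < 1}. Outside it the
#' linear boosting diverges and a `savouR_no_solution` error carrying the
#' stability margin is thrown. The tanh ansatz is solved by bisection of the
#' self-consistency equation and is stable everywhere.
#'
#' @param p_cue Probability that the rewarded cue follows the chosen target
#'   (0 < p_cue <= 1).
#' @param params An [anticipation_params()]; `params$boost` selects the
#'   ansatz.
#' @param T Delay between cue and reward (s).
#' @return A tibble with columns `T`, `A`, `B`, `eta`, `Q`, `delta_pe`,
#'   `stability_margin`.
#' @examples
#' p <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
#'                          boost = boost_spec("linear", c = 3))
#' boosted_cue_value(0.5, p, T = 1)
#' @export
boosted_cue_value <- function(p_cue, params, T) {
  stopifnot(inherits(params, "anticipation_params"))
  if (p_cue <= 0 || p_cue > 1) {
    rlang::abort("`p_cue` must lie in (0, 1]", class = "savouR_domain_error")
  }
  A <- integrated_anticipation(params$R, params$nu, params$gamma, T)
  B <- discounted_reward(params$R, params$gamma, T)
  base <- params$eta0 * A + B
  kind <- params$boost$kind

  if (kind %in% c("none", "linear")) {
    cc <- params$boost$c
    margin <- 1 - (1 - p_cue) * cc * A
    if (any(margin <= 0)) {
      rlang::abort(
        "no stable boosted value: (1 - p_cue) * c * A >= 1",
        class = "savouR_no_solution",
        stability_margin = margin)
    }
    Q <- base / margin
    delta <- (1 - p_cue) * Q
    eta <- boost_weight(params$eta0, params$boost, delta)
  } else if (kind == "step") {
    # discontinuous boost: the boosted branch delta = (1-p)((eta0+c)A + B)
    # is self-consistent whenever it is non-zero
    boosted <- (1 - p_cue) * ((params$eta0 + params$boost$c) * A + B)
    unboosted <- (1 - p_cue) * base
    delta <- ifelse(abs(boosted) > .rpe_zero_tol, boosted, unboosted)
    eta <- boost_weight(params$eta0, params$boost, delta)
    Q <- eta * A + B
    margin <- rep_len(1, length(Q))
  } else {
    # tanh ansatz: solve delta = (1-p)*(eta(delta)*A + B) by root finding
    solve_one <- function(Ai, Bi) {
      f <- function(d) {
        d - (1 - p_cue) * (boost_weight(params$eta0, params$boost, d) * Ai + Bi)
      }
      hi <- (1 - p_cue) * ((params$eta0 + params$boost$c1) *
                             abs(Ai) + abs(Bi)) + 1
      stats::uniroot(f, c(-hi, hi), tol = 1e-12, extendInt = "yes")$root
    }
    delta <- mapply(solve_one, A, B)
    eta <- boost_weight(params$eta0, params$boost, delta)
    Q <- eta * A + B
    margin <- rep_len(1, length(Q))
  }
  tibble::tibble(T = T, A = A, B = B, eta = eta, Q = Q,
                 delta_pe = delta, stability_margin = margin)
}
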