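#' The macaque information-choice task
#'
#' Three targets differ only in how often they are followed by an
#' uncertainty-resolving cue: the 100% info target always leads to a
#' definitive cue (big- or small-reward predicting, equiprobable), the 0%
#' info target always leads to an ambiguous cue, and the 50% info target
#' mixes the two. Reward contingencies are identical across targets, so any
#' preference reflects the value of the predictive cues themselves.
#'
#' @param r_big,r_small Large and small reward magnitudes (`r_big > r_small >= 0`).
#' @param T Delay between cue and reward (s).
#' @param info_probs Named numeric vector mapping target to its probability
#'   of producing an informative cue.
#' @return An object of class `info_task`.
#' @examples
#' info_task()
#' @export
info_task <- function(r_big = 0.88, r_small = 0.04, T = 2.25,
                      info_probs = c("100" = 1, "50" = 0.5, "0" = 0)) {
  if (r_big < r_small || r_small < 0) {
    rlang::abort("`r_big` must be at least `r_small` and both be non-negative",
                 class = "savouR_domain_error")
  }
  if (any(info_probs < 0 | info_probs > 1)) {
    rlang::abort("`info_probs` must be probabilities",
                 class = "savouR_domain_error")
  }
  structure(list(r_big = r_big, r_small = r_small, T = T,
                 info_probs = info_probs),
            class = "info_task")
}

#' Self-consistent target, cue and RPE values for the information task
#'
#' Solves the coupled equilibrium: target values are probability-weighted
#' means of cue values; cue values depend on the anticipation weight, itself
#' boosted by the RPE at the cue; and the RPE is the difference between the
#' cue value and the value of the preceding target. The system is solved by
#' damped fixed-point iteration on the per-(cue, target) RPEs.
#'
#' Without boosting (`c = 0`) anticipation is identical after every target
#' and the three targets have exactly equal value.
#'
#' @param task An [info_task()].
#' @param params An [anticipation_params()]; reward magnitudes come from the
#'   task, the growth/discount rates, baseline weight and boost rule from
#'   `params`.
#' @param damping Damping factor in (0, 1] applied to the RPE update.
#' @param tol Convergence tolerance on the RPE update.
#' @param max_iter Iteration cap; exceeding it raises `savouR_no_solution`.
#' @return An object of class `monkey_values`: a list with tibbles
#'   `targets` (target, Q), `cues` (cue, Q), `pairs` (cue, target, delta_pe,
#'   eta, V), `outcomes` (outcome-delivery RPEs after the ambiguous cue),
#'   plus `iterations` and `converged`.
#' @examples
#' p <- anticipation_params(nu = 0.5, gamma = 0.1, eta0 = 1,
#'                          boost = boost_spec("linear", c = 5), sigma = 0.08)
#' monkey_values(info_task(), p)
#' @export
monkey_values <- function(task, params, damping = 0.5, tol = 1e-10,
                          max_iter = 1e4) {
  stopifnot(inherits(task, "info_task"), inherits(params, "anticipation_params"))

  A_big <- integrated_anticipation(task$r_big, params$nu, params$gamma, task$T)
  B_big <- discounted_reward(task$r_big, params$gamma, task$T)
  A_small <- integrated_anticipation(task$r_small, params$nu, params$gamma, task$T)
  B_small <- discounted_reward(task$r_small, params$gamma, task$T)

  targets <- names(task$info_probs)
  p_info <- task$info_probs
  # (cue, target) pairs that occur: informative cues after targets with
  # p_info > 0, the ambiguous cue after targets with p_info < 1
  pairs <- dplyr::bind_rows(
    tidyr::expand_grid(cue = c("big", "small"), target = targets[p_info > 0]),
    tidyr::expand_grid(cue = "random", target = targets[p_info < 1]))

  delta <- stats::setNames(rep(0, nrow(pairs)),
                           paste(pairs$cue, pairs$target, sep = "."))
  value_of <- function(cue, eta) {
    switch(cue,
      big = eta * A_big + B_big,
      small = eta * A_small + B_small,
      random = ((eta * A_big + B_big) + (eta * A_small + B_small)) / 2)
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- boost_weight(params$eta0, params$boost, delta)
    V <- vapply(seq_len(nrow(pairs)),
                function(i) value_of(pairs$cue[i], eta[i]), numeric(1))
    # cue values: plain average of the per-preceding-target means
    q_cue <- vapply(c("big", "small", "random"), function(cu) {
      mean(V[pairs$cue == cu])
    }, numeric(1))
    q_target <- p_info / 2 * (q_cue[["big"]] + q_cue[["small"]]) +
      (1 - p_info) * q_cue[["random"]]
    delta_new <- q_cue[pairs$cue] - q_target[pairs$target]
    step <- delta_new - delta
    delta <- delta + damping * step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter || any(!is.finite(delta)) || max(abs(delta)) > 1e8) {
      rlang::abort(
        "information-task equilibrium did not converge (boosting too strong?)",
        class = "savouR_no_solution",
        iterations = iter, max_step = max(abs(step)))
    }
  }

  eta <- boost_weight(params$eta0, params$boost, delta)
  V <- vapply(seq_len(nrow(pairs)),
              function(i) value_of(pairs$cue[i], eta[i]), numeric(1))
  q_cue <- vapply(c("big", "small", "random"),
                  function(cu) mean(V[pairs$cue == cu]), numeric(1))
  q_target <- p_info / 2 * (q_cue[["big"]] + q_cue[["small"]]) +
    (1 - p_info) * q_cue[["random"]]

  # outcome-delivery RPE after the ambiguous cue: the expected outcome at
  # delivery is the plain mean of the two magnitudes
  expected_outcome <- (task$r_big + task$r_small) / 2
  outcomes <- tibble::tibble(
    outcome = c("big", "small"),
    delta_pe = c(task$r_big, task$r_small) - expected_outcome)

  structure(list(
    targets = tibble::tibble(target = targets, Q = unname(q_target)),
    cues = tibble::tibble(cue = names(q_cue), Q = unname(q_cue)),
    pairs = tibble::tibble(cue = pairs$cue, target = pairs$target,
                           delta_pe = unname(delta), eta = unname(eta),
                           V = V),
    outcomes = outcomes,
    task = task, params = params,
    iterations = iter, converged = converged),
    class = "monkey_values")
}

#' @export
print.monkey_values <- function(x, ...) {
  cat("<monkey_values> converged in", x$iterations, "iterations\n")
  print(x$targets)
  invisible(x)
}

#' Pairwise choice probabilities between information targets
#'
#' Maps the equilibrium target values to pairwise softmax preferences.
#'
#' @param values A [monkey_values()] result.
#' @param sigma Softmax temperature; defaults to the temperature stored in
#'   the fitted parameters.
#' @return A tibble with columns `target_x`, `target_y`, `p_choose_x`.
#' @export
monkey_preferences <- function(values, sigma = NULL) {
  stopifnot(inherits(values, "monkey_values"))
  sigma <- sigma %||% values$params$sigma
  q <- stats::setNames(values$targets$Q, values$targets$target)
  combos <- utils::combn(values$targets$target, 2)
  tibble::tibble(
    target_x = combos[1, ], target_y = combos[2, ],
    p_choose_x = unname(choice_probability(q[combos[1, ]], q[combos[2, ]],
                                           sigma)))
}

#' Squared-error surface of predicted vs observed target preferences
#'
#' Sweeps a grid of baseline anticipation weights and boosting gains,
#' computing for each cell the model's pairwise preferences and their total
#' squared error against a supplied set of observed preferences. Cells where
#' the boosted equilibrium diverges are masked (`stable = FALSE`).
#'
#' @param task An [info_task()].
#' @param params Template [anticipation_params()] providing rates and
#'   temperature; `eta0` and the linear boost gain are overridden per cell.
#' @param eta0_grid,c_grid Numeric grids.
#' @param observed Named numeric vector of observed choice probabilities,
#'   named like `"100-50"` (probability the first-named target is chosen).
#' @return A tibble with columns `eta0`, `c`, `sq_error`, `stable`.
#' @export
monkey_param_sweep <- function(task, params, eta0_grid, c_grid, observed) {
  grid <- tidyr::expand_grid(eta0 = eta0_grid, c = c_grid)
  res <- purrr::pmap_dfr(grid, function(eta0, c) {
    p <- anticipation_params(R = params$R, nu = params$nu, gamma = params$gamma,
                             eta0 = eta0,
                             boost = boost_spec("linear", c = c),
                             sigma = params$sigma)
    out <- tryCatch({
      mv <- monkey_values(task, p)
      pref <- monkey_preferences(mv)
      key <- paste(pref$target_x, pref$target_y, sep = "-")
      pred <- stats::setNames(pref$p_choose_x, key)
      err <- sum((pred[names(observed)] - observed)^2)
      tibble::tibble(sq_error = err, stable = TRUE)
    }, savouR_no_solution = function(e) {
      tibble::tibble(sq_error = NA_real_, stable = FALSE)
    })
    dplyr::bind_cols(tibble::tibble(eta0 = eta0, c = c), out)
  })
  res
}

#' Plot a preference squared-error sweep surface
#'
#' @param sweep Result of [monkey_param_sweep()].
#' @return A ggplot object; unstable cells are blank.
#' @export
plot_param_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$c, .data$eta0,
                                      fill = .data$sq_error)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "boost gain c", y = "baseline weight eta0",
                  fill = "squared error") +
    ggplot2::theme_minimal()
}
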