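#' Generalized pigeon observing task
#'
#' A two-target observing paradigm. The informative target is followed with
#' probability `p_info` by a cue that guarantees a reward `r_info` after
#' delay `T`, and otherwise by a cue guaranteeing nothing. The uninformative
#' target is followed by a non-predictive cue and rewarded with `r_noinfo`
#' with probability `p_noinfo`. The classic delay-dependent suboptimal
#' preference corresponds to `p_info = 0.5`, `p_noinfo = 1` (certain reward
#' foregone for the informative, half-rewarded target); `p_noinfo = 0.75`
#' and the `p_info = 0.2` vs `p_noinfo = 0.5` variant are also special
#' cases. The value of "no outcome" is fixed at zero.
#'
#' @param p_info Probability the informative target's rewarded cue appears.
#' @param p_noinfo Reward probability of the uninformative target.
#' @param r_info,r_noinfo Reward magnitudes.
#' @param T Delay between cue and reward (s); may be a vector.
#' @return An object of class `pigeon_task`.
#' @examples
#' pigeon_task(p_noinfo = 1, T = 1)
#' @export
pigeon_task <- function(p_info = 0.5, p_noinfo = 1, r_info = 1, r_noinfo = 1,
                        T = 1) {
  if (any(c(p_info, p_noinfo) < 0) || any(c(p_info, p_noinfo) > 1)) {
    rlang::abort("probabilities must lie in [0, 1]",
                 class = "savouR_domain_error")
  }
  if (p_info <= 0) {
    rlang::abort("`p_info` must be positive (the rewarded cue must occur)",
                 class = "savouR_domain_error")
  }
  structure(list(p_info = p_info, p_noinfo = p_noinfo,
                 r_info = r_info, r_noinfo = r_noinfo, T = T),
            class = "pigeon_task")
}

#' Value difference between informative and uninformative targets
#'
#' Computes \eqn{\Delta Q = Q_{info} - Q_{noinfo}} for a [pigeon_task()].
#' Under the linear boosting ansatz the informative target's rewarded-cue
#' value is boosted self-consistently,
#' \deqn{\Delta Q = (\eta_0 a + b)\left(
#'   \frac{p_I R_I}{1 - (1 - p_I)\,c\,A_I} - p_N R_N\right),}
#' where \eqn{a, b} are the unit-reward anticipation and discount factors
#' and \eqn{A_I = R_I a}. Without boosting (`c = 0`) the bracket reduces to
#' \eqn{p_I R_I - p_N R_N}: the conventional model always prefers the richer
#' target. With boosting, preference for the poorer-but-informative target
#' emerges at intermediate delays and reverses back at long delays as
#' discounting dominates.
#'
#' @param task A [pigeon_task()].
#' @param params An [anticipation_params()]; `params$boost` selects the
#'   ansatz (linear closed form, or tanh/step via root finding).
#' @return A tibble with columns `T`, `q_info`, `q_noinfo`, `delta_q`,
#'   `stable`, `stability_margin`. Under the linear ansatz, cells violating
#'   the stability condition have `stable = FALSE` and `NA` values.
#' @examples
#' p <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
#'                          boost = boost_spec("linear", c = 3))
#' pigeon_delta_q(pigeon_task(p_noinfo = 1, T = c(0.1, 1, 5)), p)
#' @export
pigeon_delta_q <- function(task, params) {
  stopifnot(inherits(task, "pigeon_task"), inherits(params, "anticipation_params"))
  T <- task$T
  a <- integrated_anticipation(1, params$nu, params$gamma, T)
  b <- discounted_reward(1, params$gamma, T)
  base <- params$eta0 * a + b                     # unit-reward (eta0 A + B)
  q_noinfo <- task$p_noinfo * task$r_noinfo * base
  A_I <- task$r_info * a

  kind <- params$boost$kind
  if (kind %in% c("none", "linear")) {
    margin <- 1 - (1 - task$p_info) * params$boost$c * A_I
    stable <- margin > 0
    q_splus <- ifelse(stable, task$r_info * base / margin, NA_real_)
  } else {
    pars_i <- anticipation_params(R = task$r_info, nu = params$nu,
                                  gamma = params$gamma, eta0 = params$eta0,
                                  boost = params$boost, sigma = params$sigma)
    solved <- purrr::map_dfr(T, function(Ti) {
      boosted_cue_value(task$p_info, pars_i, Ti)
    })
    q_splus <- solved$Q
    margin <- solved$stability_margin
    stable <- rep_len(TRUE, length(q_splus))
  }
  q_info <- task$p_info * q_splus                 # the unrewarded cue is worth 0
  tibble::tibble(T = T, q_info = q_info, q_noinfo = q_noinfo,
                 delta_q = q_info - q_noinfo,
                 stable = stable, stability_margin = margin)
}

#' Preference phase diagram over reward probability and scaled delay
#'
#' Evaluates the sign of \eqn{\Delta Q} on a grid of uninformative-target
#' reward probabilities and dimensionless delays \eqn{\gamma T}, marking
#' cells where the linear self-consistency condition fails. The diagram
#' interpolates between the classic observing experiments (certain vs
#' 50%-rewarded informative target at `p_noinfo = 1`, the 75% variant, and
#' the symmetric `p_noinfo = 0.5` case).
#'
#' @param params An [anticipation_params()].
#' @param p_noinfo Grid of uninformative-target reward probabilities.
#' @param gamma_T Grid of dimensionless delays \eqn{\gamma T}.
#' @param p_info Rewarded-cue probability of the informative target.
#' @param r_info,r_noinfo Reward magnitudes.
#' @return A tibble of class `pigeon_phase` with columns `p_noinfo`,
#'   `gamma_T`, `delta_q`, `preference` (`"info"`/`"noinfo"`/`"tie"`),
#'   `stable`.
#' @examples
#' p <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
#'                          boost = boost_spec("linear", c = 3))
#' phase_diagram(p, p_noinfo = c(0.5, 0.75, 1), gamma_T = c(0.1, 1, 3))
#' @export
phase_diagram <- function(params, p_noinfo = seq(0.5, 1, by = 0.05),
                          gamma_T = seq(0.05, 5, length.out = 60),
                          p_info = 0.5, r_info = 1, r_noinfo = 1) {
  stopifnot(inherits(params, "anticipation_params"))
  if (params$gamma <= 0) {
    rlang::abort("phase diagrams use the gamma-scaled delay axis; `gamma` must be > 0",
                 class = "savouR_domain_error")
  }
  grid <- tidyr::expand_grid(p_noinfo = p_noinfo, gamma_T = gamma_T)
  res <- purrr::pmap_dfr(grid, function(p_noinfo, gamma_T) {
    task <- pigeon_task(p_info = p_info, p_noinfo = p_noinfo,
                        r_info = r_info, r_noinfo = r_noinfo,
                        T = gamma_T / params$gamma)
    dq <- pigeon_delta_q(task, params)
    tibble::tibble(p_noinfo = p_noinfo, gamma_T = gamma_T,
                   delta_q = dq$delta_q, stable = dq$stable)
  })
  res$preference <- dplyr::case_when(
    !res$stable ~ NA_character_,
    res$delta_q > 0 ~ "info",
    res$delta_q < 0 ~ "noinfo",
    TRUE ~ "tie")
  class(res) <- c("pigeon_phase", class(res))
  res
}

#' @export
autoplot.pigeon_phase <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$gamma_T, .data$p_noinfo,
                                       fill = .data$preference)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(info = "#c0392b", noinfo = "#2980b9", tie = "grey80"),
      na.value = "grey40") +
    ggplot2::labs(x = expression(gamma * T), y = "p (uninformative reward)",
                  fill = "preferred",
                  title = "Observing-preference phase diagram") +
    ggplot2::theme_minimal()
}

#' Write a phase diagram as CSV matrices
#'
#' Writes the sign matrix (rows = `p_noinfo`, columns = `gamma_T`) and a
#' parallel stability mask.
#'
#' @param phase A [phase_diagram()] result.
#' @param file Base path; `<file>_sign.csv` and `<file>_mask.csv` are
#'   written.
#' @return Invisibly, the two file paths.
#' @export
write_phase_diagram <- function(phase, file) {
  wide <- tidyr::pivot_wider(
    dplyr::select(phase, "p_noinfo", "gamma_T", "delta_q"),
    names_from = "gamma_T", values_from = "delta_q")
  mask <- tidyr::pivot_wider(
    dplyr::select(phase, "p_noinfo", "gamma_T", "stable"),
    names_from = "gamma_T", values_from = "stable")
  paths <- paste0(file, c("_sign.csv", "_mask.csv"))
  readr::write_csv(wide, paths[1])
  readr::write_csv(mask, paths[2])
  invisible(paths)
}
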