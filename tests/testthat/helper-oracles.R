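# Independent oracles used across tests.

# numerical quadrature of the anticipation integral
# int_0^T exp(-gamma t) * R * exp(-nu (T - t)) dt
quadrature_anticipation <- function(R, nu, gamma, T) {
  if (T == 0) return(0)
  stats::integrate(function(t) exp(-gamma * t) * R * exp(-nu * (T - t)),
                   0, T, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# damped fixed-point iteration for delta = slope * |delta| + intercept
iterate_linear_fp <- function(slope, intercept, damping = 0.5,
                              max_iter = 20000, tol = 1e-12) {
  d <- 0
  for (i in seq_len(max_iter)) {
    d_new <- slope * abs(d) + intercept
    step <- d_new - d
    d <- d + damping * step
    if (abs(step) < tol) return(list(delta = d, converged = TRUE))
    if (abs(d) > 1e10) return(list(delta = NA_real_, converged = FALSE))
  }
  list(delta = d, converged = FALSE)
}

# plain bisection for delta = a * tanh(c2 * |delta|) + b
bisect_tanh_fp <- function(a, c2, b, lo = -1e3, hi = 1e3, tol = 1e-12) {
  f <- function(d) d - (a * tanh(c2 * abs(d)) + b)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# session log-likelihood recomputed from the exported small operations
reference_session_loglik <- function(data, params,
                                     model = make_model("boosted_full")) {
  data <- data[order(data$trial_index), ]
  q <- c(q_info = 0, q_noinfo = 0)
  ll <- 0
  for (t in seq_len(nrow(data))) {
    p_info <- trial_choice_prob(q[["q_info"]], q[["q_noinfo"]], params$sigma)
    p_obs <- if (data$choice[t] == "info") p_info else 1 - p_info
    ll <- ll + log(p_obs)
    V <- outcome_value(params, model, data$choice[t], data$outcome[t],
                       data$delay_s[t])
    q <- q_update(q[["q_info"]], q[["q_noinfo"]], data$choice[t], V,
                  params$alpha)
  }
  ll
}
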