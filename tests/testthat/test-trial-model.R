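test_that("the model zoo has the published free-parameter counts", {
  counts <- vapply(model_zoo(), `[[`, integer(1), "n_params")
  expect_equal(unname(counts[c("q_learning", "q_learning_discount",
                               "anticipation_no_boost", "boosted_no_rminus",
                               "boosted_no_discount", "boosted_full")]),
               c(3L, 5L, 7L, 4L, 5L, 6L))
  expect_equal(make_model("boosted_asymmetric")$n_params, 6L)
  expect_error(make_model("nonsense"))
})

test_that("natural and transformed parameter scales are mutual inverses", {
  set.seed(3)
  for (nm in names(model_zoo())) {
    model <- make_model(nm)
    for (i in 1:20) {
      theta <- stats::rnorm(model$n_params, sd = 1.5)
      p <- par_untransform(model, theta)
      expect_equal(unname(par_transform(model, p)), theta, tolerance = 1e-12)
      expect_true(p$alpha >= 0 && p$alpha <= 1)
      expect_true(p$gamma_plus >= 0 && p$nu_plus >= 0)
    }
  }
})

test_that("outcome values combine boosted anticipation and discounting", {
  p <- fitted_group_means()
  # savoured reward after an informative cue at 20 s
  expect_equal(outcome_value(p, choice = "info", outcome = "reward", T = 20),
               5.4837, tolerance = 1e-3)
  # uninformative path earns no anticipation credit when eta0 = 0
  expect_equal(outcome_value(p, choice = "noinfo", outcome = "reward", T = 20),
               0.85 * exp(-0.041 * 20), tolerance = 1e-10)
  # immediate delivery: value is the outcome itself
  expect_equal(outcome_value(p, choice = "info", outcome = "reward", T = 0),
               p$r_plus)
  # dread: negative anticipation below the discounted negative outcome
  v_minus <- outcome_value(p, choice = "info", outcome = "noreward", T = 7.5)
  expect_lt(v_minus, p$r_minus * exp(-0.041 * 7.5))
  expect_error(outcome_value(p, choice = "left", outcome = "reward", T = 1),
               class = "savouR_domain_error")
})

test_that("expected target-value difference is c(A+ + A-)/2, zero without boosting", {
  p <- fitted_group_means()
  T <- 20
  v_info <- (outcome_value(p, choice = "info", outcome = "reward", T = T) +
               outcome_value(p, choice = "info", outcome = "noreward", T = T)) / 2
  v_noinfo <- (outcome_value(p, choice = "noinfo", outcome = "reward", T = T) +
                 outcome_value(p, choice = "noinfo", outcome = "noreward", T = T)) / 2
  A_plus <- integrated_anticipation(p$r_plus, p$nu_plus, p$gamma_plus, T)
  A_minus <- integrated_anticipation(p$r_minus, p$nu_minus, p$gamma_minus, T)
  expect_equal(v_info - v_noinfo, p$c * (A_plus + A_minus) / 2,
               tolerance = 1e-12)

  p0 <- trial_params(alpha = 0.2, c = 0, eta0 = 0.7)
  v_info0 <- (outcome_value(p0, choice = "info", outcome = "reward", T = T) +
                outcome_value(p0, choice = "info", outcome = "noreward", T = T)) / 2
  v_noinfo0 <- (outcome_value(p0, choice = "noinfo", outcome = "reward", T = T) +
                  outcome_value(p0, choice = "noinfo", outcome = "noreward", T = T)) / 2
  expect_equal(v_info0 - v_noinfo0, 0, tolerance = 1e-12)
})

test_that("the delta rule updates only the chosen target", {
  expect_equal(q_update(0, 0, "info", 1, 0.17),
               c(q_info = 0.17, q_noinfo = 0))
  expect_equal(q_update(0.4, -0.2, "noinfo", 1, 1),
               c(q_info = 0.4, q_noinfo = 1))
  expect_equal(q_update(0.4, -0.2, "info", 5, 0),
               c(q_info = 0.4, q_noinfo = -0.2))
  expect_error(q_update(0, 0, "info", 1, 1.2), class = "savouR_domain_error")
})

test_that("session log-likelihood composes the per-trial operations", {
  p <- fitted_group_means()
  d <- simulate_subject(p, builtin_design("exp2"), seed = 5)
  expect_equal(session_loglik(d, p), reference_session_loglik(d, p),
               tolerance = 1e-10)

  # alpha = 0: values never leave zero, every choice is a coin flip
  p0 <- trial_params(alpha = 0)
  expect_equal(session_loglik(d, p0), nrow(d) * log(0.5), tolerance = 1e-12)

  # one-trial dataset: ll is the log choice probability
  d1 <- d[1, ]
  expect_equal(session_loglik(d1, p), log(0.5), tolerance = 1e-12)

  # each appended trial strictly decreases the total
  lls <- vapply(c(5, 10, 25), function(n) session_loglik(d[1:n, ], p),
                numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("the likelihood surface is smooth in the fitted parameters", {
  p <- fitted_group_means()
  model <- make_model("boosted_full")
  d <- simulate_subject(p, builtin_design("exp2"), seed = 7)
  fn <- savouR:::make_loglik_fn(d[order(d$trial_index), ], model)
  theta <- par_transform(model, p)
  # central differences at two step sizes agree: no kinks or indexing bugs
  g1 <- pracma::grad(fn, theta, heps = 1e-4)
  g2 <- pracma::grad(fn, theta, heps = 1e-5)
  expect_equal(g1, g2, tolerance = 1e-5)
  expect_true(all(is.finite(g1)))
})
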