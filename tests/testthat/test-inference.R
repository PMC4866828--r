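test_that("trial balancing equalizes delay conditions deterministically", {
  d <- simulate_subject(fitted_group_means(), builtin_design("exp1"), seed = 1)
  b1 <- balance_trials(d, seed = 3)
  expect_equal(unname(c(table(b1$delay_s))), rep(18L, 4))
  expect_equal(nrow(b1), 72L)
  expect_identical(b1, balance_trials(d, seed = 3))
  expect_false(identical(b1, balance_trials(d, seed = 4)))
  # retained trials keep their original order
  expect_true(all(diff(b1$trial_index) > 0))

  # already balanced data pass through unchanged
  d2 <- simulate_subject(fitted_group_means(), builtin_design("exp2"), seed = 1)
  expect_equal(as.data.frame(balance_trials(d2, seed = 1)),
               as.data.frame(d2[order(d2$trial_index), ]))
})

test_that("the Laplace MAP matches the conjugate-Gaussian closed form", {
  # synthetic quadratic log-likelihood: N(obs | theta, diag(s2))
  obs <- c(0.8, -0.4, 1.2)
  s2 <- c(0.5, 0.2, 1.0)
  loglik <- function(theta) sum(stats::dnorm(obs, theta, sqrt(s2), log = TRUE))
  model <- make_model("q_learning")     # any 3-parameter shell
  prior <- group_prior(model, mu = c(0, 0, 0), var = c(1, 1, 1))
  res <- savouR:::map_laplace(loglik, prior, starts = cbind(c(0, 0, 0)))
  post_var <- 1 / (1 / s2 + 1)
  post_mean <- post_var * (obs / s2)
  expect_equal(unname(res$m), post_mean, tolerance = 1e-6)
  expect_equal(diag(res$cov), post_var, tolerance = 1e-4)
  # Laplace marginal is exact for a Gaussian model
  exact <- sum(stats::dnorm(obs, 0, sqrt(s2 + 1), log = TRUE))
  expect_equal(res$log_marginal, exact, tolerance = 1e-6)
})

test_that("subject MAP interpolates between prior mean and MLE", {
  model <- make_model("boosted_no_rminus")
  truth <- trial_params(alpha = 0.3, r_plus = 1, r_minus = 0, gamma = 0.05,
                        nu_plus = 0.1, nu_minus = 0)
  d <- simulate_subject(truth, builtin_design("exp1"), seed = 21)

  mu0 <- par_transform(model, truth) + 0.5
  tight <- group_prior(model, mu0, rep(1e-6, 4))
  fit_tight <- subject_map(d, tight, model, n_restarts = 1, seed = 1)
  expect_equal(unname(fit_tight$m), unname(mu0), tolerance = 1e-2)

  flat <- group_prior(model, mu0, rep(1e4, 4))
  fit_flat <- subject_map(d, flat, model, n_restarts = 2, seed = 1)
  # at the flat-prior optimum the prior contributes ~nothing: the fit is the MLE
  fn <- savouR:::make_loglik_fn(d[order(d$trial_index), ], model)
  expect_gt(fn(fit_flat$m), fn(unname(mu0)))       # beats the starting point
  g <- pracma::grad(fn, fit_flat$m)
  expect_lt(max(abs(g)), 0.05)                     # near-stationary likelihood
})

test_that("EM shrinks to the common solution for identical subjects", {
  p <- fitted_group_means()
  model <- make_model("boosted_full")
  one <- simulate_subject(p, builtin_design("exp1"), seed = 33)
  three <- purrr::map_dfr(1:3, function(i) {
    dplyr::mutate(one, subject_id = sprintf("S%02d", i))
  })
  fit <- em_fit(three, model,
                settings = em_settings(max_iter = 8, n_restarts = 2),
                seed = 5)
  # identical data: posterior means agree across subjects, group variance
  # collapses towards its floor
  m <- do.call(rbind, lapply(fit$posteriors, `[[`, "m"))
  expect_lt(max(apply(m, 2, function(col) diff(range(col)))), 1e-4)
  expect_equal(unname(fit$prior$mu), unname(colMeans(m)), tolerance = 1e-10)
  # the penalized-evidence surrogate never drops materially across iterations
  expect_true(all(diff(fit$surrogate) > -0.5))
})

test_that("EM fits are deterministic given the seed", {
  trials <- purrr::map_dfr(1:4, function(i) {
    simulate_subject(fitted_group_means(), builtin_design("exp2"),
                     seed = 50 + i, subject_id = sprintf("S%02d", i))
  })
  s <- em_settings(max_iter = 3, n_restarts = 2)
  f1 <- em_fit(trials, make_model("boosted_no_rminus"), settings = s, seed = 7)
  f2 <- em_fit(trials, make_model("boosted_no_rminus"), settings = s, seed = 7)
  expect_identical(f1$prior$mu, f2$prior$mu)
})

test_that("iBIC decomposes into Monte-Carlo evidence and a prior-count penalty", {
  trials <- purrr::map_dfr(1:3, function(i) {
    simulate_subject(fitted_group_means(), builtin_design("exp2"),
                     seed = 60 + i, subject_id = sprintf("S%02d", i))
  })
  model <- make_model("boosted_full")
  prior <- group_prior(model, par_transform(model, fitted_group_means()),
                       rep(0.05, 6))
  score <- ibic(trials, prior, model, K = 200, seed = 1)
  expect_equal(score$n_params_prior, 12L)
  expect_equal(score$n_data, nrow(trials))
  expect_equal(score$penalty, 12 * log(nrow(trials)))
  expect_equal(score$ibic, -2 * score$log_marginal + score$penalty)

  # a near-point-mass prior makes the MC marginal the likelihood at the mean
  point <- group_prior(model, par_transform(model, fitted_group_means()),
                       rep(1e-18, 6))
  sc_point <- ibic(trials, point, model, K = 17, seed = 2)
  ll <- sum(vapply(unique(trials$subject_id), function(id) {
    session_loglik(trials[trials$subject_id == id, ], fitted_group_means())
  }, numeric(1)))
  expect_equal(sc_point$log_marginal, ll, tolerance = 1e-6)

  # Monte-Carlo noise shrinks with K: two K values agree within a few points
  s1 <- ibic(trials, prior, model, K = 400, seed = 3)$ibic
  s2 <- ibic(trials, prior, model, K = 800, seed = 4)$ibic
  expect_lt(abs(s1 - s2), 5)
})

test_that("tidy and glance summarise fits on both scales", {
  trials <- purrr::map_dfr(1:3, function(i) {
    simulate_subject(fitted_group_means(), builtin_design("exp2"),
                     seed = 70 + i, subject_id = sprintf("S%02d", i))
  })
  fit <- em_fit(trials, make_model("boosted_no_rminus"),
                settings = em_settings(max_iter = 3, n_restarts = 1), seed = 2)
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "r_plus", "gamma", "nu_plus"))
  expect_equal(td$estimate[1], stats::plogis(td$transformed_mean[1]))
  expect_equal(td$estimate[3], exp(td$transformed_mean[3]))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 3L)
  expect_equal(gl$n_params, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("discounting is identified against its no-discount rival given enough trials", {
  # at modest trial counts the iBIC prior penalty can outweigh the evidence
  # for a small discount rate; with three sessions' worth of trials the
  # generating full model separates cleanly from the nested variant
  design3 <- builtin_design("exp1")
  design3$n_trials <- design3$n_trials * 3L
  spec <- cohort_spec_fitted()
  trials <- simulate_cohort(spec, design3, seed = 101, center = TRUE)
  cmp <- compare_models(
    trials,
    list(boosted_no_discount = make_model("boosted_no_discount"),
         boosted_full = make_model("boosted_full")),
    settings = em_settings(max_iter = 25, tol = 1e-3, n_restarts = 2),
    K = 3000, seed = 17)
  expect_equal(cmp$model[1], "boosted_full")
  expect_gt(cmp$ibic[2] - cmp$ibic[1], 2 * log(nrow(trials)))
})
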