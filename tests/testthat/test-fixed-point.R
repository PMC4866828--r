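test_that("linear self-consistency has the closed-form solution when stable", {
  res <- solve_selfconsistent(selfconsistency(0.5, 1))
  expect_true(res$exists)
  expect_equal(res$delta_pe, 2)

  res <- solve_selfconsistent(selfconsistency(1.2, 0.5))
  expect_false(res$exists)
  expect_lt(res$stability_margin, 0)

  # closed form agrees with damped-iteration oracle on random stable problems
  set.seed(11)
  for (i in 1:100) {
    a <- stats::runif(1, 0, 0.95)
    b <- stats::runif(1, -2, 2)
    closed <- solve_selfconsistent(selfconsistency(a, b))
    oracle <- iterate_linear_fp(a, b)
    expect_true(closed$exists)
    expect_true(oracle$converged)
    expect_equal(closed$delta_pe, oracle$delta, tolerance = 1e-8)
    expect_lt(closed$residual, 1e-10)
  }
})

test_that("tanh self-consistency is solved for any slope and intercept", {
  res <- solve_selfconsistent(
    selfconsistency(2, 0.5, boost_spec("tanh", c1 = 1, c2 = 1)))
  expect_equal(res$delta_pe, bisect_tanh_fp(2, 1, 0.5), tolerance = 1e-9)
  expect_lt(res$residual, 1e-10)

  # exists even where the linear ansatz fails
  res <- solve_selfconsistent(
    selfconsistency(1.5, 0.7, boost_spec("tanh", c1 = 1, c2 = 2)))
  expect_true(res$exists)
  expect_lt(res$residual, 1e-10)

  # small c2*|delta|: tanh solution approaches the linear one to first order
  for (a in c(0.3, 0.6)) {
    b <- 0.001
    lin <- solve_selfconsistent(selfconsistency(a, b))
    tnh <- solve_selfconsistent(
      selfconsistency(a, b, boost_spec("tanh", c1 = 1, c2 = 1)))
    expect_equal(tnh$delta_pe, lin$delta_pe, tolerance = 1e-4)
  }
})

test_that("step self-consistency picks the consistent branch", {
  res <- solve_selfconsistent(
    selfconsistency(0.4, 0.3, boost_spec("step", c = 1)))
  expect_equal(res$delta_pe, 0.7)
  res <- solve_selfconsistent(
    selfconsistency(0.4, -0.4, boost_spec("step", c = 1)))
  expect_equal(res$delta_pe, -0.4)   # alpha + beta = 0: unboosted branch
})

test_that("boosted cue value matches the closed form and the iterative oracle", {
  p0 <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
                            boost = boost_spec("none"))
  expect_equal(boosted_cue_value(0.5, p0, 1)$Q, cue_value(p0, 1, eta = 3)$Q)

  p <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
                           boost = boost_spec("linear", c = 3))
  v <- boosted_cue_value(0.5, p, 1)
  expect_equal(v$Q, 6.3363, tolerance = 1e-4)
  # self-consistency residual: delta = (1-p)*Q and Q = eta(delta)*A + B
  eta <- boost_weight(3, p$boost, v$delta_pe)
  expect_equal(v$Q, eta * v$A + v$B, tolerance = 1e-10)
  expect_equal(v$delta_pe, 0.5 * v$Q, tolerance = 1e-10)

  # iterative oracle on the same problem
  A <- v$A; B <- v$B
  oracle <- iterate_linear_fp(0.5 * 3 * A, 0.5 * (3 * A + B))
  expect_equal(v$delta_pe, oracle$delta, tolerance = 1e-8)
})

test_that("boosted value is increasing in the gain and fails loudly when unstable", {
  qs <- vapply(c(0, 0.5, 1, 1.5, 2), function(cc) {
    p <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
                             boost = boost_spec("linear", c = cc))
    boosted_cue_value(0.5, p, 1)$Q
  }, numeric(1))
  expect_true(all(diff(qs) > 0))

  p_bad <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
                               boost = boost_spec("linear", c = 10))
  err <- tryCatch(boosted_cue_value(0.5, p_bad, 1), condition = identity)
  expect_s3_class(err, "savouR_no_solution")
  expect_true(err$stability_margin <= 0)

  expect_error(boosted_cue_value(0, p_bad, 1), class = "savouR_domain_error")
})

test_that("tanh-boosted cue value solves its self-consistency directly", {
  p <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
                           boost = boost_spec("tanh", c1 = 3, c2 = 1))
  v <- boosted_cue_value(0.5, p, 1)
  # residual of delta = (1 - p_cue) * (eta(delta) A + B)
  eta <- boost_weight(3, p$boost, v$delta_pe)
  expect_equal(v$delta_pe, 0.5 * (eta * v$A + v$B), tolerance = 1e-9)
  # remains solvable where the linear ansatz diverges
  p_big <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
                               boost = boost_spec("tanh", c1 = 10, c2 = 3))
  expect_true(is.finite(boosted_cue_value(0.5, p_big, 1)$Q))

  # step boosting has its own closed form: eta jumps to eta0 + c whenever
  # the boosted branch RPE is non-zero
  p_step <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
                                boost = boost_spec("step", c = 4))
  v_step <- boosted_cue_value(0.5, p_step, 1)
  expect_equal(v_step$eta, 7)
  expect_equal(v_step$Q, 7 * v_step$A + v_step$B)
  expect_equal(v_step$delta_pe, 0.5 * v_step$Q, tolerance = 1e-12)
})
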