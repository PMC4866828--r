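#' Group-level prior for hierarchical fitting
#'
#' Diagonal Gaussian over the transformed parameters: per-subject parameter
#' vectors are treated as random effects with mean `mu` and variance `var`
#' (off-diagonal covariance is fixed at zero, assuming independent
#' effects).
#'
#' @param model An [make_model()] specification.
#' @param mu Numeric vector of group means (transformed scale).
#' @param var Numeric vector of group variances (> 0).
#' @return An object of class `group_prior`.
#' @export
group_prior <- function(model, mu, var) {
  stopifnot(inherits(model, "anticipation_model"),
            length(mu) == model$n_params, length(var) == model$n_params)
  if (any(var <= 0)) {
    rlang::abort("prior variances must be positive",
                 class = "savouR_domain_error")
  }
  structure(list(model = model,
                 mu = stats::setNames(as.numeric(mu), model$par_names),
                 var = stats::setNames(as.numeric(var), model$par_names)),
            class = "group_prior")
}

# generic neutral starting prior: mid-range learning rate, small symmetric
# outcome values, slow rates, broad variance
default_prior <- function(model) {
  mu <- vapply(model$free, function(par) {
    switch(par,
           alpha = stats::qlogis(0.3),
           r_plus = 0.1, r_minus = 0.1,
           gamma = , gamma_plus = , gamma_minus = log(0.05),
           nu_plus = , nu_minus = log(0.1),
           eta0 = log(0.5),
           0)
  }, numeric(1))
  group_prior(model, mu, rep(4, model$n_params))
}

# Laplace-approximate MAP for one (log-likelihood, prior) pair.
# `loglik_fn` maps a transformed parameter vector to a log-likelihood.
map_laplace <- function(loglik_fn, prior, starts, maxit = 500) {
  sd <- sqrt(prior$var)
  negobj <- function(theta) {
    v <- loglik_fn(theta) + sum(stats::dnorm(theta, prior$mu, sd, log = TRUE))
    if (!is.finite(v)) return(1e10)
    -v
  }
  best <- NULL
  for (s in seq_len(ncol(starts))) {
    fit <- tryCatch(
      stats::optim(starts[, s], negobj, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::optim(starts[, s], negobj, method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    rlang::abort("all MAP restarts failed", class = "savouR_fit_error")
  }
  H <- pracma::hessian(negobj, best$par)
  H <- (H + t(H)) / 2
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov))) {
    cov <- diag(1e-2, length(best$par))
  } else {
    # repair numerically indefinite covariances by eigenvalue flooring
    e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, 1e-8)
    cov <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  }
  k <- length(best$par)
  logdet <- determinant(cov, logarithm = TRUE)$modulus[1]
  list(m = stats::setNames(best$par, names(prior$mu)),
       cov = cov,
       logpost = -best$value,
       # Laplace approximation to the subject's log marginal likelihood
       log_marginal = -best$value + 0.5 * k * log(2 * pi) + 0.5 * logdet)
}

#' Maximum-a-posteriori Laplace fit for one subject
#'
#' Maximizes log-likelihood plus log-prior over the transformed parameters
#' from multiple restarts, and returns the Gaussian (Laplace) approximation
#' of the subject posterior around the mode, with covariance from the
#' numerically differentiated Hessian.
#'
#' @param data One subject's trial records.
#' @param prior A [group_prior()].
#' @param model An [make_model()] specification.
#' @param n_restarts Number of random restarts drawn from the prior, in
#'   addition to a start at the prior mean.
#' @param start Optional extra starting vector (e.g. a previous MAP).
#' @param seed Integer seed for the restart draws.
#' @return A list with elements `m` (MAP, transformed scale), `cov`
#'   (Laplace covariance), `logpost` and `log_marginal`.
#' @export
subject_map <- function(data, prior, model = prior$model, n_restarts = 5,
                        start = NULL, seed = NULL) {
  validate_trials(data, single_subject = TRUE)
  if (!is.null(seed)) set.seed(seed)
  data <- dplyr::arrange(data, .data$trial_index)
  fn <- make_loglik_fn(data, model)
  k <- model$n_params
  starts <- cbind(prior$mu,
                  if (n_restarts > 0) {
                    prior$mu + sqrt(prior$var) *
                      matrix(stats::rnorm(k * n_restarts), k, n_restarts)
                  })
  if (!is.null(start)) starts <- cbind(start, starts)
  map_laplace(fn, prior, starts)
}

#' Settings for the hierarchical EM fit
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   group mean.
#' @param n_restarts Random restarts for the first E-step (subsequent
#'   E-steps warm-start at the previous subject MAPs).
#' @param var_floor Lower bound applied to the group variances.
#' @param accel Over-relaxation factor applied to the EM map's step
#'   (1 = plain EM; values up to ~1.9 speed up the slow final approach and
#'   remain stable).
#' @param verbose Print progress.
#' @return A list of settings.
#' @export
em_settings <- function(max_iter = 200, tol = 1e-4, n_restarts = 5,
                        var_floor = 1e-6, accel = 1, verbose = FALSE) {
  list(max_iter = max_iter, tol = tol, n_restarts = n_restarts,
       var_floor = var_floor, accel = accel, verbose = verbose)
}

#' Hierarchical random-effects fit by Laplace-approximate EM
#'
#' Alternates per-subject MAP/Laplace fits (E-step) with moment updates of
#' the diagonal group Gaussian (M-step):
#' \deqn{\mu \leftarrow \tfrac{1}{N}\sum_i m_i, \qquad
#'       \Sigma \leftarrow \mathrm{diag}\left(\tfrac{1}{N}\sum_i (m_i m_i^T
#'       + \Sigma_i) - \mu\mu^T\right).}
#' Iterates until the group mean stabilizes.
#'
#' @param data Trial records for two or more subjects.
#' @param model An [make_model()] specification.
#' @param settings An [em_settings()] list.
#' @param init Optional initial [group_prior()]. By default each subject is
#'   first fitted once under a broad neutral prior and the group Gaussian
#'   starts at the empirical moments of those estimates.
#' @param seed Integer seed driving the E-step restarts.
#' @return An object of class `anticipation_fit` with the final
#'   [group_prior()], per-subject Laplace posteriors, the per-iteration
#'   penalized-evidence surrogate, and convergence information.
#' @export
em_fit <- function(data, model = make_model("boosted_full"),
                   settings = em_settings(), init = NULL, seed = 1) {
  validate_trials(data)
  ids <- unique(data$subject_id)
  if (length(ids) < 2) {
    rlang::abort("hierarchical fitting needs at least 2 subjects",
                 class = "savouR_domain_error")
  }
  by_subject <- lapply(ids, function(id) {
    dplyr::arrange(data[data$subject_id == id, ], .data$trial_index)
  })
  k <- model$n_params
  n <- length(ids)
  prior <- init %||% default_prior(model)
  posteriors <- vector("list", n)
  surrogate <- numeric(0)
  converged <- FALSE
  omega <- settings$accel %||% 1

  for (it in seq_len(max(settings$max_iter, 1))) {
    posteriors <- lapply(seq_len(n), function(i) {
      subject_map(by_subject[[i]], prior, model,
                  n_restarts = if (it == 1) settings$n_restarts else 0,
                  start = if (it > 1) posteriors[[i]]$m,
                  seed = child_seed(seed, paste0("e", it, "s", i)))
    })
    m <- do.call(rbind, lapply(posteriors, `[[`, "m"))
    covdiag <- do.call(rbind, lapply(posteriors, function(p) diag(p$cov)))
    mu_new <- colMeans(m)
    var_new <- pmax(colMeans(m^2 + covdiag) - mu_new^2, settings$var_floor)
    surrogate <- c(surrogate,
                   sum(vapply(posteriors, `[[`, numeric(1), "log_marginal")))
    delta <- max(abs(mu_new - prior$mu))
    if (omega != 1 && it > 1) {
      # over-relaxed EM: lengthen the step of the EM map (stable for
      # omega < 2); variances are relaxed on the log scale
      mu_new <- prior$mu + omega * (mu_new - prior$mu)
      var_new <- pmax(exp(log(prior$var) + omega * (log(var_new) - log(prior$var))),
                      settings$var_floor)
    }
    prior <- group_prior(model, mu_new, var_new)
    if (settings$verbose) {
      message(sprintf("EM iter %d: surrogate %.3f, max|dmu| %.2e",
                      it, surrogate[it], delta))
    }
    if (delta < settings$tol) {
      converged <- TRUE
      break
    }
  }

  # likelihood-only curvature at each subject's MAP, recovered by removing
  # the prior precision from the Laplace posterior precision: this is the
  # measurement variance entering the group-mean standard error (the
  # posterior covariance itself is prior-dominated when the group variance
  # is small). Flat or negative directions are capped: the data simply do
  # not constrain that parameter at subject level.
  lik_var <- t(vapply(seq_len(n), function(i) {
    prec_post <- tryCatch(solve(posteriors[[i]]$cov),
                          error = function(e) diag(1 / prior$var, k))
    prec_lik <- diag(prec_post) - 1 / prior$var
    v <- ifelse(prec_lik > 1 / 25, 1 / prec_lik, 25)
    v[!is.finite(v)] <- 25
    v
  }, numeric(k)))

  structure(list(model = model, prior = prior,
                 subject_ids = ids, posteriors = posteriors,
                 lik_var = lik_var,
                 surrogate = surrogate,
                 n_em_iterations = length(surrogate),
                 converged = converged,
                 n_trials = nrow(data),
                 settings = settings,
                 ibic = NULL),
            class = "anticipation_fit")
}

#' @export
print.anticipation_fit <- function(x, ...) {
  cat("<anticipation_fit> model:", x$model$name,
      "|", length(x$subject_ids), "subjects |",
      x$n_em_iterations, "EM iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(tidy(x))
  invisible(x)
}

#' Equalize trial counts across delay conditions
#'
#' For each subject, randomly sub-samples (without replacement) each delay
#' condition down to that subject's minimum per-condition count, so the
#' likelihood weighs all delay conditions equally. Retained trials keep
#' their original order.
#'
#' @param data A trial table.
#' @param seed Integer seed (deterministic subsample).
#' @return The balanced trial table.
#' @examples
#' d <- simulate_subject(fitted_group_means(), builtin_design("exp1"), seed = 1)
#' table(balance_trials(d, seed = 1)$delay_s)
#' @export
balance_trials <- function(data, seed = 1) {
  validate_trials(data)
  purrr::map_dfr(unique(data$subject_id), function(id) {
    d <- data[data$subject_id == id, ]
    counts <- table(d$delay_s)
    m <- min(counts)
    set.seed(child_seed(seed, paste0("balance", id)))
    keep <- unlist(lapply(names(counts), function(dl) {
      rows <- which(d$delay_s == as.numeric(dl))
      if (length(rows) == m) rows else sort(sample(rows, m))
    }))
    d[sort(keep), ]
  })
}

#' Integrated BIC of a fitted group prior
#'
#' Approximates each subject's marginal likelihood by Monte-Carlo
#' integration over `K` draws from the group prior, and penalizes the
#' prior's fitted parameter count:
#' \deqn{\mathrm{iBIC} = -2 \sum_i \log \frac{1}{K} \sum_j p(D_i | h_j)
#'       + |M| \log |D|,}
#' with \eqn{|M|} = 2 x (free parameters) — a mean and a variance per
#' parameter — and \eqn{|D|} the total number of choices. Lower is better.
#'
#' @param data Trial records (the data actually fitted).
#' @param prior A fitted [group_prior()].
#' @param model An [make_model()] specification.
#' @param K Number of Monte-Carlo prior draws.
#' @param seed Integer seed.
#' @return A list with `ibic`, `log_marginal`, `penalty`, `n_params_prior`
#'   (|M|), `n_data` (|D|) and `K`.
#' @export
ibic <- function(data, prior, model = prior$model, K = 1e4, seed = 1) {
  validate_trials(data)
  stopifnot(K >= 1)
  set.seed(child_seed(seed, "ibic"))
  k <- model$n_params
  draws <- sweep(matrix(stats::rnorm(K * k), K, k) %*%
                   diag(sqrt(prior$var), k), 2, prior$mu, "+")
  ids <- unique(data$subject_id)
  log_marg <- vapply(ids, function(id) {
    d <- dplyr::arrange(data[data$subject_id == id, ], .data$trial_index)
    fn <- make_loglik_fn(d, model)
    ll <- vapply(seq_len(K), function(j) fn(draws[j, ]), numeric(1))
    log_mean_exp(ll)
  }, numeric(1))
  M <- 2L * k
  D <- nrow(data)
  penalty <- M * log(D)
  list(ibic = -2 * sum(log_marg) + penalty,
       log_marginal = sum(log_marg),
       penalty = penalty, n_params_prior = M, n_data = D, K = K)
}

#' Fit and compare a set of candidate models by iBIC
#'
#' Runs [em_fit()] and [ibic()] for each model and tabulates the scores,
#' lowest (best) first.
#'
#' @param data Trial records.
#' @param models A named list of [make_model()] specifications; defaults to
#'   the six-model [model_zoo()].
#' @param settings An [em_settings()] list shared across models.
#' @param K Monte-Carlo draws for [ibic()].
#' @param seed Integer seed.
#' @return A tibble of class `model_comparison` with columns `model`,
#'   `n_params`, `log_marginal`, `penalty`, `ibic`, `converged`; the
#'   underlying fits are attached as attribute `"fits"`.
#' @export
compare_models <- function(data, models = model_zoo(),
                           settings = em_settings(), K = 1e4, seed = 1) {
  validate_trials(data)
  fits <- purrr::imap(models, function(model, nm) {
    fit <- em_fit(data, model, settings = settings,
                  seed = child_seed(seed, paste0("fit", nm)))
    score <- ibic(data, fit$prior, model, K = K,
                  seed = child_seed(seed, paste0("ibic", nm)))
    fit$ibic <- score
    fit
  })
  out <- purrr::imap_dfr(fits, function(fit, nm) {
    tibble::tibble(model = nm, n_params = fit$model$n_params,
                   log_marginal = fit$ibic$log_marginal,
                   penalty = fit$ibic$penalty,
                   ibic = fit$ibic$ibic,
                   converged = fit$converged)
  })
  out <- dplyr::arrange(out, .data$ibic)
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", class(out))
  out
}

#' @export
autoplot.model_comparison <- function(object, ...) {
  d <- dplyr::mutate(object,
                     model = factor(.data$model, levels = rev(.data$model)))
  ggplot2::ggplot(d, ggplot2::aes(.data$ibic, .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "iBIC (lower is better)", y = NULL) +
    ggplot2::theme_minimal()
}

# back-transform one transformed value to the natural scale
natural_scale <- function(transform, x) {
  switch(transform, logit = stats::plogis(x), log = exp(x), x)
}

#' @export
tidy.anticipation_fit <- function(x, ...) {
  model <- x$model
  n <- length(x$subject_ids)
  # uncertainty of the recovered group mean: between-subject variance plus
  # the average likelihood-only (measurement) variance, over N
  meas <- if (is.null(x$lik_var)) {
    rowMeans(vapply(x$posteriors, function(p) diag(p$cov),
                    numeric(model$n_params)))
  } else {
    colMeans(x$lik_var)
  }
  se <- sqrt((x$prior$var + meas) / n)
  tibble::tibble(
    term = model$free,
    estimate = vapply(seq_len(model$n_params), function(j) {
      natural_scale(model$transforms[j], x$prior$mu[j])
    }, numeric(1)),
    transformed_term = model$par_names,
    transformed_mean = unname(x$prior$mu),
    transformed_sd = unname(sqrt(x$prior$var)),
    std.error = unname(se),
    conf.low = vapply(seq_len(model$n_params), function(j) {
      natural_scale(model$transforms[j], x$prior$mu[j] - 1.96 * se[j])
    }, numeric(1)),
    conf.high = vapply(seq_len(model$n_params), function(j) {
      natural_scale(model$transforms[j], x$prior$mu[j] + 1.96 * se[j])
    }, numeric(1)))
}

#' @export
glance.anticipation_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    n_subjects = length(x$subject_ids),
    n_trials = x$n_trials,
    n_params = x$model$n_params,
    em_iterations = x$n_em_iterations,
    converged = x$converged,
    log_evidence_laplace = x$surrogate[length(x$surrogate)],
    ibic = if (is.null(x$ibic)) NA_real_ else x$ibic$ibic)
}

#' @export
autoplot.anticipation_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "group-mean estimate (natural scale)", y = NULL) +
    ggplot2::theme_minimal()
}
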