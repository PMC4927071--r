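test_that("uniform prior makes posterior differences equal likelihood differences", {
  acq <- acq_small()
  irf <- irf_default()
  h <- simulate_histogram(3000, decay_model(2, background = 0.1), irf, acq,
                          seed = 1)
  m1 <- decay_model(1.8, background = 0.1)
  m2 <- decay_model(2.4, background = 0.05)
  d_post <- neg_log_posterior(h, m1, irf) - neg_log_posterior(h, m2, irf)
  d_lik <- -(log_likelihood(h, m1, irf) - log_likelihood(h, m2, irf))
  expect_equal(d_post, d_lik, tolerance = 1e-10)
})

test_that("posterior is +Inf outside the support", {
  acq <- acq_small()
  h <- simulate_histogram(1000, decay_model(2), irf_default(), acq, seed = 2)
  too_long <- decay_model(25)
  expect_equal(neg_log_posterior(h, too_long, irf_default()), Inf)
  tiny <- decay_model(0.001)
  expect_equal(neg_log_posterior(h, tiny, irf_default()), Inf)
})

test_that("posterior is stationary at the truth for noise-free data", {
  acq <- acq_small()
  irf <- irf_default()
  dec <- decay_model(2, background = 0.1)
  p <- decay_bin_probs(dec, irf, acq)$prob
  h <- expected_count_histogram(1e5 * p, acq)
  layout <- flimbayes:::fit_layout(1L, "free", 0, prior_spec())
  nlp <- flimbayes:::make_nlp(h, layout, irf, acq)
  th <- flimbayes:::model_to_theta(dec, layout)
  for (j in seq_along(th)) {
    e <- replace(numeric(length(th)), j, 1e-6)
    grad <- (nlp(th + e) - nlp(th - e)) / 2e-6
    # scale: curvature of the expected log-likelihood is ~ N
    expect_lt(abs(grad), 1e-2 * 1e5 * 1e-3)
  }
})

test_that("mono MAP recovers the lifetime to 1% at high counts", {
  acq <- acq_default()
  irf <- irf_default()
  h <- simulate_histogram(1e5, decay_model(2, background = 0.05), irf, acq,
                          seed = 41)
  fit <- fit_map(h, 1, irf)
  expect_equal(fit$model$lifetimes, 2, tolerance = 0.01)
  expect_true(fit$converged)
})

test_that("bi-exponential fits report lifetimes in canonical order", {
  acq <- acq_default()
  irf <- irf_default()
  for (s in 1:4) {
    h <- simulate_histogram(4000, bi_fret_decay(), irf, acq, seed = 60 + s)
    fit <- fit_map(h, 2, irf, background = "fixed")
    expect_true(fit$model$lifetimes[1] >= fit$model$lifetimes[2])
    expect_true(all(fit$model$weights > 0))
  }
})

test_that("grid search refined by simplex agrees with the simplex MAP", {
  acq <- acq_small()
  irf <- irf_default()
  h <- simulate_histogram(5000, decay_model(2.2, background = 0.08), irf,
                          acq, seed = 9)
  f_simplex <- fit_map(h, 1, irf)
  f_grid <- fit_map(h, 1, irf, method = "grid")
  expect_equal(f_grid$model$lifetimes, f_simplex$model$lifetimes,
               tolerance = 1e-3)
  f_sa <- fit_map(h, 1, irf, method = "anneal", seed = 4,
                  control = list(anneal_evals = 2000))
  expect_equal(f_sa$model$lifetimes, f_simplex$model$lifetimes,
               tolerance = 5e-3)
})

test_that("fit errors on empty data and warns on very sparse data", {
  acq <- acq_small()
  empty <- flim_histogram(integer(acq$n_bins), acq)
  expect_error(fit_map(empty, 1, irf_default()), "empty")
  sparse <- flim_histogram(replace(integer(acq$n_bins), 30, 3L), acq)
  expect_warning(fit_map(sparse, 1, irf_default()), "poorly constrained")
})

test_that("Laplace evidence matches 1-D quadrature within 0.1 nat", {
  acq <- acq_default()
  irf <- irf_default()
  h <- simulate_histogram(1e4, decay_model(2), irf, acq, seed = 3)
  f <- laplace_evidence(fit_map(h, 1, irf, background = "fixed"))
  pr <- prior_spec()
  ll <- Vectorize(function(tau) {
    log_likelihood(h, decay_model(tau), irf, acq)
  })
  l0 <- f$log_likelihood
  th <- f$model$lifetimes
  se <- sqrt(diag(f$covariance))[[1]]
  iv <- stats::integrate(function(tau) exp(ll(tau) - l0),
                         max(pr$tau_min, th - 12 * se),
                         min(pr$tau_max, th + 12 * se), rel.tol = 1e-10)
  lZ_quad <- log(iv$value) + l0 - log(pr$tau_max - pr$tau_min)
  expect_equal(f$log_evidence, lZ_quad, tolerance = 0.1)
})

test_that("Laplace covariance is PSD and shows Fisher scaling", {
  acq <- acq_default()
  irf <- irf_default()
  h <- simulate_histogram(1e4, decay_model(2, background = 0.1), irf, acq,
                          seed = 13)
  f1 <- laplace_evidence(fit_map(h, 1, irf))
  expect_true(all(diag(f1$covariance) >= 0))
  expect_true(all(eigen(f1$covariance, symmetric = TRUE)$values >= -1e-12))
  h2 <- flim_histogram(2L * h$count, acq)
  f2 <- laplace_evidence(fit_map(h2, 1, irf))
  i_tau <- which(names(f1$theta) == "tau1")
  ratio <- f1$covariance[i_tau, i_tau] / f2$covariance[i_tau, i_tau]
  expect_equal(ratio, 2, tolerance = 0.2 * 2)
})

test_that("FRET quantities follow the lifetime and amplitude formulas", {
  fit <- list(model = decay_from_amplitudes(c(2.0, 0.5), c(1, 1)))
  class(fit) <- "flim_fit"
  fq <- fret_quantities(fit)
  expect_equal(fq$E, 0.75)
  expect_equal(fq$F2, 0.5)
  expect_equal(fq$A1, fq$A2)
  same <- fret_quantities(decay_model(c(2, 2), weights = c(0.5, 0.5)))
  expect_equal(same$E, 0)
  uneven <- fret_quantities(decay_from_amplitudes(c(3, 1), c(1, 3)))
  expect_equal(uneven$F2, 0.75)
  expect_error(fret_quantities(decay_model(2)), "K = 2")
})

test_that("posterior surface normalises, marginalises and locates the MAP", {
  acq <- acq_small()
  irf <- irf_default()
  h <- simulate_histogram(4000, decay_model(2, background = 0.1), irf, acq,
                          seed = 19)
  grid <- list(w0 = seq(0.01, 0.4, length.out = 24),
               tau1 = seq(1.5, 2.6, length.out = 48))
  ps <- posterior_surface(h, 1, irf, grid = grid)
  expect_equal(sum(ps$surface$posterior), 1, tolerance = 1e-12)
  expect_equal(sum(ps$marginals$tau1$posterior), 1, tolerance = 1e-12)
  # marginalising the 2-D surface directly reproduces the marginal
  m_direct <- vapply(split(ps$surface$posterior, ps$surface$tau1), sum,
                     numeric(1))
  expect_equal(unname(m_direct), ps$marginals$tau1$posterior,
               tolerance = 1e-12)
  fit <- fit_map(h, 1, irf)
  cell <- grid$tau1[2] - grid$tau1[1]
  peak <- ps$surface$tau1[which.max(ps$surface$posterior)]
  expect_lt(abs(peak - fit$model$lifetimes), cell + 1e-9)
  expect_error(posterior_surface(h, 1, irf, grid = grid, max_cells = 100),
               "too large")
})
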