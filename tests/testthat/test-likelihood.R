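test_that("chi kernel differences integrate the convolution (derivative oracle)", {
  # d/dt of the antiderivative kernel must equal the decay-IRF convolution
  # density, checked against nested quadrature on a parameter grid
  grid <- expand.grid(tau = c(0.3, 2, 8), sigma = c(0.05, 0.25),
                      u = c(1.2, 2.8), delta = c(0, 1.0))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (t in c(g$u - 0.5, g$u + 0.4, g$u + 3)) {
      if (t <= g$delta) next
      h <- 1e-5
      fd <- (chi_kernel(g$tau, t + h, g$sigma, g$delta, g$u) -
               chi_kernel(g$tau, t - h, g$sigma, g$delta, g$u)) / (2 * h)
      ref <- oracle_conv_density(t, g$tau, g$sigma, g$delta, g$u)
      expect_equal(fd, ref, tolerance = 1e-6)
    }
  }
})

test_that("chi kernel validates parameters", {
  expect_error(chi_kernel(-1, 1, 0.1), "tau")
  expect_error(chi_kernel(2, 1, 0), "sigma")
})

test_that("psi matches 2-D quadrature on randomised bins", {
  set.seed(101)
  for (i in 1:10) {
    tau <- runif(1, 0.2, 8); sigma <- runif(1, 0.02, 0.4)
    u <- runif(1, 0.5, 4); delta <- runif(1, 0, u)
    tL <- runif(1, 0, 18); tH <- tL + runif(1, 0.05, 1)
    a <- psi_kernel(tau, tL, tH, sigma, delta, u)
    b <- oracle_psi(tau, tL, tH, sigma, delta, u)
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("psi respects the cutoff geometry", {
  # empty interval and bin entirely before the cutoff are exactly zero;
  # a straddling bin integrates from the cutoff only
  expect_equal(psi_kernel(2, 3, 3, 0.1, 0, 2), 0)
  expect_equal(psi_kernel(2, 0.2, 0.8, 0.1, delta = 1.0, u = 2), 0)
  straddle <- psi_kernel(2, 0.8, 1.4, 0.1, delta = 1.0, u = 1.1)
  from_cut <- psi_kernel(2, 1.0, 1.4, 0.1, delta = 1.0, u = 1.1)
  expect_equal(straddle, from_cut, tolerance = 1e-12)
  expect_gt(straddle, 0)
})

test_that("small-sigma limit reduces to a wrapped shifted exponential", {
  acq <- acq_config(ell_max = 3L)
  irf <- irf_model(1, u = 2, sigma = 1e-6, delta = 0)
  for (tau in c(0.8, 2, 12.5)) {
    p <- fluor_bin_prob(tau, c(3, 5, 0.5), c(4, 6, 1.0), irf, acq)
    ref <- vapply(list(c(3, 4), c(5, 6), c(0.5, 1.0)), function(b) {
      oracle_shifted_exp_prob(tau, b[1], b[2], 2, acq)
    }, numeric(1))
    expect_equal(p, ref, tolerance = 1e-7)
  }
})

test_that("bin probabilities are normalised over any full partition", {
  set.seed(7)
  for (i in 1:10) {
    acq <- acq_config(period = 25, window = runif(1, 10, 25),
                      n_bins = sample(c(64L, 256L, 301L), 1),
                      ell_max = sample(0:3, 1))
    irf <- irf_model(gamma = c(0.8, 0.2), u = runif(2, 0.5, 4),
                     sigma = runif(2, 0.03, 0.4), delta = c(0, runif(1, 0, 1)))
    w0 <- runif(1, 0, 0.5)
    dec <- decay_from_amplitudes(sort(runif(2, 0.1, 12), decreasing = TRUE),
                                 runif(2, 0.2, 2), background = w0)
    p <- decay_bin_probs(dec, irf, acq)$prob
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("wrap-around terms only add probability and fade for short lifetimes", {
  acq <- acq_config(ell_max = 3L)
  irf <- irf_default()
  # tau = T_m / 2: earlier excitations produce a strictly positive
  # pre-rise level in the bins before the IRF delay
  terms_slow <- fluor_bin_terms(acq$period / 2, irf, acq)
  early <- 1:12   # bins well before the 2 ns delay
  expect_true(all(colSums(terms_slow[-1, early, drop = FALSE]) > 0))
  expect_true(all(terms_slow >= -1e-15))
  # tau = T_m / 20: the l >= 2 history is negligible
  terms_fast <- fluor_bin_terms(acq$period / 20, irf, acq)
  expect_lt(sum(terms_fast[3:4, ]), 1e-6 * sum(terms_fast))
  # increasing ell_max never decreases any unnormalised bin mass
  gt <- flimbayes:::irf_gamma_tilde(irf)
  u0 <- flimbayes:::cpp_fluor_bin_probs(2, bin_edges(acq), gt, irf$u,
                                        irf$sigma, irf$delta, acq$period,
                                        acq$window, 0L, FALSE)
  u3 <- flimbayes:::cpp_fluor_bin_probs(2, bin_edges(acq), gt, irf$u,
                                        irf$sigma, irf$delta, acq$period,
                                        acq$window, 3L, FALSE)
  expect_true(all(u3 - u0 >= -1e-14))
})

test_that("photon bin probabilities are linear in the mixture", {
  acq <- acq_small()
  irf <- irf_default()
  # pure background: every equal bin carries |b|/T = 1/M
  bg <- decay_model(1, weights = 1e-15, background = 1 - 1e-15)
  p_bg <- decay_bin_probs(bg, irf, acq)$prob
  expect_equal(p_bg, rep(1 / acq$n_bins, acq$n_bins), tolerance = 1e-9)
  # K = 2 with equal photon weights is the mean of the single-tau models
  dec <- decay_model(c(2, 0.5), weights = c(0.5, 0.5))
  p <- decay_bin_probs(dec, irf, acq)$prob
  p1 <- decay_bin_probs(decay_model(2), irf, acq)$prob
  p2 <- decay_bin_probs(decay_model(0.5), irf, acq)$prob
  expect_equal(p, (p1 + p2) / 2, tolerance = 1e-12)
})

test_that("bins outside the window are rejected", {
  acq <- acq_small()
  expect_error(fluor_bin_prob(2, 19, 21, irf_default(), acq), "window")
  expect_error(photon_bin_prob(decay_model(2), -0.5, 1, irf_default(), acq),
               "window")
})

test_that("log-likelihood is linear in counts and rejects empty data", {
  acq <- acq_small()
  irf <- irf_default()
  dec <- decay_model(2, background = 0.1)
  h <- simulate_histogram(5000, dec, irf, acq, seed = 2)
  ll <- log_likelihood(h, dec, irf)
  h2 <- flim_histogram(2L * h$count, acq)
  expect_equal(log_likelihood(h2, dec, irf), 2 * ll, tolerance = 1e-12)
  empty <- flim_histogram(integer(acq$n_bins), acq)
  expect_error(log_likelihood(empty, dec, irf), "empty")
})

test_that("log-likelihood peaks at the generating lifetime on noise-free data", {
  acq <- acq_small()
  irf <- irf_default()
  dec <- decay_model(2, background = 0.05)
  p <- decay_bin_probs(dec, irf, acq)$prob
  h <- expected_count_histogram(1e4 * p, acq)
  taus <- seq(1.0, 3.5, by = 0.05)
  ll <- vapply(taus, function(tau) {
    log_likelihood(h, decay_model(tau, background = 0.05), irf, acq)
  }, numeric(1))
  expect_equal(taus[which.max(ll)], 2, tolerance = 0.051)
})

test_that("excluded edge bins renormalise the retained probabilities", {
  acq <- acq_config(n_bins = 64L, drop_first = 4L, drop_last = 4L)
  irf <- irf_default()
  dec <- decay_model(2, background = 0.1)
  h <- simulate_histogram(3000, dec, irf, acq, seed = 3)
  keep <- 5:60
  p <- decay_bin_probs(dec, irf, acq)$prob
  pk <- p[keep] / sum(p[keep])
  manual <- sum(ifelse(h$count[keep] > 0,
                       h$count[keep] * log(pk), 0))
  expect_equal(log_likelihood(h, dec, irf), manual, tolerance = 1e-12)
})
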