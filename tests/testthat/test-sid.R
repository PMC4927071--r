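test_that("SID recovers a known IRF and lifetime from high-count data", {
  acq <- acq_default()
  irf_true <- irf_model(1, u = 2.34, sigma = 0.087, delta = 0)
  dec <- decay_model(2.2, background = 0.02)
  h <- simulate_histogram(1e6, dec, irf_true, acq, seed = 9, mode = "binned")
  s <- fit_sid(h, K = 1, n_irf_components = 1, seed = 11)
  expect_equal(s$irf$u, 2.34, tolerance = 0.02 / 2.34)
  expect_lt(abs(s$irf$u - 2.34), 0.02)
  expect_lt(abs(s$irf$sigma - 0.087), 0.02)
  expect_lt(abs(s$model$lifetimes - 2.2), 0.05)
  expect_equal(sum(s$irf$gamma), 1, tolerance = 1e-12)
})

test_that("SID bias shrinks with photon count", {
  acq <- acq_default()
  irf_true <- irf_model(1, u = 2.34, sigma = 0.087, delta = 0)
  dec <- decay_model(2.2, background = 0.02)
  err <- vapply(c(1e4, 1e6), function(n) {
    h <- simulate_histogram(n, dec, irf_true, acq, seed = 9,
                            mode = "binned")
    s <- fit_sid(h, K = 1, seed = 11,
                 control = list(anneal_evals = 8000))
    abs(s$model$lifetimes - 2.2)
  }, numeric(1))
  expect_lt(err[2], 0.05)
  expect_lt(err[2], err[1] + 0.02)
})

test_that("a redundant second IRF component reduces to the single-component fit", {
  acq <- acq_default()
  irf_true <- irf_model(1, u = 2.34, sigma = 0.087, delta = 0)
  h <- simulate_histogram(1e6, decay_model(2.2, background = 0.02),
                          irf_true, acq, seed = 9, mode = "binned")
  s1 <- fit_sid(h, K = 1, n_irf_components = 1, seed = 11)
  s2 <- suppressWarnings(fit_sid(h, K = 1, n_irf_components = 2, seed = 12))
  dom <- which.max(s2$irf$gamma)
  expect_gt(s2$irf$gamma[dom], 0.9)
  expect_lt(abs(s2$irf$u[dom] - s1$irf$u), 0.02)
  expect_lt(abs(s2$irf$sigma[dom] - s1$irf$sigma), 0.02)
  expect_lt(abs(s2$model$lifetimes - s1$model$lifetimes), 0.03)
})

test_that("fixing the IRF at truth is at least as precise as joint estimation", {
  acq <- acq_default()
  irf_true <- irf_model(1, u = 2.34, sigma = 0.087, delta = 0)
  dec <- decay_model(2.2, background = 0.02)
  n_rep <- 16
  tau_sid <- tau_fix <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    h <- simulate_histogram(1500, dec, irf_true, acq, seed = 100 + i)
    tau_sid[i] <- fit_sid(h, K = 1, seed = i,
                          control = list(anneal_evals = 4000))$model$lifetimes
    tau_fix[i] <- fit_map(h, 1, irf_true, acq)$model$lifetimes
  }
  ratio <- stats::sd(tau_sid) / stats::sd(tau_fix)
  expect_gte(ratio, 0.6)   # joint estimation cannot beat the known IRF
  expect_lt(ratio, 2.0)    # but is only modestly degraded
})

test_that("SID validates inputs", {
  acq <- acq_small()
  empty <- flim_histogram(integer(acq$n_bins), acq)
  expect_error(fit_sid(empty, K = 1, seed = 1), "empty")
  h <- simulate_histogram(2000, decay_model(2), irf_default(), acq,
                          seed = 2)
  expect_warning(
    fit_sid(h, K = 1, n_irf_components = 3, seed = 3,
            control = list(anneal_evals = 500, polish_maxit = 100)),
    "over-fitting")
})
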