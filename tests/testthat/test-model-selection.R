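test_that("a single-candidate ensemble gets probability one", {
  acq <- acq_small()
  h <- simulate_histogram(2000, decay_model(2), irf_default(), acq, seed = 1)
  s <- select_model(h, candidates = 1L, irf = irf_default(),
                    background = "fixed")
  expect_equal(s$models$posterior, 1)
  expect_equal(s$selected, 1L)
})

test_that("evidence ratios are reciprocal and unity on the diagonal", {
  acq <- acq_small()
  h <- simulate_histogram(3000, bi_fret_decay(), irf_default(), acq,
                          seed = 2)
  s <- select_model(h, c(1L, 2L), irf_default(), background = "fixed")
  expect_equal(evidence_ratio(s, 1, 1), 1)
  expect_equal(evidence_ratio(s, 2, 1) * evidence_ratio(s, 1, 2), 1,
               tolerance = 1e-12)
  expect_error(evidence_ratio(s, 1, 3), "present")
})

test_that("strong bi-exponential data overwhelmingly favour K = 2", {
  acq <- acq_default()
  h <- simulate_histogram(1e4, bi_fret_decay(), irf_default(), acq,
                          seed = 3)
  s <- select_model(h, c(1L, 2L), irf_default(), background = "fixed")
  expect_equal(s$selected, 2L)
  expect_gt(evidence_ratio(s, 2, 1), 1e3)
  expect_equal(sum(s$models$posterior), 1, tolerance = 1e-12)
})

test_that("degenerate equal-lifetime data select the simpler model", {
  acq <- acq_default()
  dec <- decay_model(c(2, 2), weights = c(0.5, 0.5))
  h <- simulate_histogram(3000, dec, irf_default(), acq, seed = 4)
  s <- select_model(h, c(1L, 2L), irf_default(), background = "fixed")
  expect_equal(s$selected, 1L)
})

test_that("posterior model probability of the overfit model does not grow with N", {
  # Occam behaviour: for data truly mono-exponential, more photons should
  # not increase the support for the bi-exponential model
  acq <- acq_default()
  irf <- irf_default()
  p2 <- function(n, seed) {
    h <- simulate_histogram(n, decay_model(2), irf, acq, seed = seed)
    s <- select_model(h, c(1L, 2L), irf, background = "fixed")
    s$models$posterior[s$models$K == 2]
  }
  lo <- mean(vapply(1:6, function(i) p2(500, 100 + i), numeric(1)))
  hi <- mean(vapply(1:6, function(i) p2(8000, 200 + i), numeric(1)))
  expect_lte(hi, lo + 0.1)
})

test_that("chi-square F-test comparator selects mono for identical fits", {
  acq <- acq_default()
  irf <- irf_default()
  # data from a clean mono decay at high counts: the bi fit collapses onto
  # the mono fit and the F statistic carries no significant improvement
  h <- simulate_histogram(2e4, decay_model(2), irf, acq, seed = 5)
  sel <- chi2_model_selection(h, irf, acq)
  expect_equal(sel$selected_K, 1L)
  expect_gt(sel$p_value, 0.05)
})

test_that("chi-square F-test comparator detects strong bi data", {
  acq <- acq_default()
  irf <- irf_default()
  hits <- vapply(1:5, function(i) {
    h <- simulate_histogram(1e4, bi_fret_decay(), irf, acq, seed = 30 + i)
    chi2_model_selection(h, irf, acq)$selected_K == 2L
  }, logical(1))
  expect_true(all(hits))
})
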