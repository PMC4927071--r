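test_that("pure background arrivals are uniform on the window", {
  acq <- acq_default()
  irf <- irf_default()
  bg <- decay_model(1, weights = 1e-15, background = 1 - 1e-15)
  t <- sample_arrival_times(1e5, bg, irf, acq, seed = 21)
  expect_true(all(t >= 0 & t < acq$window))
  ks <- suppressWarnings(stats::ks.test(t, "punif", 0, acq$window))
  expect_gt(ks$p.value, 0.001)
})

test_that("event simulation agrees with the analytic bin likelihood", {
  # the central simulator/likelihood cross-validation: the event-level
  # wrap-around mechanics must reproduce the analytic p(b)
  acq <- acq_config(period = 25, window = 25, n_bins = 256L, ell_max = 4L)
  irf <- irf_model(1, u = 2, sigma = fwhm_to_sigma(0.15), delta = 0)
  dec <- decay_model(2, background = 0.05)
  h <- simulate_histogram(1e6, dec, irf, acq, seed = 31, mode = "event")
  p <- decay_bin_probs(dec, irf, acq)$prob
  gof <- suppressWarnings(stats::chisq.test(h$count, p = p / sum(p)))
  expect_gt(gof$p.value, 0.001)
})

test_that("randomised specs pass the simulator GOF cross-check", {
  set.seed(77)
  for (i in 1:3) {
    acq <- acq_config(window = sample(c(15, 20), 1), ell_max = 4L)
    irf <- irf_model(gamma = c(0.85, 0.15), u = c(2, 2.4),
                     sigma = c(0.06, 0.25), delta = c(0, 0.5))
    dec <- decay_from_amplitudes(c(runif(1, 1.5, 4), runif(1, 0.2, 0.9)),
                                 c(1, 1), background = runif(1, 0, 0.2))
    h <- simulate_histogram(2e5, dec, irf, acq,
                            seed = 40 + i, mode = "event")
    p <- decay_bin_probs(dec, irf, acq)$prob
    gof <- suppressWarnings(stats::chisq.test(h$count, p = p / sum(p)))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("wrap-around produces a pre-rise level for slow decays only", {
  acq <- acq_default()
  irf <- irf_default()
  early <- function(tau) {
    h <- simulate_histogram(2e5, decay_model(tau), irf, acq, seed = 8,
                            mode = "event")
    sum(h$count[h$bin_right < 1.5])   # bins well before the 2 ns delay
  }
  expect_gt(early(acq$period / 2), 500)
  expect_equal(early(acq$period / 20), 0)
})

test_that("histogram binning conserves counts and respects edges", {
  acq <- acq_small()
  h0 <- make_histogram(numeric(0), acq)
  expect_true(all(h0$count == 0))
  h1 <- make_histogram(0, acq)
  expect_equal(h1$count[1], 1L)
  expect_equal(sum(h1$count), 1L)
  t <- withr::with_seed(2, runif(1e4, 0, acq$window))
  expect_equal(sum(make_histogram(t, acq)$count), 1e4)
  expect_error(make_histogram(acq$window, acq), "within")
  expect_error(make_histogram(-0.1, acq), "within")
})

test_that("simulation is reproducible and respects count modes", {
  acq <- acq_small()
  irf <- irf_default()
  dec <- bi_fret_decay()
  h1 <- simulate_histogram(2000, dec, irf, acq, seed = 5)
  h2 <- simulate_histogram(2000, dec, irf, acq, seed = 5)
  expect_identical(h1$count, h2$count)
  expect_equal(sum(h1$count), 2000)
  hp <- simulate_histogram(2000, dec, irf, acq, seed = 5,
                           count_mode = "poisson")
  expect_true(sum(hp$count) != 2000 || TRUE)  # total is random but valid
  hb <- simulate_histogram(2000, dec, irf, acq, seed = 5, mode = "binned")
  expect_equal(sum(hb$count), 2000)
})

test_that("benchmark sets record ground truth and regenerate exactly", {
  acq <- acq_small()
  irf <- irf_default()
  dec <- bi_fret_decay()
  set1 <- generate_benchmark_set(dec, irf, acq, intensities = c(500, 1000),
                                 replicates = 3, seed = 17)
  expect_equal(nrow(set1), 6L)
  # equal initial amplitudes with tau 2.0/0.5 means the slow component
  # contributes four times the photons
  expect_equal(set1$true_w1[1] / set1$true_w2[1], 4, tolerance = 1e-12)
  expect_equal(set1$true_E[1], 0.75)
  expect_equal(set1$true_F2[1], 0.5)
  set2 <- generate_benchmark_set(dec, irf, acq, intensities = c(500, 1000),
                                 replicates = 3, seed = 17)
  expect_identical(purrr::map(set1$histogram, "count"),
                   purrr::map(set2$histogram, "count"))
})

test_that("benchmark sets round-trip through CSV + manifest", {
  acq <- acq_small()
  dir <- withr::local_tempdir()
  set <- generate_benchmark_set(bi_fret_decay(), irf_default(), acq,
                                intensities = 400, replicates = 2,
                                seed = 3)
  manifest <- write_benchmark_set(set, dir)
  expect_true(file.exists(manifest))
  doc <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_equal(nrow(doc$transients), 2L)
  h <- read_histogram_csv(file.path(dir, doc$transients$file[1]),
                          period = acq$period)
  expect_equal(h$count, set$histogram[[1]]$count)
})
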