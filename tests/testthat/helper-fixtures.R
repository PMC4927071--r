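# Shared fixtures and independent numeric oracles.

acq_default <- function(...) acq_config(...)
acq_small <- function(...) acq_config(n_bins = 64L, ...)

irf_default <- function() irf_gaussian(u = 2, fwhm = 0.15)

bi_fret_decay <- function(background = 0) {
  decay_from_amplitudes(c(2.0, 0.5), c(1, 1), background = background)
}

# histogram tibble with arbitrary (possibly non-integer) counts, bypassing
# the integer-count constructor — used for noise-free expected-count tests
expected_count_histogram <- function(counts, acq) {
  edges <- bin_edges(acq)
  out <- tibble::tibble(
    bin_index = seq_along(counts) - 1L,
    bin_left = edges[-length(edges)],
    bin_right = edges[-1L],
    count = counts
  )
  attr(out, "acq") <- acq
  out
}

# --- quadrature oracles (independent of the analytic kernel path) ---------

# integral over [tL, tH] of the decay-IRF convolution for one truncated
# Gaussian component (truncation-weight-normalised), by nested quadrature
oracle_psi <- function(tau, tL, tH, sigma, delta, u) {
  inner <- function(s) {
    if (s <= delta) return(0)
    f <- function(t) {
      exp(-t / tau) * sqrt(2 / pi) / sigma *
        exp(-0.5 * ((s - t - u) / sigma)^2) * ((s - t) > delta)
    }
    stats::integrate(f, 0, s - delta, rel.tol = 1e-10,
                     abs.tol = 1e-14)$value / tau
  }
  stats::integrate(Vectorize(inner), tL, tH, rel.tol = 1e-9,
                   abs.tol = 1e-14)$value
}

# derivative of the bin mass with respect to its upper edge: the
# convolution integrand at time s
oracle_conv_density <- function(s, tau, sigma, delta, u) {
  if (s <= delta) return(0)
  f <- function(t) {
    exp(-t / tau) * sqrt(2 / pi) / sigma *
      exp(-0.5 * ((s - t - u) / sigma)^2)
  }
  stats::integrate(f, 0, s - delta, rel.tol = 1e-10,
                   abs.tol = 1e-14)$value / tau
}

# wrap-around shifted-exponential bin mass in the sigma -> 0, delta = 0
# limit: closed form for a decay delayed by u on the periodic window
oracle_shifted_exp_prob <- function(tau, a, b, u, acq, ell_max = acq$ell_max) {
  mass <- function(lo, hi) {
    sum(vapply(0:ell_max, function(l) {
      exp(-max(l * acq$period + lo - u, 0) / tau) -
        exp(-max(l * acq$period + hi - u, 0) / tau)
    }, numeric(1)))
  }
  mass(a, b) / mass(0, acq$window)
}
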