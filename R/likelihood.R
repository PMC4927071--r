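#' Antiderivative kernel of the decay-IRF convolution
#'
#' Evaluates the closed-form antiderivative
#' \deqn{\chi(\tau, t, \sigma, \delta, u) = \mathrm{erf}\!\Big(\frac{t-u}{\sigma\sqrt2}\Big)
#'  + e^{-(t-u)/\tau + \sigma^2/2\tau^2}\Big[\mathrm{erf}\,q(t) - \mathrm{erf}\,q(\delta)\Big]}
#' with \eqn{q(x) = ((u-x)\tau + \sigma^2)/(\sigma\tau\sqrt2)}, whose
#' differences give the integral of an exponential decay convolved with a
#' truncated Gaussian instrument component over a time interval. Evaluation
#' is overflow-safe: the exponential prefactor is combined with the erf
#' bracket through scaled complementary error functions.
#'
#' @param tau Decay lifetime in ns (> 0).
#' @param t Evaluation times in ns (vectorised).
#' @param sigma Gaussian width in ns (> 0).
#' @param delta Lower cutoff in ns.
#' @param u Centre delay in ns.
#' @return Dimensionless kernel values, finite for all inputs.
#' @export
chi_kernel <- function(tau, t, sigma, delta = 0, u = 0) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  cpp_chi(tau, as.numeric(t), sigma, delta, u)
}

#' Interval integral of the decay-IRF convolution for one IRF component
#'
#' Integrates the (un-normalised) convolution of `exp(-t/tau)/tau` with one
#' truncated-Gaussian IRF component over the interval `[t_lower, t_upper]`,
#' implementing the three-case cutoff geometry: an interval entirely below
#' the cutoff contributes zero, one straddling the cutoff is integrated from
#' the cutoff, and one entirely above is integrated over its full width.
#'
#' @inheritParams chi_kernel
#' @param t_lower,t_upper Interval bounds in ns (vectorised,
#'   `t_lower <= t_upper`).
#' @return Non-negative kernel integrals (to be weighted by the
#'   truncation-corrected component weight).
#' @export
psi_kernel <- function(tau, t_lower, t_upper, sigma, delta = 0, u = 0) {
  if (tau <= 0 || sigma <= 0) {
    stop("`tau` and `sigma` must be positive", call. = FALSE)
  }
  if (any(t_upper < t_lower)) {
    stop("`t_lower` must not exceed `t_upper`", call. = FALSE)
  }
  cpp_psi(tau, as.numeric(t_lower), as.numeric(t_upper), sigma, delta, u)
}

#' Fluorescence bin likelihood for a mono-exponential decay
#'
#' Probability that a detected photon from a mono-exponential decay of
#' lifetime `tau`, convolved with the instrument response and wrapped around
#' the repetitive excitation (history terms `l = 0..ell_max`), arrives in
#' the bin `[bin_left, bin_right)`. Normalised so the probabilities over a
#' full partition of the measurement window sum to exactly 1.
#'
#' @param tau Lifetime in ns.
#' @param bin_left,bin_right Bin boundaries in ns, within `[0, window]`
#'   (vectorised).
#' @param irf An [irf_model()].
#' @param acq An [acq_config()].
#' @return Probabilities in `[0, 1]`.
#' @export
fluor_bin_prob <- function(tau, bin_left, bin_right, irf, acq) {
  stopifnot(inherits(irf, "irf_model"), inherits(acq, "acq_config"))
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (any(bin_left < 0) || any(bin_right > acq$window + 1e-12) ||
      any(bin_right < bin_left)) {
    stop("bins must lie within the measurement window [0, window]",
         call. = FALSE)
  }
  gt <- irf_gamma_tilde(irf)
  vapply(seq_along(bin_left), function(j) {
    cpp_fluor_bin_probs(tau, c(bin_left[j], bin_right[j]), gt, irf$u,
                        irf$sigma, irf$delta, acq$period, acq$window,
                        acq$ell_max, TRUE)
  }, numeric(1))
}

#' Excitation-history decomposition of the fluorescence bin likelihood
#'
#' Splits `F(tau, b)` into the contributions of the current (`l = 0`) and
#' earlier (`l >= 1`) excitation periods. The wrapped-around terms produce
#' the elevated "pre-rise" level seen in early bins when the lifetime is
#' not much shorter than the repetition period.
#'
#' @inheritParams fluor_bin_prob
#' @return A matrix with `ell_max + 1` rows (history index `l`) and one
#'   column per acquisition bin; column sums equal the total bin
#'   likelihoods.
#' @export
fluor_bin_terms <- function(tau, irf, acq) {
  stopifnot(inherits(irf, "irf_model"), inherits(acq, "acq_config"))
  gt <- irf_gamma_tilde(irf)
  cpp_fluor_bin_terms(tau, bin_edges(acq), gt, irf$u, irf$sigma, irf$delta,
                      acq$period, acq$window, acq$ell_max)
}

#' Photon bin probabilities for a full decay model
#'
#' Computes \eqn{p(b) = |b| w_0 / T + \sum_k w_k F(\tau_k, b)} for every bin
#' of the acquisition partition: a uniform background term plus the weighted
#' fluorescence bin likelihoods of each decay component.
#'
#' @param decay A [decay_model()].
#' @param irf An [irf_model()].
#' @param acq An [acq_config()].
#' @return A tibble with `bin_index`, `bin_left`, `bin_right` and `prob`;
#'   probabilities sum to 1 over the partition.
#' @export
decay_bin_probs <- function(decay, irf, acq) {
  stopifnot(inherits(decay, "decay_model"))
  p <- photon_bin_probs_vec(decay$lifetimes, decay$weights, decay$background,
                            irf, acq)
  edges <- bin_edges(acq)
  tibble::tibble(
    bin_index = seq_len(acq$n_bins) - 1L,
    bin_left = edges[-length(edges)],
    bin_right = edges[-1L],
    prob = p
  )
}

# bare probability vector over the acquisition partition
photon_bin_probs_vec <- function(lifetimes, weights, background, irf, acq,
                                 edges = bin_edges(acq)) {
  gt <- irf_gamma_tilde(irf)
  cpp_photon_bin_probs(lifetimes, weights, background, edges, gt, irf$u,
                       irf$sigma, irf$delta, acq$period, acq$window,
                       acq$ell_max)
}

#' Photon bin probability for arbitrary bins
#'
#' As [decay_bin_probs()] but for caller-specified bins rather than the
#' acquisition partition.
#'
#' @inheritParams decay_bin_probs
#' @param bin_left,bin_right Bin boundaries in ns within `[0, window]`.
#' @return Probabilities in `[0, 1]`.
#' @export
photon_bin_prob <- function(decay, bin_left, bin_right, irf, acq) {
  stopifnot(inherits(decay, "decay_model"))
  if (any(bin_left < 0) || any(bin_right > acq$window + 1e-12)) {
    stop("bins must lie within the measurement window", call. = FALSE)
  }
  bg <- decay$background * (bin_right - bin_left) / acq$window
  sig <- rep(0, length(bin_left))
  for (k in seq_len(decay$K)) {
    sig <- sig + decay$weights[k] *
      fluor_bin_prob(decay$lifetimes[k], bin_left, bin_right, irf, acq)
  }
  bg + sig
}

#' Log-likelihood of a histogram under a decay model
#'
#' Multinomial photon log-likelihood \eqn{\sum_j c_j \log p(b_j)} over the
#' retained bins of the acquisition. When edge bins are excluded
#' (`drop_first` / `drop_last`), probabilities are renormalised over the
#' retained bins, conditioning on detection within the analysed sub-window.
#'
#' @param data A `flim_histogram` (or tibble with `bin_left`, `bin_right`,
#'   `count`).
#' @param decay A [decay_model()].
#' @param irf An [irf_model()].
#' @param acq An [acq_config()]; defaults to the histogram's own.
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(data, decay, irf, acq = NULL) {
  acq <- resolve_acq(data, acq)
  check_histogram(data)
  stopifnot(inherits(decay, "decay_model"))
  keep <- retained_bins(acq)
  counts <- data$count[keep]
  if (sum(counts) == 0) {
    stop("empty data: all retained counts are zero", call. = FALSE)
  }
  p <- photon_bin_probs_vec(decay$lifetimes, decay$weights, decay$background,
                            irf, acq)
  pk <- p[keep]
  pk <- pk / sum(pk)
  if (any(!is.finite(pk)) || any(pk <= 0 & counts > 0)) return(-Inf)
  pos <- counts > 0  # bins with zero counts contribute 0 even when p(b) = 0
  sum(counts[pos] * log(pk[pos]))
}
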