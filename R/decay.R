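#' Multi-exponential decay model
#'
#' A decay model with `K` exponential components described by photon-fraction
#' weights `w_k` and lifetimes `tau_k`, plus a uniform background fraction
#' `w_0`. Weights are the fractions of *detected photons* contributed by each
#' component and must satisfy `sum(weights) = 1 - background` with all
#' `w_k > 0` and `tau_k > 0`. Lifetimes are stored in canonical descending
#' order (`tau_1 >= tau_2 >= ...`), which eliminates label switching in
#' bi-exponential fits.
#'
#' The continuous-decay *initial amplitude* of component `k` is related to
#' its photon fraction by `A_k` proportional to `w_k / tau_k` (a component's
#' photon yield is the integral of `A_k exp(-t/tau_k)`, i.e. `A_k tau_k`).
#' Equal initial amplitudes with lifetimes 2.0 and 0.5 ns therefore mean the
#' slow component contributes four times as many photons.
#'
#' @param lifetimes Lifetimes `tau_k` in ns, all > 0.
#' @param weights Photon-fraction weights `w_k`; defaults to equal fractions
#'   of `1 - background`.
#' @param background Uniform background photon fraction `w_0` in `[0, 1]`.
#' @return An object of class `decay_model`.
#' @examples
#' decay_model(2.0)                               # mono-exponential
#' decay_from_amplitudes(c(2.0, 0.5), c(1, 1))    # equal-amplitude FRET pair
#' @export
decay_model <- function(lifetimes, weights = NULL, background = 0) {
  K <- length(lifetimes)
  if (K < 1L) stop("need at least one decay component", call. = FALSE)
  if (any(lifetimes <= 0)) stop("lifetimes must be > 0", call. = FALSE)
  if (background < 0 || background > 1) {
    stop("`background` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep((1 - background) / K, K)
  if (length(weights) != K) {
    stop("`weights` must match `lifetimes` in length", call. = FALSE)
  }
  if (any(weights <= 0) && background < 1) {
    stop("weights must be > 0", call. = FALSE)
  }
  if (abs(sum(weights) - (1 - background)) > 1e-12) {
    stop("weights must sum to 1 - background (within 1e-12)", call. = FALSE)
  }
  ord <- order(lifetimes, decreasing = TRUE)
  structure(
    list(K = K, lifetimes = as.numeric(lifetimes[ord]),
         weights = as.numeric(weights[ord]),
         background = as.numeric(background)),
    class = "decay_model"
  )
}

#' @rdname decay_model
#' @param amplitudes Relative initial amplitudes `A_k` (any positive scale);
#'   converted to photon fractions via `w_k` proportional to
#'   `A_k * tau_k`.
#' @export
decay_from_amplitudes <- function(lifetimes, amplitudes, background = 0) {
  if (length(amplitudes) != length(lifetimes)) {
    stop("`amplitudes` must match `lifetimes` in length", call. = FALSE)
  }
  if (any(amplitudes <= 0)) stop("amplitudes must be > 0", call. = FALSE)
  w <- amplitudes * lifetimes
  w <- w / sum(w) * (1 - background)
  decay_model(lifetimes, w, background)
}

#' Normalised initial amplitudes of a decay model
#'
#' Converts photon-fraction weights back to initial amplitudes via
#' `A_k` proportional to `w_k / tau_k`, normalised so `sum(A) = 1`.
#'
#' @param decay A [decay_model()].
#' @return Numeric vector of amplitude shares.
#' @export
decay_amplitudes <- function(decay) {
  stopifnot(inherits(decay, "decay_model"))
  a <- decay$weights / decay$lifetimes
  a / sum(a)
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model> K = %d, background = %.4g\n", x$K, x$background))
  a <- decay_amplitudes(x)
  for (k in seq_len(x$K)) {
    cat(sprintf("  tau%d = %.4g ns  w%d = %.4g  (A%d share %.4g)\n",
                k, x$lifetimes[k], k, x$weights[k], k, a[k]))
  }
  invisible(x)
}
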