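#' Instrument response model: a mixture of truncated Gaussians
#'
#' The instrument response function (IRF) is the distribution of delays the
#' measurement apparatus imposes on detected photons (laser pulse width,
#' detector transit-time spread, electronics jitter). It is modelled as a
#' weighted sum of Gaussian densities, each truncated below a cutoff
#' `delta` and renormalised so component `i` carries total mass `gamma[i]`.
#'
#' @param gamma Component weights; must sum to 1.
#' @param u Component centre delays in ns (>= 0).
#' @param sigma Component widths (standard deviations) in ns (> 0).
#' @param delta Component lower cutoffs in ns (>= 0); the density is zero
#'   below the cutoff.
#' @return A tibble of class `irf_model` with one row per component, ordered
#'   by decreasing weight.
#' @examples
#' irf_model(gamma = c(0.9, 0.1), u = c(2.0, 2.4), sigma = c(0.06, 0.3))
#' irf_gaussian(u = 2, fwhm = 0.15)
#' @export
irf_model <- function(gamma, u, sigma, delta = 0) {
  n <- max(length(gamma), length(u), length(sigma), length(delta))
  gamma <- rep_len(gamma, n); u <- rep_len(u, n)
  sigma <- rep_len(sigma, n); delta <- rep_len(delta, n)
  if (any(gamma < 0 | gamma > 1)) {
    stop("IRF weights `gamma` must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(gamma) - 1) > 1e-12) {
    stop("IRF weights `gamma` must sum to 1", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("IRF widths `sigma` must be > 0", call. = FALSE)
  if (any(u < 0)) stop("IRF centres `u` must be >= 0", call. = FALSE)
  if (any(delta < 0)) stop("IRF cutoffs `delta` must be >= 0", call. = FALSE)
  ord <- order(gamma, decreasing = TRUE)
  out <- tibble::tibble(gamma = gamma[ord], u = u[ord], sigma = sigma[ord],
                        delta = delta[ord])
  class(out) <- c("irf_model", class(out))
  out
}

#' @rdname irf_model
#' @param fwhm Full width at half maximum in ns; converted to a standard
#'   deviation via `sigma = fwhm / (2 sqrt(2 log 2))`.
#' @export
irf_gaussian <- function(u = 2, fwhm = 0.15, delta = 0) {
  irf_model(gamma = 1, u = u, sigma = fwhm_to_sigma(fwhm), delta = delta)
}

#' Convert between FWHM and Gaussian standard deviation
#' @param fwhm,sigma Width in ns.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# truncation-corrected mixture weights gamma_i / (1 + erf((u_i - delta_i) /
# (sigma_i sqrt2))); the density of component i integrates to gamma_i over
# [delta_i, Inf).
irf_gamma_tilde <- function(irf) {
  irf$gamma / (1 + erf((irf$u - irf$delta) / (irf$sigma * sqrt(2))))
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' IRF probability density
#'
#' Evaluates the truncated-Gaussian-mixture density \eqn{\Gamma(u)} of an
#' [irf_model()] at delay times `u`.
#'
#' @param u Delay times in ns (any real values; the density is zero below
#'   every component's cutoff).
#' @param irf An [irf_model()].
#' @return Density values in 1/ns; non-negative, integrating to 1 over
#'   `[0, Inf)`.
#' @export
irf_density <- function(u, irf) {
  stopifnot(inherits(irf, "irf_model"))
  gt <- irf_gamma_tilde(irf)
  out <- numeric(length(u))
  for (i in seq_len(nrow(irf))) {
    dens <- sqrt(2 / pi) / irf$sigma[i] *
      exp(-0.5 * ((u - irf$u[i]) / irf$sigma[i])^2)
    out <- out + gt[i] * dens * (u > irf$delta[i])
  }
  out
}

#' Sample delays from an IRF model
#'
#' Draws instrument delays from the truncated-Gaussian mixture by inverse
#' transform sampling within each component.
#'
#' @param n Number of draws.
#' @param irf An [irf_model()].
#' @return Numeric vector of delays in ns.
#' @export
irf_sample <- function(n, irf) {
  stopifnot(inherits(irf, "irf_model"))
  comp <- sample.int(nrow(irf), n, replace = TRUE, prob = irf$gamma)
  p0 <- stats::pnorm(irf$delta, irf$u, irf$sigma)
  u01 <- stats::runif(n, p0[comp], 1)
  stats::qnorm(u01, irf$u[comp], irf$sigma[comp])
}

#' Read or write an IRF model as JSON
#'
#' The on-disk format is `{"components": [{"gamma": ..., "u": ...,
#' "sigma": ..., "delta": ...}, ...]}` with times in ns.
#'
#' @param path File path.
#' @param irf An [irf_model()].
#' @return `read_irf_json()` returns an [irf_model()]; `write_irf_json()`
#'   returns `path` invisibly.
#' @export
read_irf_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- doc$components
  if (is.null(comp)) stop("IRF JSON must contain `components`", call. = FALSE)
  delta <- if (is.null(comp$delta)) 0 else comp$delta
  irf_model(gamma = comp$gamma, u = comp$u, sigma = comp$sigma, delta = delta)
}

#' @rdname read_irf_json
#' @export
write_irf_json <- function(irf, path) {
  stopifnot(inherits(irf, "irf_model"))
  jsonlite::write_json(
    list(components = as.data.frame(irf)),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
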