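#' Laplace covariance and model evidence for a MAP fit
#'
#' Approximates the posterior around the MAP by a Gaussian: the Hessian `H`
#' of the negative log posterior `S` is computed by central finite
#' differences, the parameter covariance is `H^-1`, and the log model
#' evidence is
#' `log Z = -S(theta_hat) + (d/2) log(2 pi) - 0.5 log det H + log K!`,
#' the final term accounting for the `K!` exchange-symmetric posterior
#' modes of an unordered lifetime prior (fits report the canonical
#' descending-lifetime mode).
#'
#' The Gaussian is integrated over the *bounded* prior support rather than
#' all of parameter space: along each Hessian eigendirection the Gaussian
#' mass is truncated at the distance to the support boundary, and a flat or
#' non-positive curvature direction (a degenerate ridge, e.g. two equal
#' lifetimes, or a MAP on the boundary) is integrated as uniform over its
#' extent within the box. Without this truncation a near-flat direction
#' acquires an unbounded Gaussian volume and can spuriously inflate the
#' evidence of an over-parameterised model. Such conditions are recorded in
#' `laplace_note`.
#'
#' @param fit A `flim_fit` from [fit_map()].
#' @param rel_step Relative finite-difference step per parameter.
#' @return The fit, augmented with `covariance`, `log_evidence`, `hessian`
#'   and `laplace_note`.
#' @export
laplace_evidence <- function(fit, rel_step = 1e-4) {
  stopifnot(inherits(fit, "flim_fit"))
  nlp <- make_nlp(fit$data, fit$layout, fit$irf, fit$acq)
  H <- fd_hessian(nlp, fit$theta, rel_step)
  d <- length(fit$theta)
  eig <- eigen(H, symmetric = TRUE)
  vals <- eig$values
  notes <- character()
  # per-coordinate support box in the free-parameter layout
  pr <- fit$layout$prior
  lo <- c(rep(0, fit$layout$n_w), rep(pr$tau_min, fit$layout$K))
  hi <- c(rep(1, fit$layout$n_w), rep(pr$tau_max, fit$layout$K))
  th <- as.numeric(fit$theta)
  # distance from the MAP to the box boundary along +/- each eigendirection
  extent <- function(v) {
    step <- function(sgn) {
      tt <- Inf
      for (j in seq_len(d)) {
        vj <- sgn * v[j]
        if (abs(vj) > 1e-12) {
          tt <- min(tt, if (vj > 0) (hi[j] - th[j]) / vj else
            (lo[j] - th[j]) / vj)
        }
      }
      max(tt, 0)
    }
    c(step(1), step(-1))
  }
  log_contrib <- numeric(d)
  curv_floor <- 1e-8
  vals_floored <- vals
  for (i in seq_len(d)) {
    ext <- extent(eig$vectors[, i])
    len <- sum(ext)
    if (!is.finite(vals[i]) || vals[i] <= curv_floor) {
      # flat or negative-curvature direction: integrate uniformly over the box
      log_contrib[i] <- log(max(len, 1e-12))
      vals_floored[i] <- (2 * pi) / max(len, 1e-12)^2
      notes <- c(notes, "flat or non-positive curvature direction integrated over its prior extent")
    } else {
      sdev <- 1 / sqrt(vals[i])
      mass <- stats::pnorm(ext[1] / sdev) - stats::pnorm(-ext[2] / sdev)
      log_contrib[i] <- 0.5 * log(2 * pi / vals[i]) +
        log(max(mass, 1e-300))
      if (mass < 0.5) {
        notes <- c(notes, "substantial Gaussian mass truncated at the support boundary")
      }
    }
  }
  cov <- eig$vectors %*% ((1 / vals_floored) * t(eig$vectors))
  dimnames(cov) <- list(names(fit$theta), names(fit$theta))
  fit$hessian <- eig$vectors %*% (vals_floored * t(eig$vectors))
  fit$covariance <- (cov + t(cov)) / 2
  fit$log_evidence <- -fit$neg_log_posterior + sum(log_contrib) +
    lfactorial(fit$layout$K)
  fit$laplace_note <- if (length(notes)) paste(unique(notes),
                                               collapse = "; ") else NULL
  fit
}

# central-difference Hessian with per-parameter relative steps
fd_hessian <- function(fn, theta, rel_step = 1e-4) {
  d <- length(theta)
  h <- rel_step * pmax(abs(theta), 1e-2)
  H <- matrix(NA_real_, d, d)
  f0 <- fn(theta)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h[i]^2
    if (i < d) {
      for (j in seq.int(i + 1L, d)) {
        ej <- replace(numeric(d), j, h[j])
        H[i, j] <- H[j, i] <-
          (fn(theta + ei + ej) - fn(theta + ei - ej) -
             fn(theta - ei + ej) + fn(theta - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' FRET efficiency and interacting fraction from a bi-exponential fit
#'
#' For a two-component donor decay in a FRET experiment, the slow lifetime
#' is the non-interacting donor and the fast lifetime the FRETing donor:
#' the FRET efficiency is `E = 1 - tau2/tau1` (`tau1 > tau2`) and the
#' interacting fraction is `F2 = A2 / (A1 + A2)` where the initial
#' amplitudes are recovered from photon-fraction weights via
#' `A_k` proportional to `w_k / tau_k`.
#'
#' @param fit A `flim_fit` with `K = 2` (or a [decay_model()] with two
#'   components).
#' @return A one-row tibble with `E`, `F2`, `A1`, `A2`.
#' @export
fret_quantities <- function(fit) {
  model <- if (inherits(fit, "flim_fit")) fit$model else fit
  stopifnot(inherits(model, "decay_model"))
  if (model$K != 2) {
    stop("FRET quantities require a bi-exponential model (K = 2)",
         call. = FALSE)
  }
  a <- decay_amplitudes(model)
  tibble::tibble(
    E = 1 - model$lifetimes[2] / model$lifetimes[1],
    F2 = a[2], A1 = a[1], A2 = a[2]
  )
}

#' Gridded posterior surface and marginals
#'
#' Evaluates the normalised posterior on a user-specified grid over the
#' free parameters (for inspection of the posterior and its marginals, and
#' as a cross-check of the continuous-space search).
#'
#' @inheritParams fit_map
#' @param grid Named list of parameter value vectors; names must match the
#'   free-parameter layout (e.g. `w0`, `w1`, `tau1`, `tau2`).
#' @param max_cells Guard on the total grid size.
#' @return A list with `surface` (tibble of grid coordinates and normalised
#'   `posterior` summing to 1) and `marginals` (one tibble per parameter).
#' @export
posterior_surface <- function(data, K, irf, acq = NULL,
                              prior = prior_spec(),
                              background = c("free", "fixed"), bg_value = 0,
                              grid = NULL, max_cells = 2e5) {
  acq <- resolve_acq(data, acq)
  background <- match.arg(background)
  layout <- fit_layout(K, background, bg_value, prior)
  if (is.null(grid)) {
    grid <- stats::setNames(
      c(lapply(seq_len(layout$n_w), function(i) {
        seq(0.01, 0.99, length.out = 32)
      }),
      lapply(seq_len(K), function(i) {
        exp(seq(log(prior$tau_min), log(prior$tau_max), length.out = 64))
      })),
      layout$names)
  }
  if (!identical(sort(names(grid)), sort(layout$names))) {
    stop("grid axes must be named ", paste(layout$names, collapse = ", "),
         call. = FALSE)
  }
  grid <- grid[layout$names]
  n_cells <- prod(lengths(grid))
  if (n_cells > max_cells) {
    stop("grid too large (", n_cells, " cells > ", max_cells, ")",
         call. = FALSE)
  }
  cells <- do.call(tidyr::expand_grid, grid)
  nlp <- make_nlp(data, layout, irf, acq)
  s_vals <- vapply(seq_len(nrow(cells)), function(i) {
    nlp(as.numeric(cells[i, ]))
  }, numeric(1))
  w <- exp(-(s_vals - min(s_vals)))
  cells$posterior <- w / sum(w)
  marginals <- lapply(stats::setNames(layout$names, layout$names),
                      function(nm) {
    dplyr::summarise(dplyr::group_by(cells, .data[[nm]]),
                     posterior = sum(.data$posterior), .groups = "drop")
  })
  list(surface = cells, marginals = marginals)
}
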