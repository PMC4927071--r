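#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Bayesian decay fit
#'
#' @param x A `flim_fit` from [fit_map()].
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   and `std.error` (from the Laplace covariance when available).
#' @export
tidy.flim_fit <- function(x, ...) {
  se <- if (!is.null(x$covariance)) {
    sqrt(pmax(diag(x$covariance), 0))
  } else {
    rep(NA_real_, length(x$theta))
  }
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 std.error = unname(se))
}

#' @rdname tidy.flim_fit
#' @export
glance.flim_fit <- function(x, ...) {
  tibble::tibble(
    K = x$model$K,
    logLik = x$log_likelihood,
    neg_log_posterior = x$neg_log_posterior,
    log_evidence = if (is.null(x$log_evidence)) NA_real_ else x$log_evidence,
    method = x$method,
    n_evals = x$n_evals,
    converged = x$converged
  )
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf("<flim_fit> MAP %s-exponential fit (%s)\n",
              c("mono", "bi", "tri")[min(x$model$K, 3)], x$method))
  print(x$model)
  cat(sprintf("  neg log posterior %.4f", x$neg_log_posterior))
  if (!is.null(x$log_evidence)) {
    cat(sprintf(", log evidence %.4f", x$log_evidence))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a direct (ML/LS) fit
#'
#' @param x A `flim_direct_fit`.
#' @param ... Unused.
#' @export
tidy.flim_direct_fit <- function(x, ...) {
  L <- length(x$tau)
  tibble::tibble(
    term = c("Z", paste0("A", seq_len(L)), paste0("tau", seq_len(L))),
    estimate = c(x$Z, x$A, x$tau)
  )
}

#' @rdname tidy.flim_direct_fit
#' @export
glance.flim_direct_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    pearson_chisq = x$pearson_chisq,
    deviance = x$deviance,
    reduced_chisq = x$reduced_chisq,
    window_first = x$window[[1]],
    window_last = x$window[[2]],
    converged = x$converged
  )
}

#' Tidy a model-selection result
#'
#' @param x A `flim_model_selection`.
#' @param ... Unused.
#' @return The per-model evidence/posterior tibble.
#' @export
tidy.flim_model_selection <- function(x, ...) x$models

#' Tidy a joint IRF-and-decay fit
#'
#' @param x A `flim_sid`.
#' @param ... Unused.
#' @export
tidy.flim_sid <- function(x, ...) {
  K <- x$model$K
  irf_terms <- unlist(lapply(seq_len(nrow(x$irf)), function(i) {
    stats::setNames(
      c(x$irf$gamma[i], x$irf$u[i], x$irf$sigma[i], x$irf$delta[i]),
      paste0(c("gamma", "u", "sigma", "delta"), i))
  }))
  est <- c(stats::setNames(x$model$lifetimes, paste0("tau", seq_len(K))),
           stats::setNames(x$model$weights, paste0("w", seq_len(K))),
           w0 = x$model$background, irf_terms)
  tibble::tibble(term = names(est), estimate = unname(est))
}

# ---- plotting --------------------------------------------------------------

#' Plot a decay histogram
#'
#' @param object A `flim_histogram`.
#' @param log_counts Plot counts on a log10 axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flim_histogram <- function(object, log_counts = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_left,
                                            y = .data$count)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::labs(x = "arrival time (ns)", y = "photon counts")
  if (log_counts) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a Bayesian decay fit over its data
#'
#' Overlays the fitted expected counts (model bin probabilities scaled by
#' the retained photon total) on the measured histogram.
#'
#' @param object A `flim_fit`.
#' @param log_counts Plot counts on a log10 axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flim_fit <- function(object, log_counts = TRUE, ...) {
  data <- object$data
  acq <- object$acq
  keep <- retained_bins(acq)
  p <- photon_bin_probs_vec(object$model$lifetimes, object$model$weights,
                            object$model$background, object$irf, acq)
  expected <- p / sum(p[keep]) * sum(data$count[keep])
  df <- dplyr::mutate(data, expected = expected,
                      retained = dplyr::row_number() %in% keep)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_left)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$count), colour = "grey40") +
    ggplot2::geom_line(
      data = dplyr::filter(df, .data$retained),
      ggplot2::aes(y = .data$expected), colour = "#c0392b") +
    ggplot2::labs(x = "arrival time (ns)", y = "photon counts",
                  title = sprintf("MAP %d-exponential fit", object$model$K))
  if (log_counts) g <- g + ggplot2::scale_y_log10()
  g
}

#' Plot posterior model probabilities
#'
#' @param object A `flim_model_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flim_model_selection <- function(object, ...) {
  ggplot2::ggplot(object$models,
                  ggplot2::aes(x = factor(.data$K), y = .data$posterior)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::labs(x = "decay components K", y = "posterior probability")
}

#' Plot a precision benchmark
#'
#' Fractional precision (bias-masked) against photon count per method and
#' parameter, on log-log axes.
#'
#' @param object A `flim_benchmark`.
#' @param parameters Optional subset of parameter names to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flim_benchmark <- function(object, parameters = NULL, ...) {
  df <- object$summary
  if (!is.null(parameters)) {
    df <- dplyr::filter(df, .data$parameter %in% parameters)
  }
  df <- dplyr::filter(df, !is.na(.data$frac_precision_masked))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intensity,
                                   y = 100 * .data$frac_precision_masked,
                                   colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "photon counts", y = "fractional precision (%)",
                  colour = NULL)
}
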