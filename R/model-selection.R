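#' Bayesian decay model selection
#'
#' Selects between candidate decay model orders by Laplace-approximated
#' model evidence: each candidate `K` is fitted by [fit_map()], its evidence
#' `Z_K` approximated by [laplace_evidence()], and posterior model
#' probabilities are formed by combining the evidences with a prior over
#' the candidate set (uniform by default). The full probability
#' distribution is returned, not just the winning model.
#'
#' @inheritParams fit_map
#' @param candidates Integer vector of candidate model orders (at least 2
#'   of them, e.g. `c(1, 2)` for mono-vs-bi selection).
#' @param model_prior Prior probabilities over `candidates`; uniform by
#'   default.
#' @return An object of class `flim_model_selection`: a list with `models`
#'   (tibble of `K`, `log_evidence`, `prior`, `posterior`, diagnostics),
#'   `selected` (the maximum-posterior order), and `fits` (per-candidate
#'   `flim_fit` objects).
#' @export
select_model <- function(data, candidates = c(1L, 2L), irf, acq = NULL,
                         prior = prior_spec(),
                         background = c("free", "fixed"), bg_value = 0,
                         model_prior = NULL, seed = NULL, ...) {
  acq <- resolve_acq(data, acq)
  candidates <- as.integer(candidates)
  if (length(candidates) < 1L) stop("need at least one candidate model",
                                    call. = FALSE)
  background <- match.arg(background)
  if (is.null(model_prior)) {
    model_prior <- rep(1 / length(candidates), length(candidates))
  }
  stopifnot(length(model_prior) == length(candidates),
            abs(sum(model_prior) - 1) < 1e-8)
  # fit in ascending order so each richer model can be seeded with
  # embeddings of the simpler optimum (a nested model must never fit worse)
  ord <- order(candidates)
  fits <- vector("list", length(candidates))
  for (i in ord) {
    K <- candidates[i]
    prev <- Filter(function(f) !is.null(f) && f$model$K < K, fits)
    extra <- unlist(lapply(prev, function(f) {
      embed_starts(f$model, fit_layout(K, background, bg_value, prior))
    }), recursive = FALSE)
    f <- fit_map(data, K, irf, acq, prior = prior, background = background,
                 bg_value = bg_value, seed = seed,
                 extra_starts = extra %||% list(), ...)
    fits[[i]] <- laplace_evidence(f)
  }
  logZ <- vapply(fits, `[[`, numeric(1), "log_evidence")
  notes <- vapply(fits, function(f) {
    if (is.null(f$laplace_note)) NA_character_ else f$laplace_note
  }, character(1))
  lp <- logZ + log(model_prior)
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  models <- tibble::tibble(
    K = candidates, log_evidence = logZ, prior = model_prior,
    posterior = post, laplace_note = notes
  )
  structure(
    list(models = models,
         selected = candidates[which.max(post)],
         fits = stats::setNames(fits, paste0("K", candidates))),
    class = "flim_model_selection"
  )
}

#' @export
print.flim_model_selection <- function(x, ...) {
  cat("<flim_model_selection> selected K =", x$selected, "\n")
  print(x$models)
  invisible(x)
}

#' Bayes factor between two candidate models
#'
#' @param result A [select_model()] result.
#' @param K_a,K_b Candidate model orders present in the result.
#' @return The posterior odds `p(H_a | D) / p(H_b | D)` (equal to the Bayes
#'   factor times the prior odds).
#' @export
evidence_ratio <- function(result, K_a, K_b) {
  stopifnot(inherits(result, "flim_model_selection"))
  m <- result$models
  ia <- match(K_a, m$K); ib <- match(K_b, m$K)
  if (is.na(ia) || is.na(ib)) {
    stop("both candidates must be present in the selection result",
         call. = FALSE)
  }
  exp((m$log_evidence[ia] + log(m$prior[ia])) -
        (m$log_evidence[ib] + log(m$prior[ib])))
}

#' Chi-square (F-test) model selection on maximum-likelihood fits
#'
#' The classical direct-fitting comparator: mono- and bi-exponential
#' maximum-likelihood fits are compared by a nested-model F-test on their
#' Pearson chi-square statistics over the fit window,
#' `F = (delta chi2 / delta dof) / (chi2_2 / dof_2)`, selecting the
#' bi-exponential model when the improvement is significant at level
#' `alpha`.
#'
#' @inheritParams fit_ml
#' @param alpha Significance level of the F-test.
#' @return A one-row tibble with `selected_K`, `statistic`, `p_value`, and
#'   the per-order chi-square values.
#' @export
chi2_model_selection <- function(data, irf, acq = NULL, window = NULL,
                                 alpha = 0.05) {
  acq <- resolve_acq(data, acq)
  f1 <- fit_ml(data, L = 1, irf = irf, acq = acq, window = window)
  f2 <- fit_ml(data, L = 2, irf = irf, acq = acq, window = window)
  n_bins <- f1$window[2] - f1$window[1] + 1L
  dof1 <- n_bins - 3L   # Z, A, tau
  dof2 <- n_bins - 5L   # Z, A1, A2, tau1, tau2
  d_dof <- dof1 - dof2
  chisq1 <- f1$pearson_chisq
  chisq2 <- f2$pearson_chisq
  stat <- ((chisq1 - chisq2) / d_dof) / (chisq2 / dof2)
  p <- if (is.finite(stat) && stat > 0) {
    stats::pf(stat, d_dof, dof2, lower.tail = FALSE)
  } else {
    1
  }
  tibble::tibble(
    selected_K = if (p < alpha && chisq2 < chisq1) 2L else 1L,
    statistic = stat, p_value = p,
    chisq_mono = chisq1, chisq_bi = chisq2
  )
}
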