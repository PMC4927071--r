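#' Simultaneous instrument-response-and-decay estimation
#'
#' Jointly estimates the truncated-Gaussian-mixture IRF parameters and the
#' decay parameters from decay data alone (no separate IRF measurement):
#' simulated annealing over the joint parameter space under bounded uniform
#' priors, followed by a downhill-simplex polish. The overall time origin
#' trades off against the decay onset, so the fit is anchored by requiring
#' the dominant component's centre delay to lie in the observed rise region
#' of the transient (bins around the steepest ascent of the smoothed
#' counts) and by constraining each cutoff to `[0, u_i]`.
#'
#' @inheritParams fit_map
#' @param K Decay model order.
#' @param n_irf_components Number of Gaussian IRF components (1 or 2
#'   validated; larger values are accepted with an over-fitting warning).
#' @param sigma_max Upper bound on component widths (ns).
#' @param rise_halfwidth Half-width, in bins, of the admissible region for
#'   the dominant component's centre delay around the steepest ascent.
#' @param control List with `anneal_evals`, `cooling`, `block`,
#'   `polish_maxit`.
#' @return An object of class `flim_sid` with `irf` (the estimated
#'   [irf_model()], components ordered by weight), `model` (the estimated
#'   [decay_model()]), `neg_log_posterior` and annealing diagnostics.
#' @export
fit_sid <- function(data, K = 1L, n_irf_components = 1L, irf = NULL,
                    acq = NULL, prior = prior_spec(),
                    background = c("free", "fixed"), bg_value = 0,
                    sigma_max = 0.5, rise_halfwidth = 10L, seed = NULL,
                    control = list()) {
  acq <- resolve_acq(data, acq)
  check_histogram(data)
  background <- match.arg(background)
  I <- as.integer(n_irf_components)
  if (I < 1L) stop("need at least one IRF component", call. = FALSE)
  if (I > 2L) {
    warning("more than two IRF components risks over-fitting the IRF ",
            "approximation", call. = FALSE)
  }
  ctrl <- utils::modifyList(
    list(anneal_evals = 2e4, cooling = 0.97, block = 100L,
         polish_maxit = 2000L), control)
  keep <- retained_bins(acq)
  counts <- data$count[keep]
  if (sum(counts) == 0) {
    stop("empty data: all retained counts are zero", call. = FALSE)
  }
  layout <- fit_layout(K, background, bg_value, prior)

  # anchor: steepest ascent of the smoothed transient
  sm <- smooth_counts(data$count)
  rise_bin <- which.max(diff(sm))
  bw <- bin_width(acq)
  t_rise <- (rise_bin - 0.5) * bw
  u1_lo <- max(0, t_rise - rise_halfwidth * bw)
  u1_hi <- min(acq$window, t_rise + rise_halfwidth * bw)

  # theta = (decay block, per-component u_i, sigma_i, delta_frac_i,
  #          gamma_1..gamma_{I-1}); delta_i = delta_frac_i * u_i
  irf_names <- c(paste0("u", seq_len(I)), paste0("sigma", seq_len(I)),
                 paste0("dfrac", seq_len(I)),
                 if (I > 1) paste0("gamma", seq_len(I - 1L)))
  lower <- c(rep(0, layout$n_w), rep(prior$tau_min, K),
             u1_lo, rep(0, I - 1L), rep(1e-3, I), rep(0, I),
             rep(0, I - 1L))
  upper <- c(rep(1, layout$n_w), rep(prior$tau_max, K),
             u1_hi, rep(acq$window, I - 1L), rep(sigma_max, I), rep(1, I),
             rep(0.999, I - 1L))
  nd <- layout$d

  theta_irf <- function(theta) {
    u <- theta[nd + seq_len(I)]
    sigma <- theta[nd + I + seq_len(I)]
    dfrac <- theta[nd + 2L * I + seq_len(I)]
    gam <- if (I > 1) {
      g <- theta[nd + 3L * I + seq_len(I - 1L)]
      c(g, 1 - sum(g))
    } else 1
    list(gamma = gam, u = u, sigma = sigma, delta = dfrac * u)
  }
  edges <- bin_edges(acq)
  objective <- function(theta) {
    viol <- sum(pmax(lower - theta, 0)^2) + sum(pmax(theta - upper, 0)^2)
    if (viol > 0) return(1e12 * (1 + viol))
    dec <- theta[seq_len(nd)]
    if (!in_support(dec, layout)) {
      return(1e12 * (1 + support_violation(dec, layout)))
    }
    ir <- theta_irf(theta)
    if (any(ir$gamma < 0) || any(ir$sigma <= 0)) return(1e12)
    m <- theta_to_model(dec, layout)
    gt <- ir$gamma / (1 + erf((ir$u - ir$delta) / (ir$sigma * sqrt(2))))
    p <- cpp_photon_bin_probs(m$lifetimes, m$weights, m$background, edges,
                              gt, ir$u, ir$sigma, ir$delta, acq$period,
                              acq$window, acq$ell_max)
    pk <- p[keep]
    s <- sum(pk)
    if (!is.finite(s) || s <= 0) return(1e12)
    pos <- counts > 0
    ll <- sum(counts[pos] * log(pk[pos] / s))
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  init_decay <- start_points(data, layout, acq, 1L)[[1]]
  init <- c(init_decay,
            stats::setNames(
              c(rep(mean(c(u1_lo, u1_hi)), I),
                rep(0.1, I), rep(0.05, I), rep(0.8, max(I - 1L, 0))),
              irf_names))
  sa <- sa_minimize(objective, init, lower, upper,
                    n_eval = ctrl$anneal_evals, cooling = ctrl$cooling,
                    block = ctrl$block, seed = seed)
  polish <- stats::optim(sa$par, objective, method = "Nelder-Mead",
                         control = list(maxit = ctrl$polish_maxit,
                                        reltol = 1e-12))
  best <- if (polish$value < sa$value) polish else sa
  dec <- theta_to_model(best$par[seq_len(nd)], layout)
  ir <- theta_irf(best$par)
  irf_est <- irf_model(gamma = ir$gamma, u = ir$u,
                       sigma = pmax(ir$sigma, 1e-6), delta = ir$delta)
  model <- decay_model(
    dec$lifetimes, pmax(dec$weights, 1e-12) /
      sum(pmax(dec$weights, 1e-12)) * (1 - dec$background),
    dec$background)
  structure(
    list(irf = irf_est, model = model, neg_log_posterior = best$value,
         anneal = list(acceptance = sa$acceptance,
                       final_temp = sa$final_temp,
                       evals = ctrl$anneal_evals, seed = seed),
         rise_window = c(u1_lo, u1_hi), data = data, acq = acq),
    class = "flim_sid"
  )
}

#' @export
print.flim_sid <- function(x, ...) {
  cat("<flim_sid> joint IRF + decay estimate\n")
  cat(sprintf("  neg log posterior: %.4f\n", x$neg_log_posterior))
  print(x$model)
  cat("  IRF components:\n")
  print(as.data.frame(x$irf), row.names = FALSE)
  invisible(x)
}
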