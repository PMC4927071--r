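#' Prior specification for decay-parameter estimation
#'
#' The default prior is uniform: lifetimes uniform on `[tau_min, tau_max]`
#' (independently per component) and the weight vector uniform on its
#' simplex slice (the background fraction and photon-fraction weights,
#' subject to non-negativity and the sum constraint). A uniform prior makes
#' the maximum a posteriori estimate coincide with the maximum-likelihood
#' estimate while keeping the Laplace model evidence proper on a bounded
#' box.
#'
#' @param tau_min,tau_max Lifetime bounds in ns.
#' @param alpha Optional opaque hyperparameter vector retained for prior
#'   families that use one (the default uniform prior has none).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(tau_min = 0.01, tau_max = 20, alpha = NULL) {
  stopifnot(tau_min > 0, tau_max > tau_min)
  structure(list(tau_min = tau_min, tau_max = tau_max, alpha = alpha),
            class = "prior_spec")
}

# ---- free-parameter layout -------------------------------------------------
#
# theta = (weight block, tau_1..tau_K)
#   background free : weight block = (w0, w1, ..., w_{K-1}); w_K derived
#   background fixed: weight block = (w1, ..., w_{K-1});     w_K derived
# The uniform prior log-density over the support is constant:
#   weights: log K!  (free bg, uniform on the K-simplex in (w0, w1..wK))
#            log (K-1)! - (K-1) log(1 - bg)   (fixed bg)
#   lifetimes: -K log(tau_max - tau_min)

fit_layout <- function(K, background = c("free", "fixed"), bg_value = 0,
                       prior = prior_spec()) {
  background <- match.arg(background)
  n_w <- if (background == "free") K else K - 1L
  w_names <- if (background == "free") {
    c("w0", if (K > 1) paste0("w", seq_len(K - 1L)))
  } else if (K > 1) paste0("w", seq_len(K - 1L)) else character()
  lp_w <- if (background == "free") {
    lfactorial(K)
  } else {
    lfactorial(K - 1L) - (K - 1L) * log1p(-bg_value)
  }
  list(
    K = K, background = background, bg_value = bg_value, prior = prior,
    n_w = n_w, d = n_w + K,
    names = c(w_names, paste0("tau", seq_len(K))),
    log_prior = lp_w - K * log(prior$tau_max - prior$tau_min)
  )
}

theta_to_model <- function(theta, layout) {
  K <- layout$K
  taus <- theta[layout$n_w + seq_len(K)]
  if (layout$background == "free") {
    w0 <- theta[1]
    w_free <- if (K > 1) theta[1 + seq_len(K - 1L)] else numeric()
  } else {
    w0 <- layout$bg_value
    w_free <- if (K > 1) theta[seq_len(K - 1L)] else numeric()
  }
  w_last <- 1 - w0 - sum(w_free)
  list(weights = c(w_free, w_last), lifetimes = taus, background = w0)
}

in_support <- function(theta, layout) {
  m <- theta_to_model(theta, layout)
  pr <- layout$prior
  all(is.finite(theta)) &&
    all(m$lifetimes >= pr$tau_min) && all(m$lifetimes <= pr$tau_max) &&
    all(m$weights >= 0) && m$background >= 0 && m$background <= 1
}

# squared distance to the support box, used as a smooth exterior penalty so
# the simplex search is steered back rather than stalled on a flat plateau
support_violation <- function(theta, layout) {
  m <- theta_to_model(theta, layout)
  pr <- layout$prior
  v <- sum(pmax(pr$tau_min - m$lifetimes, 0)^2) +
    sum(pmax(m$lifetimes - pr$tau_max, 0)^2) +
    sum(pmax(-m$weights, 0)^2) +
    max(-m$background, 0)^2 + max(m$background - 1, 0)^2
  v
}

# negative log posterior as a function of theta (prior constant included)
make_nlp <- function(data, layout, irf, acq) {
  keep <- retained_bins(acq)
  counts <- data$count[keep]
  edges <- bin_edges(acq)
  gt <- irf_gamma_tilde(irf)
  function(theta) {
    if (!in_support(theta, layout)) {
      return(1e12 * (1 + support_violation(theta, layout)))
    }
    m <- theta_to_model(theta, layout)
    p <- cpp_photon_bin_probs(m$lifetimes, m$weights, m$background, edges,
                              gt, irf$u, irf$sigma, irf$delta, acq$period,
                              acq$window, acq$ell_max)
    pk <- p[keep]
    s <- sum(pk)
    if (!is.finite(s) || s <= 0) return(1e12)
    pos <- counts > 0
    ll <- sum(counts[pos] * log(pk[pos] / s))
    if (!is.finite(ll)) return(1e12)
    -(ll + layout$log_prior)
  }
}

#' Negative log posterior of a decay model
#'
#' Evaluates `-log[prior density x likelihood]` for an explicit decay model
#' (the model-evidence normalisation constant is omitted as it does not
#' depend on the parameters). Returns `Inf` outside the prior support.
#'
#' @inheritParams log_likelihood
#' @param prior A [prior_spec()].
#' @param background `"free"` if the background fraction is a free
#'   parameter of the fit this value will be compared against, `"fixed"`
#'   otherwise (affects only the constant prior density).
#' @return A single number; `Inf` outside the support.
#' @export
neg_log_posterior <- function(data, decay, irf, acq = NULL,
                              prior = prior_spec(),
                              background = c("free", "fixed")) {
  acq <- resolve_acq(data, acq)
  background <- match.arg(background)
  layout <- fit_layout(decay$K, background, decay$background, prior)
  theta <- model_to_theta(decay, layout)
  if (!in_support(theta, layout)) return(Inf)
  make_nlp(data, layout, irf, acq)(theta)
}

model_to_theta <- function(decay, layout) {
  K <- decay$K
  w_free <- if (K > 1) decay$weights[seq_len(K - 1L)] else numeric()
  w_block <- if (layout$background == "free") {
    c(decay$background, w_free)
  } else {
    w_free
  }
  stats::setNames(c(w_block, decay$lifetimes), layout$names)
}

# ---- deterministic multi-start construction --------------------------------

# moment-based initial guesses: background from the pre-rise plateau, the
# dominant lifetime from the log-linear tail slope
moment_init <- function(data, acq, prior) {
  counts <- data$count
  M <- length(counts)
  sm <- smooth_counts(counts)
  peak <- which.max(sm)
  bw <- bin_width(acq)
  pre <- if (peak > 6) stats::median(counts[seq_len(peak - 4L)]) else 0
  bg_guess <- min(0.9, max(0, pre * M / max(1, sum(counts))))
  tail_idx <- seq.int(min(peak + 3L, M - 4L), M - max(1L, acq$drop_last))
  y <- pmax(counts[tail_idx] - pre, 0.5)
  slope <- stats::coef(stats::lm(log(y) ~ tail_idx))[2]
  tau_guess <- if (is.finite(slope) && slope < 0) -bw / slope else 2
  tau_guess <- min(max(tau_guess, prior$tau_min * 2), prior$tau_max / 2)
  list(background = bg_guess, tau = tau_guess)
}

smooth_counts <- function(counts) {
  as.numeric(stats::filter(counts, rep(1 / 5, 5), sides = 2)) |>
    (\(x) ifelse(is.na(x), counts, x))()
}

start_points <- function(data, layout, acq, n_starts) {
  init <- moment_init(data, acq, layout$prior)
  K <- layout$K
  tau0 <- init$tau
  # deterministic spread: scale factors around the moment estimate
  tau_sets <- if (K == 1) {
    lapply(c(1, 0.5, 2, 0.25, 4, 0.1, 8, 1.5), function(f) tau0 * f)
  } else {
    fs <- list(c(1.2, 0.25), c(1, 0.5), c(1.5, 0.15), c(0.8, 0.3),
               c(2, 0.6), c(1.1, 0.08), c(0.6, 0.2), c(3, 1))
    lapply(fs, function(f) tau0 * f)
  }
  w_sets <- if (layout$background == "free") {
    if (K == 1) {
      list(init$background, 0.05, 0.2, 0.5)
    } else {
      b <- init$background
      list(c(b, (1 - b) * 0.8), c(b, (1 - b) * 0.5), c(0.05, 0.6),
           c(0.2, 0.4))
    }
  } else {
    if (K == 1) list(numeric()) else list(0.8, 0.5, 0.3, 0.65)
  }
  starts <- list()
  i <- 0L
  repeat {
    i <- i + 1L
    th <- c(w_sets[[((i - 1L) %% length(w_sets)) + 1L]],
            pmin(pmax(tau_sets[[((i - 1L) %% length(tau_sets)) + 1L]],
                      layout$prior$tau_min * 1.01),
                 layout$prior$tau_max * 0.99))
    starts[[i]] <- stats::setNames(th, layout$names)
    if (length(starts) >= n_starts) break
  }
  starts
}

# ---- MAP estimation --------------------------------------------------------

#' Maximum a posteriori decay-parameter estimation
#'
#' Fits a `K`-exponential decay model to a photon-count histogram by
#' minimising the negative log posterior. The default search runs the
#' downhill simplex from a deterministic set of multi-starts spread over
#' the prior box around moment-based initial guesses; `"grid"` performs an
#' exhaustive scan of a discretised parameter box refined by a simplex
#' polish, and `"anneal"` runs simulated annealing followed by a simplex
#' polish.
#'
#' @inheritParams log_likelihood
#' @param K Number of exponential components to fit.
#' @param prior A [prior_spec()].
#' @param background `"free"` to estimate the uniform background fraction,
#'   `"fixed"` to hold it at `bg_value`.
#' @param bg_value Background fraction when `background = "fixed"`.
#' @param method Optimiser: `"simplex"`, `"grid"` or `"anneal"`.
#' @param n_starts Number of deterministic simplex starts.
#' @param seed Integer seed (used by `"anneal"`).
#' @param control List of optimiser settings (`maxit`, `reltol`,
#'   `grid_nodes`, `anneal_evals`).
#' @param extra_starts Optional list of additional named start vectors in
#'   the free-parameter layout (used e.g. to seed a `K`-component fit with
#'   embeddings of a simpler model's optimum).
#' @return An object of class `flim_fit` with elements `model` (the MAP
#'   [decay_model()], lifetimes in canonical descending order),
#'   `neg_log_posterior`, `theta`, `layout`, optimiser diagnostics, and the
#'   inputs needed by [laplace_evidence()].
#' @examples
#' acq <- acq_config(n_bins = 64)
#' irf <- irf_gaussian()
#' h <- simulate_histogram(2e4, decay_model(2.2, background = 0.05),
#'                         irf, acq, seed = 1)
#' fit <- fit_map(h, K = 1, irf = irf)
#' tidy(fit)
#' @export
fit_map <- function(data, K, irf, acq = NULL, prior = prior_spec(),
                    background = c("free", "fixed"), bg_value = 0,
                    method = c("simplex", "grid", "anneal"),
                    n_starts = NULL, seed = NULL, control = list(),
                    extra_starts = list()) {
  acq <- resolve_acq(data, acq)
  check_histogram(data)
  background <- match.arg(background)
  method <- match.arg(method)
  keep <- retained_bins(acq)
  total <- sum(data$count[keep])
  if (total == 0) {
    stop("empty data: all retained counts are zero", call. = FALSE)
  }
  layout <- fit_layout(K, background, bg_value, prior)
  if (total < 5 * layout$d) {
    warning("fewer than 5 retained counts per free parameter; estimates ",
            "will be poorly constrained", call. = FALSE)
  }
  nlp <- make_nlp(data, layout, irf, acq)
  ctrl <- utils::modifyList(
    list(maxit = 1000L, reltol = 1e-10, grid_nodes = NULL,
         anneal_evals = 1e4), control)
  if (is.null(n_starts)) n_starts <- if (layout$d > 2) 8L else 4L

  evals <- 0L
  best <- NULL
  note_result <- function(par, value, conv) {
    if (is.null(best) || value < best$value) {
      best <<- list(par = par, value = value, convergence = conv)
    }
  }
  run_simplex <- function(par0) {
    if (layout$d == 1L) {
      op <- stats::optimize(function(x) nlp(x), c(prior$tau_min,
                                                  prior$tau_max),
                            tol = 1e-9)
      evals <<- evals + 50L
      note_result(stats::setNames(op$minimum, layout$names),
                  op$objective, 0L)
    } else {
      op <- stats::optim(par0, nlp, method = "Nelder-Mead",
                         control = list(maxit = ctrl$maxit,
                                        reltol = ctrl$reltol))
      evals <<- evals + op$counts[[1]]
      note_result(op$par, op$value, op$convergence)
    }
  }

  if (method == "simplex") {
    starts <- c(start_points(data, layout, acq, n_starts), extra_starts)
    for (s in starts) run_simplex(s)
  } else if (method == "grid") {
    g <- grid_nodes(layout, ctrl$grid_nodes)
    vals <- apply(g, 1L, nlp)
    evals <- evals + nrow(g)
    note_result(stats::setNames(g[which.min(vals), ], layout$names),
                min(vals), 0L)
    run_simplex(best$par)
  } else {
    lower <- c(rep(0, layout$n_w), rep(prior$tau_min, K))
    upper <- c(rep(1, layout$n_w), rep(prior$tau_max, K))
    st <- start_points(data, layout, acq, 1L)[[1]]
    sa <- sa_minimize(nlp, st, lower, upper, n_eval = ctrl$anneal_evals,
                      seed = seed)
    evals <- evals + ctrl$anneal_evals
    note_result(sa$par, sa$value, 0L)
    run_simplex(best$par)
  }

  m <- theta_to_model(best$par, layout)
  ord <- order(m$lifetimes, decreasing = TRUE)
  model <- decay_model(
    lifetimes = m$lifetimes[ord],
    weights = pmax(m$weights[ord], 1e-12) /
      sum(pmax(m$weights[ord], 1e-12)) * (1 - m$background),
    background = min(max(m$background, 0), 1)
  )
  theta_hat <- model_to_theta(model, layout)
  structure(
    list(model = model, theta = theta_hat, layout = layout,
         neg_log_posterior = best$value,
         log_likelihood = -(best$value) - layout$log_prior,
         method = method, n_evals = evals,
         converged = identical(best$convergence, 0L),
         covariance = NULL, log_evidence = NULL, laplace_note = NULL,
         data = data, irf = irf, acq = acq, prior = prior, seed = seed),
    class = "flim_fit"
  )
}

grid_nodes <- function(layout, nodes = NULL, max_total = 2e5) {
  if (is.null(nodes)) nodes <- c(w = 16L, tau = 32L)
  repeat {
    per_axis <- c(rep(nodes[["w"]], layout$n_w), rep(nodes[["tau"]],
                                                     layout$K))
    if (prod(per_axis) <= max_total) break
    nodes <- pmax(c(w = nodes[["w"]] %/% 2L, tau = nodes[["tau"]] %/% 2L),
                  4L)
    if (all(nodes == 4L)) break
  }
  pr <- layout$prior
  axes <- c(
    lapply(seq_len(layout$n_w), function(i) {
      seq(0.001, 0.999, length.out = nodes[["w"]])
    }),
    lapply(seq_len(layout$K), function(i) {
      exp(seq(log(pr$tau_min), log(pr$tau_max),
              length.out = nodes[["tau"]]))
    })
  )
  as.matrix(do.call(expand.grid, axes))
}

# Start vectors for a K'-component layout built by embedding a fitted
# simpler model: append extra components at fractions of the fastest fitted
# lifetime with a small weight share, and a "split" variant that divides the
# dominant component in two. Guarantees the richer model starts at least as
# good as the nested optimum.
embed_starts <- function(model, layout) {
  K_new <- layout$K
  K_old <- model$K
  if (K_new <= K_old) return(list())
  m <- K_new - K_old
  pr <- layout$prior
  mk_theta <- function(taus, weights, bg) {
    dm <- decay_model(pmin(pmax(taus, pr$tau_min * 1.001),
                           pr$tau_max * 0.999),
                      weights / sum(weights) * (1 - bg), bg)
    model_to_theta(dm, layout)
  }
  bg <- if (layout$background == "free") model$background else
    layout$bg_value
  out <- list()
  for (f in c(0.5, 0.2)) {
    taus <- c(model$lifetimes, min(model$lifetimes) * f * seq_len(m))
    w <- c(model$weights * 0.9, rep(0.1 * sum(model$weights) / m, m))
    out[[length(out) + 1L]] <- mk_theta(taus, w, bg)
  }
  i_dom <- which.max(model$weights)
  taus <- c(model$lifetimes, model$lifetimes[i_dom] * 0.7 * seq_len(m))
  w <- model$weights
  w_new <- rep(w[i_dom] / (m + 1), m)
  w[i_dom] <- w[i_dom] / (m + 1)
  out[[length(out) + 1L]] <- mk_theta(taus, c(w, w_new), bg)
  out
}

# bounded simulated annealing with geometric cooling; the initial
# temperature is set from the spread of random probe evaluations
sa_minimize <- function(fn, par0, lower, upper, n_eval = 1e4,
                        cooling = 0.97, block = 100L, seed = NULL,
                        scale = NULL) {
  run <- function() {
    d <- length(par0)
    if (is.null(scale)) scale <- 0.05 * (upper - lower)
    probes <- vapply(seq_len(100L), function(i) {
      fn(stats::runif(d, lower, upper))
    }, numeric(1))
    probes <- probes[is.finite(probes) & probes < 1e11]
    temp <- if (length(probes) > 1) max(stats::sd(probes), 1) else 1
    cur <- pmin(pmax(par0, lower), upper)
    f_cur <- fn(cur)
    best <- cur; f_best <- f_cur
    accept <- 0L
    for (i in seq_len(n_eval)) {
      prop <- cur + stats::rnorm(d, 0, scale)
      # reflect proposals back into the box
      prop <- ifelse(prop < lower, 2 * lower - prop, prop)
      prop <- ifelse(prop > upper, 2 * upper - prop, prop)
      prop <- pmin(pmax(prop, lower), upper)
      f_prop <- fn(prop)
      if (is.finite(f_prop) &&
          (f_prop < f_cur ||
           stats::runif(1) < exp((f_cur - f_prop) / temp))) {
        cur <- prop; f_cur <- f_prop; accept <- accept + 1L
        if (f_cur < f_best) { best <- cur; f_best <- f_cur }
      }
      if (i %% block == 0L) temp <- temp * cooling
    }
    list(par = stats::setNames(best, names(par0)), value = f_best,
         acceptance = accept / n_eval, final_temp = temp)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
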