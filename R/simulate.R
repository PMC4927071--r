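#' Sample TCSPC photon arrival times
#'
#' Forward event-level simulator: each detected photon is attributed to the
#' uniform background with probability `w_0` (arrival uniform on the
#' measurement window) or to decay component `k` with probability `w_k`, in
#' which case an emission time `t ~ Exp(tau_k)` and an instrument delay
#' `u ~ Gamma(u)` are drawn and the recorded arrival time is the wrap-around
#' `(t + u) mod period`. Events falling outside the measurement window are
#' rejected and redrawn, so the returned times reproduce the within-window
#' conditioning of the analytic bin likelihood.
#'
#' @param n Number of accepted arrival times to return.
#' @param decay A [decay_model()].
#' @param irf An [irf_model()].
#' @param acq An [acq_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` arrival times in `[0, window)`.
#' @export
sample_arrival_times <- function(n, decay, irf, acq, seed = NULL) {
  stopifnot(inherits(decay, "decay_model"), inherits(irf, "irf_model"),
            inherits(acq, "acq_config"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  run <- function() {
    out <- numeric(0)
    proposed <- 0
    probs <- c(decay$background, decay$weights)
    while (length(out) < n) {
      m <- max(1000L, as.integer(ceiling((n - length(out)) * 1.4)))
      comp <- sample.int(decay$K + 1L, m, replace = TRUE, prob = probs) - 1L
      dt <- numeric(m)
      is_bg <- comp == 0L
      dt[is_bg] <- stats::runif(sum(is_bg), 0, acq$window)
      if (any(!is_bg)) {
        ns <- sum(!is_bg)
        t_em <- stats::rexp(ns, rate = 1 / decay$lifetimes[comp[!is_bg]])
        u <- irf_sample(ns, irf)
        dt[!is_bg] <- (t_em + u) %% acq$period
      }
      keep <- dt < acq$window
      out <- c(out, dt[keep])
      proposed <- proposed + m
      if (proposed >= 1e6 && length(out) / proposed < 1e-6) {
        stop("arrival-time acceptance rate below 1e-6; check the window ",
             "and decay parameters", call. = FALSE)
      }
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Bin arrival times into a histogram
#'
#' @param times Arrival times in ns, all within `[0, window)`.
#' @param acq An [acq_config()].
#' @return A [flim_histogram()] whose counts sum to `length(times)`.
#' @export
make_histogram <- function(times, acq) {
  stopifnot(inherits(acq, "acq_config"))
  if (length(times) > 0 && (any(times < 0) || any(times >= acq$window))) {
    stop("arrival times must lie within [0, window)", call. = FALSE)
  }
  edges <- bin_edges(acq)
  idx <- findInterval(times, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = acq$n_bins)
  flim_histogram(counts, acq)
}

#' Simulate a TCSPC histogram
#'
#' Generates a photon-count histogram either by event-level simulation
#' (sampling every photon arrival; exercises the wrap-around mechanics
#' independently of the analytic likelihood) or by per-bin Poisson draws
#' around the analytic expected counts (`mode = "binned"`, faster and
#' matching Poisson-noise-per-bin synthetic data generation).
#'
#' @param n Target photon count (expected count under
#'   `count_mode = "poisson"`).
#' @param decay A [decay_model()].
#' @param irf An [irf_model()].
#' @param acq An [acq_config()].
#' @param seed Optional integer seed.
#' @param mode `"event"` for photon-level simulation, `"binned"` for
#'   per-bin noise around analytic expectations.
#' @param count_mode `"fixed"` for exactly `n` photons, `"poisson"` for a
#'   Poisson-distributed total with mean `n`.
#' @return A [flim_histogram()].
#' @export
simulate_histogram <- function(n, decay, irf, acq, seed = NULL,
                               mode = c("event", "binned"),
                               count_mode = c("fixed", "poisson")) {
  mode <- match.arg(mode)
  count_mode <- match.arg(count_mode)
  run <- function() {
    if (mode == "event") {
      n_eff <- if (count_mode == "poisson") stats::rpois(1, n) else n
      if (n_eff == 0) return(flim_histogram(integer(acq$n_bins), acq))
      make_histogram(sample_arrival_times(n_eff, decay, irf, acq), acq)
    } else {
      p <- photon_bin_probs_vec(decay$lifetimes, decay$weights,
                                decay$background, irf, acq)
      counts <- if (count_mode == "poisson") {
        stats::rpois(acq$n_bins, n * p)
      } else {
        as.integer(stats::rmultinom(1, n, p))
      }
      flim_histogram(counts, acq)
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a replicated synthetic benchmark set
#'
#' Simulates `replicates` transients at each requested intensity from a
#' known ground-truth decay model, recording the truth alongside each
#' histogram. Per-transient seeds are derived deterministically from the
#' root seed, so a fixed seed regenerates the set exactly.
#'
#' @param decay Ground-truth [decay_model()].
#' @param irf Generating [irf_model()].
#' @param acq An [acq_config()].
#' @param intensities Vector of total photon counts N.
#' @param replicates Number of transients per intensity.
#' @param seed Root integer seed.
#' @inheritParams simulate_histogram
#' @return A tibble with one row per transient: `intensity`, `replicate`,
#'   `seed`, list-column `histogram`, and ground-truth columns (lifetimes,
#'   photon-fraction weights, amplitude shares, background).
#' @export
generate_benchmark_set <- function(decay, irf, acq, intensities,
                                   replicates, seed = 1L,
                                   mode = c("event", "binned"),
                                   count_mode = c("fixed", "poisson")) {
  stopifnot(replicates >= 1)
  mode <- match.arg(mode)
  count_mode <- match.arg(count_mode)
  grid <- tidyr::expand_grid(intensity = intensities,
                             replicate = seq_len(replicates))
  grid$seed <- derive_seeds(seed, nrow(grid))
  grid$histogram <- purrr::map2(grid$intensity, grid$seed, function(n, s) {
    simulate_histogram(n, decay, irf, acq, seed = s, mode = mode,
                       count_mode = count_mode)
  })
  truth <- decay_truth_row(decay)
  out <- dplyr::bind_cols(grid, truth[rep(1, nrow(grid)), ])
  attr(out, "decay") <- decay
  attr(out, "irf") <- irf
  attr(out, "acq") <- acq
  out
}

# deterministic per-replicate seed stream (kept below .Machine$integer.max)
derive_seeds <- function(root, n) {
  as.integer((as.numeric(root) + 99991 * seq_len(n)) %% 2147483629)
}

decay_truth_row <- function(decay) {
  a <- decay_amplitudes(decay)
  row <- c(
    stats::setNames(decay$lifetimes, paste0("true_tau", seq_len(decay$K))),
    stats::setNames(decay$weights, paste0("true_w", seq_len(decay$K))),
    stats::setNames(a, paste0("true_A", seq_len(decay$K))),
    true_background = decay$background
  )
  if (decay$K == 2) {
    row <- c(row,
             true_E = unname(1 - decay$lifetimes[2] / decay$lifetimes[1]),
             true_F2 = unname(a[2]))
  }
  tibble::as_tibble(as.list(row))
}

#' Write a benchmark set to disk
#'
#' Emits one histogram CSV per transient (columns `bin_index`,
#' `bin_left_ns`, `bin_right_ns`, `count`) plus a `manifest.json` recording
#' per-transient ground truth, seeds and acquisition metadata.
#'
#' @param set A tibble from [generate_benchmark_set()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_benchmark_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acq <- attr(set, "acq")
  files <- character(nrow(set))
  for (i in seq_len(nrow(set))) {
    files[i] <- sprintf("transient_%04d.csv", i)
    write_histogram_csv(set$histogram[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    acquisition = unclass(acq),
    transients = dplyr::mutate(
      dplyr::select(set, -dplyr::any_of("histogram")), file = files)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
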