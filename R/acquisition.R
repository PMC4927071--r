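#' Acquisition configuration for a TCSPC measurement
#'
#' Describes the timing geometry of a time-correlated single photon counting
#' (TCSPC) acquisition: the excitation repetition period, the measurement
#' window over which arrival times are recorded, the number of equal-width
#' histogram bins, how many terms of the excitation history to include in
#' likelihood sums, and any bins excluded from likelihood evaluation at the
#' start and end of the transient (regions often corrupted by
#' time-to-amplitude converter dithering).
#'
#' @param period Excitation repetition period \eqn{T_m} in ns (40 MHz
#'   repetition corresponds to 25 ns).
#' @param window Measurement window duration \eqn{T} in ns; must satisfy
#'   `0 < window <= period`.
#' @param n_bins Number of equal-width bins subdividing the window.
#' @param ell_max Highest excitation-history index included when summing
#'   wrapped-around contributions; `1` (the current and the immediately
#'   preceding excitation period) suffices when lifetimes are much shorter
#'   than `period`.
#' @param drop_first,drop_last Number of bins excluded from likelihood
#'   evaluation at the start/end of the transient.
#' @return An object of class `acq_config`.
#' @examples
#' acq_config()                      # the 40 MHz / 20 ns / 256 bin system
#' acq_config(period = 25, window = 25, n_bins = 64)
#' @export
acq_config <- function(period = 25, window = 20, n_bins = 256L, ell_max = 1L,
                       drop_first = 0L, drop_last = 0L) {
  stopifnot(is.numeric(period), length(period) == 1L, is.finite(period),
            is.numeric(window), length(window) == 1L, is.finite(window))
  if (!(window > 0 && window <= period)) {
    stop("`window` must satisfy 0 < window <= period", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  ell_max <- as.integer(ell_max)
  drop_first <- as.integer(drop_first)
  drop_last <- as.integer(drop_last)
  if (n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
  if (ell_max < 0L) stop("`ell_max` must be >= 0", call. = FALSE)
  if (drop_first < 0L || drop_last < 0L) {
    stop("excluded bin counts must be non-negative", call. = FALSE)
  }
  if (drop_first + drop_last >= n_bins) {
    stop("excluded bins must number strictly fewer than `n_bins`",
         call. = FALSE)
  }
  structure(
    list(period = period, window = window, n_bins = n_bins,
         ell_max = ell_max, drop_first = drop_first, drop_last = drop_last),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf(
    "<acq_config> period %.4g ns, window %.4g ns, %d bins, ell_max %d",
    x$period, x$window, x$n_bins, x$ell_max))
  if (x$drop_first > 0 || x$drop_last > 0) {
    cat(sprintf(", dropping %d+%d edge bins", x$drop_first, x$drop_last))
  }
  cat("\n")
  invisible(x)
}

#' Bin edges of an acquisition configuration
#'
#' @param acq An [acq_config()].
#' @return Numeric vector of `n_bins + 1` strictly increasing edges spanning
#'   `[0, window]`; bins follow the half-open convention `[left, right)`.
#' @export
bin_edges <- function(acq) {
  stopifnot(inherits(acq, "acq_config"))
  seq(0, acq$window, length.out = acq$n_bins + 1L)
}

bin_width <- function(acq) acq$window / acq$n_bins

# indices (1-based) of bins retained for likelihood evaluation
retained_bins <- function(acq) {
  seq.int(acq$drop_first + 1L, acq$n_bins - acq$drop_last)
}

#' Construct a decay histogram
#'
#' Builds the tabular histogram representation used throughout the package:
#' a tibble with 0-based `bin_index`, bin boundaries in ns (half-open
#' `[bin_left, bin_right)`), and non-negative integer photon counts, carrying
#' the acquisition configuration as an attribute.
#'
#' @param counts Integer vector of per-bin photon counts, length
#'   `acq$n_bins`.
#' @param acq An [acq_config()].
#' @return A tibble of class `flim_histogram`.
#' @export
flim_histogram <- function(counts, acq) {
  stopifnot(inherits(acq, "acq_config"))
  if (length(counts) != acq$n_bins) {
    stop("`counts` must have one entry per bin", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("counts must be integral", call. = FALSE)
  }
  edges <- bin_edges(acq)
  out <- tibble::tibble(
    bin_index = seq_len(acq$n_bins) - 1L,
    bin_left = edges[-length(edges)],
    bin_right = edges[-1L],
    count = as.integer(round(counts))
  )
  attr(out, "acq") <- acq
  class(out) <- c("flim_histogram", class(out))
  out
}

# Resolve the acquisition config for a histogram-accepting function.
resolve_acq <- function(data, acq = NULL) {
  if (is.null(acq)) acq <- attr(data, "acq")
  if (is.null(acq)) {
    stop("no acquisition configuration: supply `acq` or use a histogram ",
         "created by this package", call. = FALSE)
  }
  stopifnot(inherits(acq, "acq_config"))
  acq
}

check_histogram <- function(data) {
  need <- c("bin_left", "bin_right", "count")
  if (!all(need %in% names(data))) {
    stop("histogram must have columns bin_left, bin_right, count",
         call. = FALSE)
  }
  invisible(data)
}
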