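#' Read a decay histogram from CSV
#'
#' Reads the package interchange format: a CSV with header columns
#' `bin_index`, `bin_left_ns`, `bin_right_ns`, `count` describing
#' contiguous equal-width bins over the measurement window. Vendor TCSPC
#' formats are out of scope; export to this schema upstream, or extend this
#' reader as the adapter point.
#'
#' @param path CSV file path.
#' @param period Excitation repetition period in ns (not stored in the
#'   CSV; 25 ns corresponds to the common 40 MHz repetition rate).
#' @param ell_max,drop_first,drop_last Passed to [acq_config()].
#' @return A [flim_histogram()] carrying the reconstructed [acq_config()]
#'   as an attribute.
#' @export
read_histogram_csv <- function(path, period = 25, ell_max = 1L,
                               drop_first = 0L, drop_last = 0L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("bin_index", "bin_left_ns", "bin_right_ns", "count")
  if (nrow(df) == 0 || !all(need %in% names(df))) {
    stop("histogram CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$bin_index), ]
  bad <- which(!is.finite(df$count) | df$count < 0 |
                 abs(df$count - round(df$count)) > 1e-9)
  if (length(bad) > 0) {
    stop("invalid counts at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  gaps <- which(abs(df$bin_left_ns[-1L] -
                      df$bin_right_ns[-nrow(df)]) > 1e-9)
  if (length(gaps) > 0) {
    stop("non-contiguous bins at line(s) ",
         paste(gaps + 2L, collapse = ", "), " of ", path, call. = FALSE)
  }
  window <- max(df$bin_right_ns)
  acq <- acq_config(period = period, window = window, n_bins = nrow(df),
                    ell_max = ell_max, drop_first = drop_first,
                    drop_last = drop_last)
  flim_histogram(df$count, acq)
}

#' Write a decay histogram to CSV
#'
#' @param data A histogram tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(data, path) {
  check_histogram(data)
  out <- tibble::tibble(
    bin_index = if ("bin_index" %in% names(data)) data$bin_index else
      seq_len(nrow(data)) - 1L,
    bin_left_ns = data$bin_left,
    bin_right_ns = data$bin_right,
    count = data$count
  )
  readr::write_csv(out, path)
  invisible(path)
}
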