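#' Global synchrony between two daily series
#'
#' Pearson correlation over the full overlap of two aligned daily series —
#' used to validate a mobility proxy (e.g. aggregated roaming counts)
#' against an independent reference (e.g. air-passenger arrivals).
#'
#' @param x,y numeric vectors, or data frames with `date` plus one value
#'   column, in which case dates must match exactly after sorting.
#' @return Pearson correlation in \[-1, 1\]; `NA_real_` when either series
#'   is constant (zero variance).
#' @export
global_synchrony <- function(x, y) {
  al <- align_series(x, y)
  if (length(al$x) < 2) {
    mf_abort("mobiflux_alignment_error",
             "synchrony needs at least 2 aligned observations")
  }
  if (sd(al$x) == 0 || sd(al$y) == 0) return(NA_real_)
  cor(al$x, al$y)
}

align_series <- function(x, y) {
  take <- function(s) {
    if (is.data.frame(s)) {
      val_col <- setdiff(names(s), "date")[1]
      s <- s[order(s$date), ]
      list(date = s$date, value = as.numeric(s[[val_col]]))
    } else {
      list(date = NULL, value = as.numeric(s))
    }
  }
  a <- take(x); b <- take(y)
  if (!is.null(a$date) && !is.null(b$date)) {
    if (length(a$date) != length(b$date) || any(a$date != b$date)) {
      mf_abort("mobiflux_alignment_error",
               "series must be aligned on identical date sets")
    }
  } else if (length(a$value) != length(b$value)) {
    mf_abort("mobiflux_alignment_error", "series must have equal length")
  }
  list(x = a$value, y = b$value)
}

#' Sliding-window (local) synchrony between two daily series
#'
#' For each window size `W`, slides a window of `W` consecutive days in
#' steps of 1 day and computes the Pearson correlation inside each window.
#' Windows where either sub-series is constant are undefined (`NA`) and are
#' excluded from the mean and median; the exclusion count is reported.
#' `W` equal to the series length reduces exactly to [global_synchrony()].
#'
#' @inheritParams global_synchrony
#' @param window_sizes integer vector of window lengths in days
#'   (default `c(5, 10, 15, 20, 25)`).
#' @return list with `rho_g` and `windows`, a data frame with one row per
#'   window size: `W`, `mu` (mean rho), `median` (median rho), `n_windows`,
#'   `n_undefined`; plus `values`, a list of the per-window correlation
#'   vectors keyed by window size.
#' @export
local_synchrony <- function(x, y, window_sizes = c(5, 10, 15, 20, 25)) {
  al <- align_series(x, y)
  n <- length(al$x)
  if (any(window_sizes < 3)) {
    mf_abort("mobiflux_config_error",
             "window sizes below 3 days give unstable correlations")
  }
  if (any(window_sizes > n)) {
    mf_abort("mobiflux_config_error",
             "window size exceeds series length")
  }
  values <- lapply(window_sizes, function(w) {
    starts <- seq_len(n - w + 1)
    vapply(starts, function(t) {
      xs <- al$x[t:(t + w - 1)]
      ys <- al$y[t:(t + w - 1)]
      if (sd(xs) == 0 || sd(ys) == 0) NA_real_ else cor(xs, ys)
    }, numeric(1))
  })
  names(values) <- as.character(window_sizes)
  windows <- data.frame(
    W = window_sizes,
    mu = vapply(values, function(v) mean(v, na.rm = TRUE), numeric(1)),
    median = vapply(values, function(v) median(v, na.rm = TRUE), numeric(1)),
    n_windows = vapply(values, length, integer(1)),
    n_undefined = vapply(values, function(v) sum(is.na(v)), integer(1)),
    row.names = NULL)
  list(rho_g = global_synchrony(al$x, al$y), windows = windows,
       values = values)
}
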