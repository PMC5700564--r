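# Temporal autocorrelation of the movement index, lag-based window choice,
# and the centered moving average that turns the index into the PII.

#' Autocorrelation of a movement-index series
#'
#' Mean-removed sample autocorrelation (standard biased estimator) of a
#' regularly gridded series. Undefined entries (gaps, endpoints) are
#' mean-imputed for estimation only; the imputed count is disclosed in the
#' result and the 5% significance band uses the number of *defined* values.
#'
#' @param series numeric vector on the regular fix grid; `NA` = undefined.
#' @param max_lag largest lag to compute; must be below half the series
#'   length. Default `min(40, floor(n/2) - 1)`.
#' @return list of class `pii_acf` with `lags` (0..max_lag), `values`,
#'   `sig_limit` (`1.96 / sqrt(n_effective)`), `n_effective`, `n_imputed`.
#' @export
index_acf <- function(series, max_lag = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  ndef <- sum(!is.na(x))
  if (ndef < 30) stop("need at least 30 defined values for the ACF")
  if (is.null(max_lag)) max_lag <- min(40L, n %/% 2L - 1L)
  if (max_lag >= n / 2) stop("max_lag must be below half the series length")
  mu <- mean(x, na.rm = TRUE)
  if (stats::var(x, na.rm = TRUE) == 0)
    stop("constant series has zero variance; ACF undefined")
  xi <- x
  xi[is.na(xi)] <- mu
  a <- stats::acf(xi, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(list(lags = 0:max_lag,
                 values = as.numeric(a$acf),
                 sig_limit = 1.96 / sqrt(ndef),
                 n_effective = ndef,
                 n_imputed = n - ndef),
            class = "pii_acf")
}

#' @export
print.pii_acf <- function(x, ...) {
  cat(sprintf("Movement-index ACF: %d lags, n_effective %d (%d gap values mean-imputed), 5%% limits +/- %.4f\n",
              length(x$lags) - 1L, x$n_effective, x$n_imputed, x$sig_limit))
  fz <- which(x$values <= 0 & x$lags > 0)
  if (length(fz)) cat(sprintf("first non-positive lag: %d\n", x$lags[min(fz)]))
  invisible(x)
}

#' @export
as.data.frame.pii_acf <- function(x, ...) {
  data.frame(lag = x$lags, value = x$values, sig_limit = x$sig_limit)
}

#' Choose the moving-average window from the lag structure
#'
#' The window is the first lag at which the index autocorrelation reaches
#' zero (first non-positive value), rounded up to odd so the centered window
#' has a middle fix, with a minimum of 3. An `override` (e.g. the 15-fix
#' window corresponding to the 2.5-day mean lag across study animals)
#' bypasses selection entirely.
#'
#' @param acf_res a [index_acf()] result.
#' @param override odd window to use instead of the selected one.
#' @param min_window smallest admissible window (default 3).
#' @return odd integer window length (number of fixes).
#' @export
select_window <- function(acf_res, override = NULL, min_window = 3L) {
  if (!is.null(override)) {
    override <- as.integer(override)
    if (override %% 2L == 0L || override < min_window)
      stop("override window must be odd and >= ", min_window)
    return(override)
  }
  stopifnot(inherits(acf_res, "pii_acf"))
  pos <- which(acf_res$values <= 0 & acf_res$lags > 0)
  if (!length(pos))
    stop("autocorrelation never reaches zero within max_lag; ",
         "supply an explicit window via override")
  w <- acf_res$lags[min(pos)]
  if (w %% 2L == 0L) w <- w + 1L
  max(as.integer(w), as.integer(min_window))
}

#' Centered moving average of the movement index (the PII)
#'
#' Smooths the composite index with an odd, centered moving window, averaging
#' only over defined values. A fix whose (possibly edge-truncated) window
#' holds fewer than half the nominal window count of defined values is left
#' undefined rather than averaged over thin support.
#'
#' @param index either a numeric vector of index values (`NA` = undefined) or
#'   a [movement_index()] data.frame.
#' @param window odd window length in fixes, >= 3.
#' @return data.frame of class `pii_series`: `seq`, `index`, `pii`,
#'   `defined`; attributes `window` and `edge_policy`.
#' @export
smooth_index <- function(index, window) {
  if (is.data.frame(index)) {
    m <- index$index
    ts <- index$timestamp
    seqs <- index$seq
    aid <- attr(index, "animal_id")
  } else {
    m <- as.numeric(index)
    ts <- NULL
    seqs <- seq_along(m)
    aid <- NA_character_
  }
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  n <- length(m)
  if (window > n) stop("window larger than the series")
  half <- window %/% 2L
  pii <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    vals <- m[lo:hi]
    vals <- vals[!is.na(vals)]
    if (length(vals) >= window / 2) pii[i] <- mean(vals)
  }
  out <- data.frame(seq = seqs, index = m, pii = pii, defined = !is.na(pii))
  if (!is.null(ts)) out$timestamp <- ts
  structure(out, window = window, edge_policy = "half-window",
            animal_id = aid,
            class = c("pii_series", "data.frame"))
}
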