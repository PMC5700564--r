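# One-call pipeline: metrics -> scaling -> index -> ACF -> window -> PII ->
# behavior + circadian labels + segments, for a single trajectory.

#' Run the full PII pipeline on one trajectory
#'
#' Convenience wrapper chaining [compute_metrics()], [compute_scaling()],
#' [movement_index()], [index_acf()], [select_window()], [smooth_index()],
#' [classify_pii()], [circadian_class()] and [segment_labels()].
#'
#' @param traj a [trajectory()].
#' @param window `"auto"` for per-animal ACF-based selection (the default
#'   analytical mode), or an odd integer override — 15 is the documented
#'   paper-mode window (the 2.5-day mean lag at 4-h fixes).
#' @param thresholds classification thresholds `c(low, high)`.
#' @param radius,fidelity_window site-fidelity parameters in meters/minutes.
#' @param max_lag ACF lag ceiling.
#' @param ... further arguments to [compute_metrics()].
#' @return list of class `pii_run`: `metrics`, `scaling`, `index`, `acf`,
#'   `window`, `pii`, `labels` (data.frame with `animal_id`, `seq`,
#'   `timestamp`, `pii`, `behavior`, `circadian`), `segments`.
#' @export
run_pii <- function(traj, window = "auto", thresholds = c(1.4, 1.8),
                    radius = 100, fidelity_window = 8 * 7 * 24 * 60,
                    max_lag = NULL, ...) {
  metrics <- compute_metrics(traj, radius = radius, window = fidelity_window, ...)
  scaling <- compute_scaling(metrics)
  idx <- movement_index(metrics, scaling)
  acf_res <- tryCatch(index_acf(idx$index, max_lag), error = function(e) NULL)
  w <- if (identical(window, "auto")) {
    if (is.null(acf_res))
      stop("ACF could not be estimated; supply an explicit window")
    select_window(acf_res)
  } else select_window(acf_res, override = window)
  pii <- smooth_index(idx, w)
  behavior <- classify_pii(pii, thresholds)
  labels <- data.frame(animal_id = attr(traj, "animal_id"),
                       seq = traj$seq, timestamp = traj$timestamp,
                       index = idx$index, pii = pii$pii,
                       behavior = behavior,
                       circadian = circadian_class(traj$timestamp),
                       stringsAsFactors = FALSE)
  structure(list(metrics = metrics, scaling = scaling, index = idx,
                 acf = acf_res, window = w, pii = pii, labels = labels,
                 segments = segment_labels(behavior,
                                           attr(traj, "nominal_interval")),
                 thresholds = thresholds),
            class = "pii_run")
}

#' @export
print.pii_run <- function(x, ...) {
  cat(sprintf("PII run: animal %s, window %d fixes, thresholds (%.2f, %.2f)\n",
              x$labels$animal_id[1], x$window, x$thresholds[1], x$thresholds[2]))
  print(table(x$labels$behavior, useNA = "ifany"))
  cat(sprintf("%d segments\n", nrow(x$segments)))
  invisible(x)
}
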