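# Behavioral classification of the PII, circadian classes, segmentation,
# evaluation against field verifications, and class-frequency summaries.

BEHAVIOR_LEVELS <- c("directed", "search", "cache")
CIRCADIAN_LEVELS <- c("nocturnal", "crepuscular", "diurnal")

# Default six-fix collar schedule: nominal local-standard hours and their
# circadian classes (21:00/01:00 nocturnal, 05:00/17:00 crepuscular,
# 09:00/13:00 diurnal).
DEFAULT_CIRCADIAN_SCHEME <- c(`21` = "nocturnal", `1` = "nocturnal",
                              `5` = "crepuscular", `17` = "crepuscular",
                              `9` = "diurnal", `13` = "diurnal")

#' Classify PII values into behavior classes
#'
#' Three-class threshold rule: PII above the high threshold is caching /
#' denning behavior; values in the closed interval \[low, high\] are search;
#' values below the low threshold are directed movement. Ties at the
#' boundaries go to search ("greater than" the high threshold is required
#' for a cache label).
#'
#' @param pii a [smooth_index()] result, or a numeric vector of PII values.
#' @param thresholds numeric pair `c(low, high)`, default `c(1.4, 1.8)`.
#' @return factor with levels `directed`, `search`, `cache`; `NA` where PII
#'   is undefined.
#' @export
classify_pii <- function(pii, thresholds = c(low = 1.4, high = 1.8)) {
  v <- if (is.data.frame(pii)) pii$pii else as.numeric(pii)
  lo <- thresholds[[1]]; hi <- thresholds[[2]]
  if (!(lo < hi)) stop("configuration error: thresholds must satisfy low < high")
  lab <- ifelse(v > hi, "cache", ifelse(v < lo, "directed", "search"))
  factor(lab, levels = BEHAVIOR_LEVELS)
}

#' Circadian class of a time of day
#'
#' Maps a timestamp to the circadian class of the nearest nominal fix hour
#' of the collar schedule (circular distance on the 24-h clock; ties go to
#' the earlier scheduled hour). An alternative schedule can be supplied as a
#' named vector of hour -> class.
#'
#' @param timestamp POSIXct vector (local standard time).
#' @param scheme named character vector mapping nominal hours to classes;
#'   default is the six-fix schedule.
#' @return factor with levels `nocturnal`, `crepuscular`, `diurnal`.
#' @export
circadian_class <- function(timestamp, scheme = DEFAULT_CIRCADIAN_SCHEME) {
  hours <- as.numeric(names(scheme))
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  lab <- vapply(h, function(hh) {
    d <- abs(hh - hours)
    d <- pmin(d, 24 - d)
    unname(scheme[which.min(d)])
  }, character(1))
  factor(lab, levels = CIRCADIAN_LEVELS)
}

#' Build contiguous behavioral segments (paths)
#'
#' Run-length encodes per-fix behavior labels into maximal runs of equal
#' labels. Undefined fixes break runs; segments therefore tile the defined
#' portion of the record without overlap and adjacent segments differ in
#' label (or are separated by undefined fixes).
#'
#' @param labels factor/character vector of per-fix behavior labels (`NA` =
#'   undefined).
#' @param nominal_interval fix interval in minutes, used for durations.
#' @return data.frame of class `pii_segments`: `label`, `start_seq`,
#'   `end_seq`, `n_fixes`, `duration_hours`.
#' @export
segment_labels <- function(labels, nominal_interval = 240) {
  lab <- as.character(labels)
  r <- rle(ifelse(is.na(lab), "<undef>", lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "<undef>"
  out <- data.frame(label = factor(r$values[keep], levels = BEHAVIOR_LEVELS),
                    start_seq = starts[keep], end_seq = ends[keep],
                    n_fixes = r$lengths[keep])
  out$duration_hours <- out$n_fixes * nominal_interval / 60
  structure(out, class = c("pii_segments", "data.frame"))
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Evaluate PII classification against field verifications
#'
#' Compares per-fix behavior labels with field-investigated site classes.
#' Predicted `directed` and `search` collapse to `non_feeding`; predicted
#' `cache` stays `cache`. Truth records are matched to fixes by `seq` when
#' present, otherwise by nearest timestamp within one nominal interval;
#' unresolvable records are listed, excluded, and counted.
#'
#' @param labels data.frame with columns `animal_id`, `seq`, `timestamp`
#'   (optional), and `behavior` (per-fix labels, `NA` allowed).
#' @param truth a [read_verification_table()] data.frame (columns
#'   `animal_id`, `seq` and/or `timestamp`, `observed_class`).
#' @param nominal_interval minutes, for timestamp matching.
#' @return object of class `pii_confusion`: list with `per_animal` and
#'   `pooled` count tables (rows `non_feeding`/`cache` x
#'   correct/incorrect, with percent correct rounded half-up to whole
#'   percent) and `unmatched` truth records.
#' @export
evaluate_classification <- function(labels, truth, nominal_interval = 240) {
  if (nrow(truth) == 0L) stop("empty verification table; nothing to evaluate")
  stopifnot(all(c("animal_id", "behavior") %in% names(labels)))
  pred_all <- ifelse(as.character(labels$behavior) == "cache",
                     "cache", "non_feeding")
  matched <- data.frame(animal_id = character(0), observed = character(0),
                        predicted = character(0), stringsAsFactors = FALSE)
  unmatched <- truth[0, ]
  for (k in seq_len(nrow(truth))) {
    sel <- labels$animal_id == truth$animal_id[k]
    hit <- NA_integer_
    if (!is.na(truth$seq[k])) {
      w <- which(sel & labels$seq == truth$seq[k])
      if (length(w)) hit <- w[1L]
    } else if (!is.null(truth$timestamp) && !is.na(truth$timestamp[k]) &&
               "timestamp" %in% names(labels)) {
      dt <- abs(as.numeric(labels$timestamp) - as.numeric(truth$timestamp[k])) / 60
      dt[!sel] <- Inf
      if (any(dt <= nominal_interval)) hit <- which.min(dt)
    }
    if (is.na(hit) || is.na(labels$behavior[hit])) {
      unmatched <- rbind(unmatched, truth[k, ])
    } else {
      matched <- rbind(matched, data.frame(
        animal_id = truth$animal_id[k],
        observed = truth$observed_class[k],
        predicted = pred_all[hit], stringsAsFactors = FALSE))
    }
  }
  if (nrow(matched) == 0L) stop("no verification record could be matched to a labeled fix")
  conf_table <- function(d) {
    out <- data.frame(observed = c("non_feeding", "cache"),
                      correct = c(sum(d$observed == "non_feeding" & d$predicted == "non_feeding"),
                                  sum(d$observed == "cache" & d$predicted == "cache")),
                      incorrect = c(sum(d$observed == "non_feeding" & d$predicted != "non_feeding"),
                                    sum(d$observed == "cache" & d$predicted != "cache")))
    out$total <- out$correct + out$incorrect
    out$percent_correct <- ifelse(out$total > 0,
                                  round_half_up(100 * out$correct / out$total), NA)
    out
  }
  per_animal <- lapply(split(matched, matched$animal_id), conf_table)
  pooled <- conf_table(matched)
  overall <- function(tab) round_half_up(100 * sum(tab$correct) / sum(tab$total))
  structure(list(per_animal = per_animal,
                 per_animal_percent = vapply(per_animal, overall, numeric(1)),
                 pooled = pooled,
                 overall_percent = overall(pooled),
                 n_matched = nrow(matched),
                 unmatched = unmatched),
            class = "pii_confusion")
}

#' @export
print.pii_confusion <- function(x, ...) {
  cat("PII classification vs. field verification\n")
  for (a in names(x$per_animal)) {
    cat(sprintf("\n%s (overall %d%%)\n", a, x$per_animal_percent[[a]]))
    print(x$per_animal[[a]], row.names = FALSE)
  }
  cat(sprintf("\nAll animals pooled (n = %d): overall %d%% correct\n",
              x$n_matched, x$overall_percent))
  print(x$pooled, row.names = FALSE)
  if (nrow(x$unmatched))
    cat(sprintf("%d verification record(s) could not be matched and were excluded\n",
                nrow(x$unmatched)))
  invisible(x)
}

#' Rolling class frequencies over time
#'
#' Proportion of each behavior class among defined fixes within rolling
#' windows, exposing seasonal signals (denning, migration) as shifts in
#' class frequency.
#'
#' @param labels per-fix behavior labels (factor/character, `NA` allowed).
#' @param timestamp POSIXct vector aligned with `labels`.
#' @param window_days window length in days (>= 1).
#' @param step_days stride between window starts in days (default 1).
#' @return data.frame: `window_start`, `window_end`, `n`, `p_directed`,
#'   `p_search`, `p_cache`; proportions sum to 1 on every row.
#' @export
class_frequencies <- function(labels, timestamp, window_days = 30,
                              step_days = 1) {
  stopifnot(window_days >= 1)
  lab <- as.character(labels)
  t <- as.numeric(timestamp)
  ok <- !is.na(lab)
  starts <- seq(min(t), max(t), by = step_days * 86400)
  rows <- lapply(starts, function(s) {
    inwin <- ok & t >= s & t < s + window_days * 86400
    n <- sum(inwin)
    if (n == 0L) return(NULL)
    data.frame(window_start = as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
               window_end = as.POSIXct(s + window_days * 86400,
                                       origin = "1970-01-01", tz = "UTC"),
               n = n,
               p_directed = sum(lab[inwin] == "directed") / n,
               p_search = sum(lab[inwin] == "search") / n,
               p_cache = sum(lab[inwin] == "cache") / n)
  })
  do.call(rbind, rows)
}
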