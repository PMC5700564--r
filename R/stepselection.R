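# Paired use-versus-availability step selection against a covariate raster,
# stratified into circadian x behavior subsets and fitted with binary
# logistic regression to expose statistical nonstationarity of selection.

#' Maximum single-interval step length (d_max)
#'
#' The largest Euclidean displacement between consecutive valid fixes one
#' nominal interval apart; steps spanning missed fixes (longer gaps) do not
#' qualify. Defines the radius of the availability disc for the animal.
#'
#' @param traj a [trajectory()].
#' @param tolerance timing slack in minutes around the nominal interval.
#' @return meters.
#' @export
max_step <- function(traj, tolerance = 15) {
  stopifnot(inherits(traj, "trajectory"))
  t <- as.numeric(traj$timestamp) / 60
  ival <- attr(traj, "nominal_interval")
  i <- which(traj$valid[-nrow(traj)] & traj$valid[-1L] &
             abs(diff(t) - ival) <= tolerance)
  if (!length(i)) stop("no consecutive valid fixes at the nominal interval")
  max(sqrt(diff(traj$x)[i]^2 + diff(traj$y)[i]^2))
}

#' Build paired use/availability samples
#'
#' For each fix t0 preceded by a valid fix t-1 one nominal interval earlier,
#' the used value is the raster value at t0 and the availability value is
#' the mean raster value over the disc of radius `d_max` centered at t-1
#' (the window of what was reachable during that movement). Pairs whose used
#' location falls outside the raster (or on nodata) are skipped and
#' reported, as are fixes without behavior/circadian labels (they could not
#' enter any of the nine subsets).
#'
#' @param traj a [trajectory()].
#' @param raster an [ascii_grid()] covariate raster (projected meters
#'   matching the fix table; e.g. topographic exposure at 30 m).
#' @param behavior,circadian per-fix labels aligned to `traj` (see
#'   [classify_pii()], [circadian_class()]).
#' @param d_max availability radius in meters; default [max_step()] of the
#'   trajectory.
#' @param tolerance timing slack in minutes.
#' @return data.frame of class `use_avail_pairs`: `animal_id`, `seq`,
#'   `used_value`, `avail_mean`, `circadian`, `behavior`; skipped fixes are
#'   reported in attribute `skipped`.
#' @export
build_pairs <- function(traj, raster, behavior, circadian,
                        d_max = NULL, tolerance = 15) {
  stopifnot(inherits(traj, "trajectory"), inherits(raster, "ascii_grid"))
  if (is.null(d_max)) d_max <- max_step(traj, tolerance)
  t <- as.numeric(traj$timestamp) / 60
  ival <- attr(traj, "nominal_interval")
  rows <- vector("list", nrow(traj))
  skipped <- integer(0)
  for (i in 2:nrow(traj)) {
    if (!traj$valid[i] || !traj$valid[i - 1L]) next
    if (abs((t[i] - t[i - 1L]) - ival) > tolerance) next
    if (is.na(behavior[i]) || is.na(circadian[i])) next
    used <- grid_value_at(raster, traj$x[i], traj$y[i])
    avail <- grid_disc_mean(raster, traj$x[i - 1L], traj$y[i - 1L], d_max)
    if (is.na(used) || is.na(avail)) { skipped <- c(skipped, i); next }
    rows[[i]] <- data.frame(animal_id = attr(traj, "animal_id"),
                            seq = traj$seq[i],
                            used_value = used, avail_mean = avail,
                            circadian = as.character(circadian[i]),
                            behavior = as.character(behavior[i]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(animal_id = character(0), seq = integer(0),
                                      used_value = numeric(0), avail_mean = numeric(0),
                                      circadian = character(0), behavior = character(0))
  structure(out, d_max = d_max, skipped = skipped,
            class = c("use_avail_pairs", "data.frame"))
}

#' Partition pairs into the nine circadian x behavior subsets
#'
#' @param pairs a [build_pairs()] data.frame (or any data.frame with
#'   `circadian` and `behavior` columns).
#' @return named list of 9 data.frames (`nocturnal.directed`, ...); empty
#'   subsets are present (zero rows) and flagged in attribute `empty`.
#' @export
partition_subsets <- function(pairs) {
  keys <- as.vector(outer(CIRCADIAN_LEVELS, BEHAVIOR_LEVELS,
                          function(a, b) paste(a, b, sep = ".")))
  out <- lapply(keys, function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    pairs[!is.na(pairs$circadian) & !is.na(pairs$behavior) &
          pairs$circadian == parts[1] & pairs$behavior == parts[2], ,
          drop = FALSE]
  })
  names(out) <- keys
  structure(out, empty = keys[vapply(out, nrow, integer(1)) == 0L])
}

#' Fit the selection coefficient for one subset
#'
#' Stacks each pair into one used record (response 1, covariate =
#' `used_value`) and one availability record (response 0, covariate =
#' `avail_mean`) and fits an ordinary binomial logistic regression. The
#' returned beta is the log-odds change per covariate unit. Non-convergence
#' or (quasi-)complete separation is flagged and no coefficient is reported.
#'
#' @param subset data.frame of pairs (one circadian x behavior subset).
#' @param min_pairs smallest subset size for a reported coefficient
#'   (default 20; tiny strata separate or fit unstably).
#' @param subset_id optional label carried through to the result.
#' @return list of class `selection_fit`: `subset`, `beta`, `se`, `n_pairs`,
#'   `converged`, `separation`, `note`.
#' @export
fit_selection <- function(subset, min_pairs = 20, subset_id = NA_character_) {
  n <- nrow(subset)
  res <- list(subset = subset_id, beta = NA_real_, se = NA_real_,
              n_pairs = n, converged = FALSE, separation = FALSE,
              note = "")
  class(res) <- "selection_fit"
  if (n < min_pairs) {
    res$note <- sprintf("only %d pairs (< %d); no coefficient reported", n, min_pairs)
    return(res)
  }
  y <- rep(c(1, 0), each = n)
  cov <- c(subset$used_value, subset$avail_mean)
  if (stats::sd(cov) == 0) {
    res$note <- "no contrast: covariate constant across used and available"
    return(res)
  }
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ cov, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (fit$deviance < 1e-6) sep_warned <- TRUE   # perfect fit = separation
  if (sep_warned || !fit$converged || abs(co["cov", "Estimate"]) > 50) {
    res$separation <- sep_warned
    res$note <- "non-convergence or separation; no coefficient reported"
    return(res)
  }
  res$beta <- unname(co["cov", "Estimate"])
  res$se <- unname(co["cov", "Std. Error"])
  res$converged <- TRUE
  res
}

#' @export
print.selection_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("selection fit [%s]: beta %.4f (SE %.4f), %d pairs\n",
                x$subset, x$beta, x$se, x$n_pairs))
  else
    cat(sprintf("selection fit [%s]: no coefficient (%s)\n", x$subset, x$note))
  invisible(x)
}

#' Fit all nine circadian x behavior subsets
#'
#' @param pairs a [build_pairs()] data.frame.
#' @param min_pairs see [fit_selection()].
#' @return data.frame of class `selection_results`, one row per subset:
#'   `subset`, `circadian`, `behavior`, `beta`, `se`, `n_pairs`,
#'   `converged`, `note`.
#' @export
fit_selection_all <- function(pairs, min_pairs = 20) {
  subs <- partition_subsets(pairs)
  rows <- lapply(names(subs), function(k) {
    f <- fit_selection(subs[[k]], min_pairs = min_pairs, subset_id = k)
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(subset = k, circadian = parts[1], behavior = parts[2],
               beta = f$beta, se = f$se, n_pairs = f$n_pairs,
               converged = f$converged, note = f$note,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("selection_results", "data.frame"))
}

#' Nonstationarity comparison of selection coefficients
#'
#' Orders the estimable subset coefficients and attaches Wald 95% intervals.
#' Statistical nonstationarity of selection shows up as non-overlapping
#' intervals across behavior or circadian strata; no hypothesis-test
#' machinery beyond interval overlap is applied.
#'
#' @param results a [fit_selection_all()] data.frame.
#' @return data.frame of class `nonstationarity_report`, estimable subsets
#'   ordered by beta (descending) with `ci_lo`/`ci_hi`; attribute `message`
#'   states insufficiency when fewer than 2 subsets are estimable.
#' @export
nonstationarity_report <- function(results) {
  est <- results[results$converged & !is.na(results$beta), , drop = FALSE]
  msg <- NULL
  if (nrow(est) < 2L)
    msg <- sprintf("only %d estimable subset(s); no cross-subset comparison possible",
                   nrow(est))
  est$ci_lo <- est$beta - 1.96 * est$se
  est$ci_hi <- est$beta + 1.96 * est$se
  est <- est[order(-est$beta), , drop = FALSE]
  est$rank <- seq_len(nrow(est))
  structure(est[, c("rank", "subset", "circadian", "behavior", "beta", "se",
                    "ci_lo", "ci_hi", "n_pairs")],
            message = msg,
            class = c("nonstationarity_report", "data.frame"))
}

#' @export
print.nonstationarity_report <- function(x, ...) {
  msg <- attr(x, "message")
  if (!is.null(msg)) cat("NOTE:", msg, "\n")
  if (nrow(x)) {
    cat("Selection coefficients by circadian x behavior subset (most positive first):\n")
    print(as.data.frame(x), row.names = FALSE, digits = 4)
    if (nrow(x) >= 2L) {
      top <- x[1L, ]; bot <- x[nrow(x), ]
      overlap <- top$ci_lo <= bot$ci_hi
      cat(if (overlap)
        "Extreme subsets' 95% intervals overlap: no ordering claim.\n"
      else
        sprintf("Nonstationarity: %s (beta %.3f) and %s (beta %.3f) have non-overlapping 95%% intervals.\n",
                top$subset, top$beta, bot$subset, bot$beta))
    }
  }
  invisible(x)
}
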