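# Per-fix movement metrics and the composite movement index.
#
# Four characteristics are computed at each interior fix t0 from its valid
# neighbors t-1 and t+1:
#   speed          S = (d1/dt1 + d2/dt2) / 2            [m/min]
#   turning        TA_standard = |turn angle| / 180     [0, 1]
#   straightness   M_str = (d1 + d2) / c                [>= 1]
#   site fidelity  M_fid = w * dbar                     [m-weighted]
# and standardized per animal; their partial sum (speed entering as its
# complement) is the composite movement index in [0, 4].

#' Step geometry at one fix
#'
#' Computes distances and elapsed times for the movement triple
#' (t-1, t0, t+1), where t-1 and t+1 are the nearest valid fixes before and
#' after `seq`. If `seq` is invalid, lacks a neighbor, or either adjacent gap
#' exceeds `gap_factor` nominal intervals, the geometry is undefined and
#' `NULL` is returned (not an error).
#'
#' @param traj a [trajectory()].
#' @param seq scheduled position of t0.
#' @param gap_factor maximum allowed gap on each side, as a multiple of the
#'   nominal interval (default 2).
#' @return list with `d1`, `d2`, `c` (meters), `dt1`, `dt2` (minutes),
#'   `turn_deg` (absolute turn in \[0, 180\]), or `NULL` if undefined.
#' @export
step_geometry <- function(traj, seq, gap_factor = 2) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (seq < 1L || seq > n || !traj$valid[seq]) return(NULL)
  vprev <- which(traj$valid[seq_len(seq - 1L)])
  vnext <- which(traj$valid[-seq_len(seq)]) + seq
  if (!length(vprev) || !length(vnext)) return(NULL)
  i0 <- max(vprev); i2 <- min(vnext)
  ival <- attr(traj, "nominal_interval")
  t <- as.numeric(traj$timestamp) / 60
  dt1 <- t[seq] - t[i0]; dt2 <- t[i2] - t[seq]
  if (dt1 > gap_factor * ival + 1e-9 || dt2 > gap_factor * ival + 1e-9) return(NULL)
  p0 <- c(traj$x[i0], traj$y[i0])
  p1 <- c(traj$x[seq], traj$y[seq])
  p2 <- c(traj$x[i2], traj$y[i2])
  d1 <- sqrt(sum((p1 - p0)^2)); d2 <- sqrt(sum((p2 - p1)^2))
  ch <- sqrt(sum((p2 - p0)^2))
  turn <- if (d1 == 0 || d2 == 0) 0 else {
    h1 <- atan2(p1[2] - p0[2], p1[1] - p0[1])
    h2 <- atan2(p2[2] - p1[2], p2[1] - p1[1])
    dh <- (h2 - h1) %% (2 * pi)
    if (dh > pi) dh <- 2 * pi - dh
    dh * 180 / pi
  }
  list(d1 = d1, d2 = d2, c = ch, dt1 = dt1, dt2 = dt2, turn_deg = turn)
}

#' Speed at a fix
#'
#' Average of the two step speeds around t0, in meters per minute.
#'
#' @param geom a [step_geometry()] result.
#' @return numeric, m/min.
#' @export
speed_at <- function(geom) {
  (geom$d1 / geom$dt1 + geom$d2 / geom$dt2) / 2
}

#' Standardized absolute turn angle
#'
#' @param geom a [step_geometry()] result.
#' @return `|turn| / 180`, in \[0, 1\].
#' @export
turn_standard <- function(geom) {
  abs(geom$turn_deg) / 180
}

#' Straightness index
#'
#' Ratio of the two step lengths to the chord: 1 for straight travel, large
#' for out-and-back recursion. When the chord is shorter than `chord_floor`
#' (including an exact return, chord 0) the ratio is unbounded and the
#' capped-high sentinel `Inf` is returned; it standardizes to 1 because the
#' top decile is capped at 1 anyway.
#'
#' @param geom a [step_geometry()] result.
#' @param chord_floor meters; below this the sentinel is used (default 1).
#' @return numeric >= 1, or `Inf` (capped-high sentinel).
#' @export
straightness <- function(geom, chord_floor = 1) {
  if (geom$c < chord_floor) return(Inf)
  (geom$d1 + geom$d2) / geom$c
}

# Site fidelity for every valid fix of a trajectory (production route:
# temporal-window-sliced scan; the O(n^2) all-pairs oracle lives in the
# tests). Neighbors are valid fixes other than self within `radius` meters
# AND within +/- `window` minutes.
fidelity_all <- function(traj, radius = 100, window = 8 * 7 * 24 * 60,
                         max_possible_neighbors = NULL) {
  if (is.null(max_possible_neighbors))
    max_possible_neighbors <- 2 * window / attr(traj, "nominal_interval")
  t <- as.numeric(traj$timestamp) / 60
  out <- rep(NA_real_, nrow(traj))
  vidx <- which(traj$valid)
  x <- traj$x; y <- traj$y
  for (i in vidx) {
    lo <- findInterval(t[i] - window - 1e-9, t) + 1L
    hi <- findInterval(t[i] + window + 1e-9, t)
    j <- vidx[vidx >= lo & vidx <= hi & vidx != i]
    if (!length(j)) { out[i] <- 0; next }
    d <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
    d <- d[d <= radius]
    out[i] <- if (!length(d)) 0 else
      mean(d) * (length(d) / max_possible_neighbors)
  }
  out
}

#' Site fidelity at one fix
#'
#' Spatiotemporal clustering measure: the mean distance from the fix to all
#' other valid fixes within `radius` meters and within +/- `window` minutes,
#' multiplied by the fraction those neighbors make of the maximum possible
#' number of in-window fixes. Zero when no neighbor falls in the window.
#'
#' @param traj a [trajectory()].
#' @param seq scheduled position of the fix.
#' @param radius spatial window radius in meters (default 100, the
#'   conventional kill/cache-site clustering distance).
#' @param window temporal half-window in minutes (default 8 weeks, the
#'   longest a den is typically used before cubs travel).
#' @param max_possible_neighbors denominator of the weight; default
#'   `2 * window / nominal_interval` (672 for +/- 8 weeks at 4-h fixes),
#'   deliberately not truncated at record boundaries.
#' @return unitless value >= 0, or `NA` if the fix is invalid.
#' @export
site_fidelity <- function(traj, seq, radius = 100, window = 8 * 7 * 24 * 60,
                          max_possible_neighbors = NULL) {
  fidelity_all(traj, radius, window, max_possible_neighbors)[seq]
}

#' Compute all per-fix movement metrics for a trajectory
#'
#' @param traj a [trajectory()].
#' @param radius,window,max_possible_neighbors site-fidelity parameters, see
#'   [site_fidelity()].
#' @param gap_factor gap policy for the step geometry, see [step_geometry()].
#' @param chord_floor straightness sentinel floor in meters.
#' @return data.frame of class `movement_metrics`, one row per scheduled fix:
#'   `seq`, `timestamp`, `defined`, `d1`, `d2`, `chord`, `turn_deg`, `speed`,
#'   `ta_standard`, `straightness_raw` (Inf = capped-high sentinel),
#'   `site_fidelity_raw`. First/last valid fixes and fixes violating the gap
#'   policy have undefined geometry metrics but still carry site fidelity.
#' @export
compute_metrics <- function(traj, radius = 100, window = 8 * 7 * 24 * 60,
                            max_possible_neighbors = NULL, gap_factor = 2,
                            chord_floor = 1) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  out <- data.frame(seq = traj$seq, timestamp = traj$timestamp,
                    defined = FALSE,
                    d1 = NA_real_, d2 = NA_real_, chord = NA_real_,
                    turn_deg = NA_real_, speed = NA_real_,
                    ta_standard = NA_real_, straightness_raw = NA_real_,
                    site_fidelity_raw = NA_real_)
  out$site_fidelity_raw <- fidelity_all(traj, radius, window,
                                        max_possible_neighbors)
  for (i in seq_len(n)) {
    g <- step_geometry(traj, i, gap_factor)
    if (is.null(g)) next
    out$defined[i] <- TRUE
    out$d1[i] <- g$d1; out$d2[i] <- g$d2; out$chord[i] <- g$c
    out$turn_deg[i] <- g$turn_deg
    out$speed[i] <- speed_at(g)
    out$ta_standard[i] <- turn_standard(g)
    out$straightness_raw[i] <- straightness(g, chord_floor)
  }
  structure(out, animal_id = attr(traj, "animal_id"),
            nominal_interval = attr(traj, "nominal_interval"),
            radius = radius, window = window,
            class = c("movement_metrics", "data.frame"))
}

#' Per-animal scaling constants for standardization
#'
#' Each metric is rescaled to \[0, 1\] by its per-animal maximum, except
#' straightness, whose heavy right tail is rescaled by the 90th percentile
#' (values in the 90th-100th percentile standardize to 1). The percentile is
#' the linear-interpolation quantile (R type 7) over finite straightness
#' values of defined records; capped-high sentinels are excluded from the
#' percentile but standardize to 1.
#'
#' @param metrics a [compute_metrics()] result.
#' @param straightness_prob percentile used for the straightness scale
#'   (default 0.9).
#' @return list of class `scaling_constants`: `animal_id`, `max_speed`,
#'   `straightness_p90`, `max_fidelity`, plus the fidelity parameters echoed.
#' @export
compute_scaling <- function(metrics, straightness_prob = 0.9) {
  stopifnot(inherits(metrics, "movement_metrics"))
  def <- metrics$defined
  if (!any(def)) stop("no defined metric records; cannot compute scaling")
  str_fin <- metrics$straightness_raw[def & is.finite(metrics$straightness_raw)]
  structure(list(
    animal_id = attr(metrics, "animal_id"),
    max_speed = max(metrics$speed[def]),
    straightness_p90 = if (length(str_fin))
      unname(stats::quantile(str_fin, straightness_prob, type = 7)) else 1,
    max_fidelity = max(metrics$site_fidelity_raw, na.rm = TRUE),
    fidelity_radius = attr(metrics, "radius"),
    fidelity_window = attr(metrics, "window")),
    class = "scaling_constants")
}

#' @export
print.scaling_constants <- function(x, ...) {
  cat(sprintf("Scaling constants (%s): max speed %.3f m/min, straightness p90 %.3f, max fidelity %.4f\n",
              x$animal_id, x$max_speed, x$straightness_p90, x$max_fidelity))
  invisible(x)
}

#' Composite movement index
#'
#' Partial sum of the four standardized metrics with speed entering as its
#' complement:
#' `M = (1 - speed_std) + ta_standard + straightness_std + fidelity_std`,
#' with a potential range of 0 to 4. Low values are fast, straight movements
#' through rarely visited areas; high values are slow, tortuous movements in
#' frequently revisited areas (caches, dens).
#'
#' @param metrics a [compute_metrics()] result.
#' @param scaling a [compute_scaling()] result (defaults to scaling computed
#'   from `metrics` itself).
#' @return data.frame of class `movement_index`: per-fix `seq`, `timestamp`,
#'   `defined`, the standardized components `speed_std`, `ta_standard`,
#'   `straightness_std`, `fidelity_std`, and the composite `index` in
#'   \[0, 4\] (`NA` where undefined).
#' @export
movement_index <- function(metrics, scaling = compute_scaling(metrics)) {
  stopifnot(inherits(metrics, "movement_metrics"),
            inherits(scaling, "scaling_constants"))
  speed_std <- pmin(metrics$speed / scaling$max_speed, 1)
  straightness_std <- pmin(metrics$straightness_raw / scaling$straightness_p90, 1)
  fidelity_std <- if (scaling$max_fidelity > 0)
    pmin(metrics$site_fidelity_raw / scaling$max_fidelity, 1)
  else ifelse(is.na(metrics$site_fidelity_raw), NA_real_, 0)
  idx <- (1 - speed_std) + metrics$ta_standard + straightness_std + fidelity_std
  out <- data.frame(seq = metrics$seq, timestamp = metrics$timestamp,
                    defined = metrics$defined & !is.na(idx),
                    speed_std = speed_std, ta_standard = metrics$ta_standard,
                    straightness_std = straightness_std,
                    fidelity_std = fidelity_std, index = idx)
  out$index[!out$defined] <- NA_real_
  structure(out, animal_id = attr(metrics, "animal_id"),
            nominal_interval = attr(metrics, "nominal_interval"),
            class = c("movement_index", "data.frame"))
}
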