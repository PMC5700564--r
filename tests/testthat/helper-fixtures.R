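# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (O(n^2) scans, direct sums) and never share code with the package's
# production paths.

t0 <- as.POSIXct("2010-03-01 01:00:00", tz = "UTC")

# Trajectory from a coordinate matrix on a perfect nominal grid.
make_traj <- function(xy, start = t0, interval = 240, animal = "A1",
                      valid = rep(TRUE, nrow(xy))) {
  fixes <- data.frame(animal_id = animal,
                      timestamp = start + (seq_len(nrow(xy)) - 1) * interval * 60,
                      x = ifelse(valid, xy[, 1], NA_real_),
                      y = ifelse(valid, xy[, 2], NA_real_),
                      valid = valid)
  trajectory(fixes, nominal_interval = interval)
}

# Brute-force all-pairs site-fidelity oracle (full distance matrix).
fidelity_oracle <- function(traj, radius = 100, window = 8 * 7 * 24 * 60,
                            mpn = 2 * window / attr(traj, "nominal_interval")) {
  n <- nrow(traj)
  D <- as.matrix(stats::dist(cbind(traj$x, traj$y)))
  tmin <- as.numeric(traj$timestamp) / 60
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!traj$valid[i]) next
    sel <- logical(n)
    for (j in seq_len(n)) {
      if (j == i || !traj$valid[j]) next
      if (abs(tmin[j] - tmin[i]) <= window && D[i, j] <= radius) sel[j] <- TRUE
    }
    out[i] <- if (!any(sel)) 0 else mean(D[i, sel]) * (sum(sel) / mpn)
  }
  out
}

# Direct-sum biased autocorrelation oracle.
acf_oracle <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  denom <- sum(x^2)
  vapply(0:max_lag, function(k)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / denom, numeric(1))
}

# Synthetic metrics table with chosen standardized-component inputs, for
# exercising movement_index() at controlled values.
fake_metrics <- function(speed, ta, straight, fid, interval = 240) {
  n <- length(speed)
  out <- data.frame(seq = seq_len(n),
                    timestamp = t0 + (seq_len(n) - 1) * interval * 60,
                    defined = TRUE,
                    d1 = NA_real_, d2 = NA_real_, chord = NA_real_,
                    turn_deg = ta * 180, speed = speed,
                    ta_standard = ta, straightness_raw = straight,
                    site_fidelity_raw = fid)
  structure(out, animal_id = "FAKE", nominal_interval = interval,
            radius = 100, window = 8 * 7 * 24 * 60,
            class = c("movement_metrics", "data.frame"))
}

fake_scaling <- function(max_speed, p90, max_fid) {
  structure(list(animal_id = "FAKE", max_speed = max_speed,
                 straightness_p90 = p90, max_fidelity = max_fid,
                 fidelity_radius = 100, fidelity_window = 8 * 7 * 24 * 60),
            class = "scaling_constants")
}

# Labels + truth fixture realizing given confusion counts for one animal:
# counts = c(nf_correct, nf_incorrect, cache_correct, cache_incorrect).
confusion_fixture <- function(animal, counts, seq_offset = 0L) {
  pred <- c(rep("search", counts[1]), rep("cache", counts[2]),
            rep("cache", counts[3]), rep("search", counts[4]))
  obs <- c(rep("non_feeding", counts[1] + counts[2]),
           rep("cache", counts[3] + counts[4]))
  n <- length(pred)
  list(labels = data.frame(animal_id = animal, seq = seq_offset + seq_len(n),
                           behavior = pred, stringsAsFactors = FALSE),
       truth = data.frame(animal_id = animal, seq = seq_offset + seq_len(n),
                          observed_class = obs, stringsAsFactors = FALSE))
}

# Full printed confusion-count fixture across the five field-verified
# animals: per-animal (nf_correct, nf_incorrect, cache_correct,
# cache_incorrect).
table3_counts <- list(AS02 = c(2, 0, 20, 4),
                      C07 = c(26, 0, 17, 10),
                      AS07 = c(3, 0, 13, 3),
                      C04 = c(22, 0, 26, 4),
                      P26 = c(7, 2, 40, 18))

table3_fixture <- function() {
  off <- 0L
  labels <- NULL; truth <- NULL
  for (a in names(table3_counts)) {
    fx <- confusion_fixture(a, table3_counts[[a]], off)
    labels <- rbind(labels, fx$labels)
    truth <- rbind(truth, fx$truth)
    off <- off + nrow(fx$labels)
  }
  list(labels = labels, truth = truth)
}

write_fix_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
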