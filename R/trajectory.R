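# Fix tables and trajectories on a nominal collar schedule.
#
# A trajectory is a data.frame with one row per *scheduled* fix slot:
# columns animal_id, seq, timestamp, x, y, valid. Failed acquisitions are
# retained as invalid placeholder rows with NA coordinates so that all
# downstream metrics see a regular temporal grid.

#' Construct a trajectory object
#'
#' A trajectory holds the ordered, timestamped planar fixes of one animal on
#' the nominal collar schedule. Coordinates must be projected planar meters
#' (e.g. UTM); timestamps are local standard time (no daylight-saving shifts).
#'
#' @param fixes data.frame with columns `animal_id`, `timestamp` (POSIXct),
#'   `x`, `y` (meters), `valid` (logical). Rows must be on the nominal grid
#'   and strictly increasing in time.
#' @param nominal_interval scheduled minutes between fixes (default 240, i.e.
#'   six fixes per day).
#' @return object of class `trajectory` (a data.frame with a `seq` column and
#'   attributes `animal_id` and `nominal_interval`).
#' @export
trajectory <- function(fixes, nominal_interval = 240) {
  stopifnot(is.data.frame(fixes),
            all(c("animal_id", "timestamp", "x", "y", "valid") %in% names(fixes)))
  if (nrow(fixes) == 0L) stop("trajectory must contain at least one fix")
  if (length(unique(fixes$animal_id)) != 1L)
    stop("a trajectory holds exactly one animal")
  ts <- as.numeric(fixes$timestamp)
  if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing")
  dt <- diff(ts) / 60
  if (length(dt) && any(abs(dt / nominal_interval - round(dt / nominal_interval)) > 1e-6))
    stop("consecutive timestamps must differ by integer multiples of the nominal interval")
  bad <- fixes$valid & (!is.finite(fixes$x) | !is.finite(fixes$y))
  if (any(bad)) stop("valid fixes must have finite coordinates")
  fixes$x[!fixes$valid] <- NA_real_
  fixes$y[!fixes$valid] <- NA_real_
  fixes$seq <- seq_len(nrow(fixes))
  fixes <- fixes[, c("animal_id", "seq", "timestamp", "x", "y", "valid")]
  structure(fixes,
            animal_id = fixes$animal_id[1L],
            nominal_interval = nominal_interval,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> animal %s: %d scheduled fixes (%d valid, FSR %.3f), interval %d min\n",
              attr(x, "animal_id"), nrow(x), sum(x$valid), fix_success_rate(x),
              attr(x, "nominal_interval")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more fixes\n", nrow(x) - 6L))
  invisible(x)
}

#' Fix success rate
#'
#' Fraction of scheduled fix slots that yielded a location, relative to the
#' nominal grid spanning the first to last observed timestamp.
#'
#' @param traj a [trajectory()].
#' @return numeric in \[0, 1\].
#' @export
fix_success_rate <- function(traj) {
  sum(traj$valid) / nrow(traj)
}

looks_geographic <- function(x, y) {
  fx <- x[is.finite(x)]; fy <- y[is.finite(y)]
  length(fx) > 0 && length(fy) > 0 &&
    all(abs(fx) <= 360) && all(abs(fy) <= 90)
}

# Snap observed timestamps onto the nominal grid anchored at the earliest fix.
# Within `tolerance` minutes the fix is treated as on-grid; between tolerance
# and 2x tolerance it is snapped; beyond that it is excluded from the grid
# (and reported), since the collar schedule cannot be trusted for it.
snap_to_grid <- function(ts, nominal_interval, tolerance) {
  step <- nominal_interval * 60
  anchor <- ts[1L]
  k <- round((ts - anchor) / step)
  off_min <- abs(ts - (anchor + k * step)) / 60
  list(slot = k, off_min = off_min, excluded = off_min > 2 * tolerance)
}

#' Read a delimited GPS fix table into trajectories
#'
#' Reads a delimited text file of GPS fixes, validates it, and returns one
#' [trajectory()] per animal with schedule gaps filled by invalid placeholder
#' fixes on the nominal grid. Coordinates must already be projected planar
#' meters; columns that look like longitude/latitude degrees are refused
#' unless `assume_projected = TRUE`.
#'
#' Timestamps are parsed as local standard time (stored tz `"UTC"` so no
#' daylight-saving shift is ever applied). A fix whose timestamp is more than
#' `tolerance` minutes off the nominal grid is snapped if within
#' `2 * tolerance`, else flagged and excluded (reported in the
#' `excluded` attribute of the trajectory).
#'
#' @param path file path of a delimited table with a header row.
#' @param col_map named list mapping the required fields `animal_id`,
#'   `timestamp`, `x`, `y` (and optionally `valid`) to column names in the
#'   file.
#' @param sep field separator (default comma).
#' @param time_format timestamp format string, or `NULL` for ISO 8601.
#' @param nominal_interval scheduled fix interval in minutes.
#' @param tolerance off-grid tolerance in minutes (default 15).
#' @param assume_projected set `TRUE` to accept coordinates whose ranges look
#'   like geographic degrees.
#' @return list of [trajectory()] objects, one per animal.
#' @export
read_fix_table <- function(path,
                           col_map = list(animal_id = "animal_id",
                                          timestamp = "timestamp",
                                          x = "x", y = "y", valid = "valid"),
                           sep = ",",
                           time_format = NULL,
                           nominal_interval = 240,
                           tolerance = 15,
                           assume_projected = FALSE) {
  if (!file.exists(path)) stop("fix table not found: ", path)
  raw <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE),
                  error = function(e) stop("fix table is empty or unreadable: ",
                                           path, call. = FALSE))
  if (nrow(raw) == 0L) stop("fix table is empty: ", path)
  req <- c("animal_id", "timestamp", "x", "y")
  for (f in req) {
    cn <- col_map[[f]]
    if (is.null(cn) || !cn %in% names(raw))
      stop("configuration error: required column for '", f, "' not found in ", path)
  }
  d <- data.frame(animal_id = as.character(raw[[col_map$animal_id]]),
                  x = as.numeric(raw[[col_map$x]]),
                  y = as.numeric(raw[[col_map$y]]),
                  stringsAsFactors = FALSE)
  d$timestamp <- parse_time(raw[[col_map$timestamp]], time_format)
  if (anyNA(d$timestamp)) stop("unparseable timestamps in ", path)
  vcol <- col_map$valid
  if (!is.null(vcol) && vcol %in% names(raw)) {
    v <- raw[[vcol]]
    d$valid <- if (is.logical(v)) v else as.logical(as.integer(v) != 0L)
  } else {
    d$valid <- is.finite(d$x) & is.finite(d$y)
  }
  d$valid <- d$valid & is.finite(d$x) & is.finite(d$y)
  if (!assume_projected && looks_geographic(d$x, d$y))
    stop("coordinates look like longitude/latitude degrees; all metrics are ",
         "Euclidean in meters. Project the data first, or pass ",
         "assume_projected = TRUE if these really are planar meters.")
  lapply(split(d, d$animal_id), build_trajectory,
         nominal_interval = nominal_interval, tolerance = tolerance)
}

parse_time <- function(x, time_format = NULL) {
  if (inherits(x, "POSIXct")) return(x)
  if (is.null(time_format)) {
    ts <- as.POSIXct(as.character(x), tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d %H:%M", "%Y/%m/%d %H:%M:%S"))
  } else {
    ts <- as.POSIXct(as.character(x), tz = "UTC", format = time_format)
  }
  ts
}

build_trajectory <- function(d, nominal_interval, tolerance) {
  d <- d[order(as.numeric(d$timestamp)), , drop = FALSE]
  if (anyDuplicated(as.numeric(d$timestamp)))
    stop("data error: duplicate (animal, timestamp) for animal ", d$animal_id[1L])
  ts <- as.numeric(d$timestamp)
  sn <- snap_to_grid(ts, nominal_interval, tolerance)
  excluded <- d[sn$excluded, , drop = FALSE]
  keep <- !sn$excluded
  slot <- sn$slot[keep]
  if (anyDuplicated(slot))
    stop("data error: multiple fixes snap to one scheduled slot for animal ",
         d$animal_id[1L])
  d <- d[keep, , drop = FALSE]
  step <- nominal_interval * 60
  anchor <- ts[1L]
  grid_slots <- seq.int(min(slot), max(slot))
  grid <- data.frame(
    animal_id = d$animal_id[1L],
    timestamp = as.POSIXct(anchor + grid_slots * step,
                           origin = "1970-01-01", tz = "UTC"),
    x = NA_real_, y = NA_real_, valid = FALSE,
    stringsAsFactors = FALSE)
  at <- match(slot, grid_slots)
  grid$x[at] <- d$x
  grid$y[at] <- d$y
  grid$valid[at] <- d$valid
  out <- trajectory(grid, nominal_interval = nominal_interval)
  attr(out, "excluded") <- excluded
  out
}

#' Write a trajectory back to a delimited fix table
#'
#' Coordinates are written with full double precision so that a
#' write-then-read round trip reproduces timestamps, coordinates, and
#' validity exactly.
#'
#' @param traj a [trajectory()] or list of trajectories.
#' @param path output file path.
#' @export
write_fix_table <- function(traj, path) {
  if (inherits(traj, "trajectory")) traj <- list(traj)
  rows <- do.call(rbind, lapply(traj, function(tr) {
    data.frame(animal_id = tr$animal_id,
               timestamp = format(tr$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               x = ifelse(is.na(tr$x), "", sprintf("%.17g", tr$x)),
               y = ifelse(is.na(tr$y), "", sprintf("%.17g", tr$y)),
               valid = as.integer(tr$valid),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trajectory against its nominal schedule
#'
#' Report-only check of the temporal grid: runs of missed fixes, off-grid
#' timestamps, and the fix success rate. Never mutates its input.
#'
#' @param traj a [trajectory()].
#' @param tolerance off-grid tolerance in minutes.
#' @return object of class `trajectory_validation`: a list with elements
#'   `animal_id`, `n_scheduled`, `n_valid`, `fsr`, `gap_runs` (data.frame of
#'   start_seq/end_seq/length), `off_grid`, `excluded`, `issues`.
#' @export
validate_trajectory <- function(traj, tolerance = 15) {
  stopifnot(inherits(traj, "trajectory"))
  runs <- rle(!traj$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gap <- runs$values
  gap_runs <- data.frame(start_seq = starts[gap], end_seq = ends[gap],
                         length = runs$lengths[gap])
  excluded <- attr(traj, "excluded")
  n_excl <- if (is.null(excluded)) 0L else nrow(excluded)
  issues <- character(0)
  if (nrow(gap_runs)) issues <- c(issues, sprintf("%d gap run(s) totalling %d missed fixes",
                                                  nrow(gap_runs), sum(gap_runs$length)))
  if (n_excl) issues <- c(issues, sprintf("%d fix(es) excluded as off-grid beyond 2x tolerance", n_excl))
  structure(list(animal_id = attr(traj, "animal_id"),
                 n_scheduled = nrow(traj),
                 n_valid = sum(traj$valid),
                 fsr = fix_success_rate(traj),
                 gap_runs = gap_runs,
                 off_grid = excluded,
                 tolerance = tolerance,
                 issues = issues),
            class = "trajectory_validation")
}

#' @export
print.trajectory_validation <- function(x, ...) {
  cat(sprintf("Trajectory validation: animal %s\n", x$animal_id))
  cat(sprintf("  scheduled slots: %d   valid fixes: %d   FSR: %.3f\n",
              x$n_scheduled, x$n_valid, x$fsr))
  if (length(x$issues) == 0) cat("  no issues\n")
  else for (i in x$issues) cat("  - ", i, "\n", sep = "")
  invisible(x)
}

#' Read a field-verification table
#'
#' Field investigations of GPS sites label each investigated site as `cache`
#' (prey remains / scavenging evidence found) or `non_feeding`. Records are
#' linked to fixes by a `seq` column or by `timestamp`.
#'
#' @param path delimited text file with header and columns `animal_id`,
#'   `observed_class`, and either `seq` or `timestamp`.
#' @param sep field separator.
#' @param label_map optional named character vector mapping raw labels to the
#'   two canonical categories, e.g. `c(kill = "cache")`.
#' @param time_format timestamp format passed to the parser.
#' @return data.frame of class `field_verification` with columns `animal_id`,
#'   `seq` (may be NA), `timestamp` (may be NA), `observed_class`.
#' @export
read_verification_table <- function(path, sep = ",", label_map = NULL,
                                    time_format = NULL) {
  if (!file.exists(path)) stop("verification table not found: ", path)
  raw <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    out <- data.frame(animal_id = character(0), seq = integer(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      observed_class = character(0))
    class(out) <- c("field_verification", "data.frame")
    return(out)
  }
  if (!all(c("animal_id", "observed_class") %in% names(raw)))
    stop("configuration error: verification table needs animal_id and observed_class")
  lab <- as.character(raw$observed_class)
  if (!is.null(label_map)) {
    hit <- lab %in% names(label_map)
    lab[hit] <- unname(label_map[lab[hit]])
  }
  ok <- lab %in% c("cache", "non_feeding")
  if (!all(ok))
    stop("data error: unknown observed_class label(s): ",
         paste(unique(lab[!ok]), collapse = ", "))
  out <- data.frame(animal_id = as.character(raw$animal_id),
                    seq = if ("seq" %in% names(raw)) as.integer(raw$seq) else NA_integer_,
                    observed_class = lab,
                    stringsAsFactors = FALSE)
  out$timestamp <- if ("timestamp" %in% names(raw))
    parse_time(raw$timestamp, time_format)
  else as.POSIXct(rep(NA_real_, nrow(out)), origin = "1970-01-01", tz = "UTC")
  class(out) <- c("field_verification", "data.frame")
  out
}
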