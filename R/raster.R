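# Minimal single-band covariate raster on a regular grid in projected meters.
# Stored as a matrix with row 1 at the top (north), columns increasing east;
# cell centers sit at half-cell offsets from the lower-left corner origin.
# Read/written as ESRI ASCII grid, a plain-text interchange format.

#' Construct a covariate raster
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xll,yll coordinates (meters) of the lower-left corner of the grid.
#' @param cellsize cell edge length in meters (default 30).
#' @param nodata_value value encoding missing cells on disk.
#' @return object of class `ascii_grid`.
#' @export
ascii_grid <- function(values, xll = 0, yll = 0, cellsize = 30,
                       nodata_value = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  values[values == nodata_value] <- NA_real_
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata_value = nodata_value,
                 nrows = nrow(values), ncols = ncol(values)),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("<ascii_grid> %d x %d cells of %g m, lower-left (%g, %g), value range [%g, %g]\n",
              x$nrows, x$ncols, x$cellsize, x$xll, x$yll,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return an [ascii_grid()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (f in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[f]])) stop("malformed ASCII grid header: missing ", f)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else hdr$yllcenter - hdr$cellsize / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("ASCII grid data size does not match header dimensions")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  ascii_grid(m, xll = xll, yll = yll, cellsize = hdr$cellsize,
             nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid an [ascii_grid()].
#' @param path output file path.
#' @param digits significant digits for cell values.
#' @export
write_ascii_grid <- function(grid, path, digits = 6) {
  stopifnot(inherits(grid, "ascii_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata_value
  hdr <- c(sprintf("ncols %d", grid$ncols),
           sprintf("nrows %d", grid$nrows),
           sprintf("xllcorner %.6f", grid$xll),
           sprintf("yllcorner %.6f", grid$yll),
           sprintf("cellsize %.6f", grid$cellsize),
           sprintf("NODATA_value %g", grid$nodata_value))
  body <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# 0-based-style cell arithmetic, 1-based indices: row 1 at top.
grid_cell_of <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  row <- grid$nrows - floor((y - grid$yll) / grid$cellsize)
  ok <- col >= 1 & col <= grid$ncols & row >= 1 & row <= grid$nrows
  list(row = ifelse(ok, row, NA_integer_), col = ifelse(ok, col, NA_integer_))
}

grid_cell_center <- function(grid, row, col) {
  list(x = grid$xll + (col - 0.5) * grid$cellsize,
       y = grid$yll + (grid$nrows - row + 0.5) * grid$cellsize)
}

#' Raster value at a point
#'
#' @param grid an [ascii_grid()].
#' @param x,y point coordinates in meters (vectors allowed).
#' @return cell value(s); `NA` outside the grid or on nodata cells.
#' @export
grid_value_at <- function(grid, x, y) {
  cc <- grid_cell_of(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(cc$row)
  out[ok] <- grid$values[cbind(cc$row[ok], cc$col[ok])]
  out
}

#' Mean raster value over a disc
#'
#' Mean of all cells whose centers lie within `radius` of `(cx, cy)`,
#' excluding nodata cells. If no cell center falls inside the disc (radius
#' smaller than one cell), the cell containing the center point is used as
#' minimum support.
#'
#' @param grid an [ascii_grid()].
#' @param cx,cy disc center in meters.
#' @param radius disc radius in meters.
#' @return mean cell value, or `NA` if the disc misses the grid entirely.
#' @export
grid_disc_mean <- function(grid, cx, cy, radius) {
  cs <- grid$cellsize
  cols <- seq.int(max(1L, floor((cx - radius - grid$xll) / cs) + 1),
                  min(grid$ncols, floor((cx + radius - grid$xll) / cs) + 1))
  rows <- seq.int(max(1L, grid$nrows - floor((cy + radius - grid$yll) / cs)),
                  min(grid$nrows, grid$nrows - floor((cy - radius - grid$yll) / cs)))
  if (!length(cols) || !length(rows)) return(NA_real_)
  rc <- expand.grid(row = rows, col = cols)
  ctr <- grid_cell_center(grid, rc$row, rc$col)
  inside <- (ctr$x - cx)^2 + (ctr$y - cy)^2 <= radius^2
  vals <- grid$values[cbind(rc$row[inside], rc$col[inside])]
  vals <- vals[!is.na(vals)]
  if (length(vals)) return(mean(vals))
  v <- grid_value_at(grid, cx, cy)
  if (is.na(v)) NA_real_ else v
}
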