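#' In-memory single-band raster on a regular metric grid
#'
#' Minimal raster container used throughout the package. Values are stored as
#' a numeric matrix whose row index increases with y (row 1 is the bottom
#' row), so `values[i, j]` sits at the cell center
#' `(xmin + (j - 0.5) * cellsize, ymin + (i - 0.5) * cellsize)`.
#' All coordinates are meters in a projected CRS; no geographic-degree
#' arithmetic is ever performed.
#'
#' @param values numeric matrix of cell values (row 1 = southernmost row).
#' @param xmin,ymin coordinates of the grid's lower-left corner (m).
#' @param cellsize cell edge length (m).
#' @return an object of class `rz_raster`.
#' @export
rz_raster <- function(values, xmin = 0, ymin = 0, cellsize) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize,
         nrow = nrow(values), ncol = ncol(values)),
    class = "rz_raster"
  )
}

#' @export
print.rz_raster <- function(x, ...) {
  cat(sprintf("<rz_raster> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, x$ymin))
  cat(sprintf("  range: [%g, %g]\n", min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Cell-center coordinates of raster cells
#'
#' @param r an `rz_raster`.
#' @param idx optional vector of linear cell indices (column-major, as used
#'   by the underlying matrix); defaults to all cells.
#' @return two-column matrix of (x, y) cell centers in meters.
#' @export
raster_coords <- function(r, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(r$nrow * r$ncol)
  i <- ((idx - 1L) %% r$nrow) + 1L   # row
  j <- ((idx - 1L) %/% r$nrow) + 1L  # col
  cbind(x = r$xmin + (j - 0.5) * r$cellsize,
        y = r$ymin + (i - 0.5) * r$cellsize)
}

#' Linear cell index containing each point
#'
#' Points outside the grid get NA. A point exactly on an interior cell edge
#' is assigned to the cell above/right of the edge (half-open cells), so
#' every point belongs to exactly one cell.
#'
#' @param r an `rz_raster`.
#' @param x,y point coordinates (m).
#' @return integer vector of linear (column-major) cell indices.
#' @export
raster_cell_at <- function(r, x, y) {
  j <- floor((x - r$xmin) / r$cellsize) + 1
  i <- floor((y - r$ymin) / r$cellsize) + 1
  ok <- i >= 1 & i <= r$nrow & j >= 1 & j <= r$ncol
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((j[ok] - 1) * r$nrow + i[ok])
  out
}

#' Sample raster values at point locations (nearest cell)
#'
#' @inheritParams raster_cell_at
#' @return numeric vector of cell values, NA outside the grid.
#' @export
raster_sample <- function(r, x, y) {
  idx <- raster_cell_at(r, x, y)
  out <- rep(NA_real_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- r$values[idx[ok]]
  out
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS software. Rows are
#' written north to south as the format requires.
#'
#' @param r an `rz_raster`.
#' @param path file path (conventionally `.asc`).
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns an `rz_raster`.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", r$ncol),
    sprintf("NROWS %d", r$nrow),
    sprintf("XLLCORNER %.10g", r$xmin),
    sprintf("YLLCORNER %.10g", r$ymin),
    sprintf("CELLSIZE %.10g", r$cellsize),
    "NODATA_VALUE -9999"
  ), con)
  vals <- r$values
  vals[is.na(vals)] <- -9999
  for (i in rev(seq_len(r$nrow))) {
    writeLines(paste(format(vals[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), toupper(kv[, 1]))
  dat <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(h[["NROWS"]]); nc <- as.integer(h[["NCOLS"]])
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to bottom-up rows
  if ("NODATA_VALUE" %in% names(h)) m[m == h[["NODATA_VALUE"]]] <- NA
  rz_raster(m, xmin = h[["XLLCORNER"]], ymin = h[["YLLCORNER"]],
            cellsize = h[["CELLSIZE"]])
}
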