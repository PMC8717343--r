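#' Regular single-band raster surface
#'
#' `grid_surface` is the pipeline's exchange format for gridded fields: DEMs,
#' terrain derivatives, distance-to-track surfaces and probability maps. It is
#' a plain matrix plus georeferencing. Row 1 is the northmost row; the origin
#' is the outer (north-west) corner of cell (1,1); the centre of cell (i,j)
#' sits at `(origin_x + (j - 0.5) * cell, origin_y - (i - 0.5) * cell)`.
#' Missing cells are `NA`.
#'
#' @param values numeric matrix (rows north to south).
#' @param origin_x,origin_y coordinates (m) of the north-west outer corner.
#' @param cell cell size in metres (> 0).
#' @param crs_label free-text coordinate system label.
#' @return An object of class `grid_surface`.
#' @export
grid_surface <- function(values, origin_x = 0, origin_y = nrow(values) * cell,
                         cell = 1, crs_label = "local-metres") {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot_scalar(cell, "cell", positive = TRUE)
  stopifnot_scalar(origin_x, "origin_x")
  stopifnot_scalar(origin_y, "origin_y")
  structure(list(values = values, origin_x = origin_x, origin_y = origin_y,
                 cell = cell, nrows = nrow(values), ncols = ncol(values),
                 crs_label = crs_label),
            class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_surface> %d x %d cells @ %g m (%s)\n",
              x$nrows, x$ncols, x$cell, x$crs_label))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$origin_x, x$origin_x + x$ncols * x$cell,
              x$origin_y - x$nrows * x$cell, x$origin_y))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  values: min %.3f, mean %.3f, max %.3f (%d nodata)\n",
                min(v[ok]), mean(v[ok]), max(v[ok]), sum(!ok)))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param g a [grid_surface].
#' @return List with vectors `x` (length ncols) and `y` (length nrows), plus
#'   matrices `X`, `Y` of per-cell centre coordinates.
#' @export
grid_centres <- function(g) {
  x <- g$origin_x + (seq_len(g$ncols) - 0.5) * g$cell
  y <- g$origin_y - (seq_len(g$nrows) - 0.5) * g$cell
  list(x = x, y = y,
       X = matrix(x, g$nrows, g$ncols, byrow = TRUE),
       Y = matrix(y, g$nrows, g$ncols))
}

## Empty grid covering extent [0, extent_x] x [0, extent_y] at `cell`.
grid_from_extent <- function(extent_x, extent_y, cell, crs_label = "local-metres") {
  nr <- max(1L, as.integer(round(extent_y / cell)))
  nc <- max(1L, as.integer(round(extent_x / cell)))
  grid_surface(matrix(NA_real_, nr, nc), origin_x = 0, origin_y = nr * cell,
               cell = cell, crs_label = crs_label)
}

#' Bilinear sampling of a grid surface
#'
#' Samples grid values at arbitrary coordinates by bilinear interpolation
#' between the four surrounding cell centres. Coordinates outside the hull of
#' cell centres are clamped to the nearest centre row/column (flat edge
#' extension); `NA` in any contributing cell yields `NA`.
#'
#' @param g a [grid_surface].
#' @param x,y numeric vectors of coordinates (m).
#' @return Numeric vector of sampled values.
#' @export
grid_bilinear <- function(g, x, y) {
  cc <- grid_centres(g)
  ## fractional column/row position relative to first centre
  fc <- (x - cc$x[1]) / g$cell + 1
  fr <- (cc$y[1] - y) / g$cell + 1
  fc <- pmin(pmax(fc, 1), g$ncols)
  fr <- pmin(pmax(fr, 1), g$nrows)
  c0 <- pmin(floor(fc), g$ncols - 1L); c0[g$ncols == 1L] <- 1L
  r0 <- pmin(floor(fr), g$nrows - 1L); r0[g$nrows == 1L] <- 1L
  c0 <- pmax(c0, 1L); r0 <- pmax(r0, 1L)
  tx <- fc - c0
  ty <- fr - r0
  c1 <- pmin(c0 + 1L, g$ncols)
  r1 <- pmin(r0 + 1L, g$nrows)
  v <- g$values
  idx <- function(r, c) v[cbind(r, c)]
  z <- (1 - tx) * (1 - ty) * idx(r0, c0) + tx * (1 - ty) * idx(r0, c1) +
    (1 - tx) * ty * idx(r1, c0) + tx * ty * idx(r1, c1)
  z
}

## Nearest-cell (row, col) indices for coordinates; NA outside the grid extent.
grid_rowcol <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$cell) + 1L
  row <- floor((g$origin_y - y) / g$cell) + 1L
  bad <- col < 1L | col > g$ncols | row < 1L | row > g$nrows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Write a grid surface as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster with the standard six-line header; `NA` cells are
#' written as the nodata value (-9999).
#'
#' @param g a [grid_surface].
#' @param path output file path.
#' @param digits significant digits written per value.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(g, path, digits = 7) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$ncols),
               sprintf("nrows %d", g$nrows),
               sprintf("xllcorner %.6f", g$origin_x),
               sprintf("yllcorner %.6f", g$origin_y - g$nrows * g$cell),
               sprintf("cellsize %.6f", g$cell),
               "NODATA_value -9999"), con)
  v <- g$values
  v[!is.finite(v)] <- -9999
  for (i in seq_len(g$nrows))
    writeLines(paste(signif(v[i, ], digits), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path of a `.asc` raster.
#' @param crs_label coordinate system label to attach.
#' @return A [grid_surface]; nodata cells become `NA`.
#' @export
read_esri_ascii <- function(path, crs_label = "local-metres") {
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[req]])) stop("missing ESRI ASCII header field: ", req)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- lines[(n_hdr + 1L):length(lines)]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("ESRI ASCII body has wrong cell count")
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_surface(m, origin_x = hdr$xllcorner, origin_y = hdr$yllcorner + nr * hdr$cellsize,
               cell = hdr$cellsize, crs_label = crs_label)
}

#' @export
plot.grid_surface <- function(x, main = "", ...) {
  cc <- grid_centres(x)
  graphics::image(cc$x, rev(cc$y), t(x$values[x$nrows:1, , drop = FALSE]),
                  xlab = "x (m)", ylab = "y (m)", main = main, useRaster = TRUE, ...)
  invisible(x)
}
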