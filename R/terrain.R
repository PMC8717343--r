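## Shifted copies of a matrix for 3x3 focal work: di, dj in {-1, 0, 1};
## cells whose neighbour falls off the grid become NA.
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) + di
  cj <- seq_len(nc) + dj
  ok_r <- ri >= 1 & ri <= nr
  ok_c <- cj >= 1 & cj <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], cj[ok_c]]
  out
}

#' Smooth a DEM with a 5x5 Gaussian kernel
#'
#' Convolution with a normalized 5x5 Gaussian kernel (sigma = 1 cell).
#' Nodata and edges are handled by renormalizing the kernel over the valid
#' cells under it, so the filter is mean-preserving everywhere it can be
#' evaluated.
#'
#' @param dem a [grid_surface] with at least 5 rows and columns.
#' @return The smoothed [grid_surface].
#' @export
gaussian_smooth <- function(dem) {
  if (dem$nrows < 5 || dem$ncols < 5) stop("grid must be at least 5 x 5")
  off <- -2:2
  w1 <- exp(-off^2 / 2)
  kern <- outer(w1, w1)
  kern <- kern / sum(kern)
  v <- dem$values
  num <- matrix(0, dem$nrows, dem$ncols)
  den <- matrix(0, dem$nrows, dem$ncols)
  for (a in seq_along(off)) for (b in seq_along(off)) {
    sh <- shift_mat(v, off[a], off[b])
    ok <- !is.na(sh)
    num[ok] <- num[ok] + kern[a, b] * sh[ok]
    den[ok] <- den[ok] + kern[a, b]
  }
  out <- num / den
  out[is.na(v)] <- NA_real_   # nodata cells stay nodata
  grid_surface(out, origin_x = dem$origin_x, origin_y = dem$origin_y,
               cell = dem$cell, crs_label = dem$crs_label)
}

#' Resample a grid surface bilinearly
#'
#' Builds a new grid over the same extent at `new_cell` resolution and fills
#' it by cell-centre-aligned bilinear interpolation of the source. A target
#' cell is nodata when any of its four contributing source cells is nodata.
#'
#' @param surface a [grid_surface].
#' @param new_cell target cell size (m, > 0).
#' @return The resampled [grid_surface].
#' @export
resample_bilinear <- function(surface, new_cell) {
  stopifnot_scalar(new_cell, "new_cell", positive = TRUE)
  if (abs(new_cell - surface$cell) < 1e-12) return(surface)
  ex <- surface$ncols * surface$cell
  ey <- surface$nrows * surface$cell
  nr <- max(1L, as.integer(round(ey / new_cell)))
  nc <- max(1L, as.integer(round(ex / new_cell)))
  out <- grid_surface(matrix(NA_real_, nr, nc), origin_x = surface$origin_x,
                      origin_y = surface$origin_y, cell = new_cell,
                      crs_label = surface$crs_label)
  cc <- grid_centres(out)
  vals <- grid_bilinear(surface, as.vector(cc$X), as.vector(cc$Y))
  out$values <- matrix(vals, nr, nc)
  out
}

## depth grid -> elevation matrix (positive up) for gradient work
elev_of <- function(dem) -dem$values

#' Horn slope, northness and eastness
#'
#' Horn's weighted finite differences on the 3x3 neighbourhood of each cell
#' (computed on elevation = -depth): east gradient
#' `p = ((z3 + 2 z6 + z9) - (z1 + 2 z4 + z7)) / (8 g)` and the analogous
#' north gradient `q`; slope = `atan(sqrt(p^2 + q^2))` in degrees; aspect is
#' the downslope compass direction (0 = north, clockwise), reported as
#' northness `NS = cos(aspect)` and eastness `WE = sin(aspect)`. Flat cells
#' (slope 0) take NS = WE = 0; cells with incomplete neighbourhoods are
#' nodata.
#'
#' @param dem a [grid_surface] of depths (m, positive down).
#' @return List of three [grid_surface]s: `slope` (degrees), `NS`, `WE`.
#' @export
horn_slope_aspect <- function(dem) {
  e <- dem
  e$values <- elev_of(dem)
  g <- dem$cell
  ## z1 z2 z3 / z4 z5 z6 / z7 z8 z9 with z1 at the north-west corner
  z <- function(di, dj) shift_mat(e$values, di, dj)
  z1 <- z(-1, -1); z2 <- z(-1, 0); z3 <- z(-1, 1)
  z4 <- z(0, -1);                   z6 <- z(0, 1)
  z7 <- z(1, -1);  z8 <- z(1, 0);  z9 <- z(1, 1)
  p <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * g)   # d elev / d east
  q <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * g)   # d elev / d north
  slope <- atan(sqrt(p^2 + q^2)) * 180 / pi
  aspect <- (atan2(-p, -q) * 180 / pi) %% 360   # downslope bearing
  ns <- cos(aspect * pi / 180)
  we <- sin(aspect * pi / 180)
  ## numerically flat cells (slope below 1e-8 deg) are snapped to exact zero
  ## with the NS = WE = 0 convention, so round-off never manufactures aspect
  flat <- !is.na(slope) & slope <= 1e-8
  slope[flat] <- 0
  ns[flat] <- 0; we[flat] <- 0
  mk <- function(m) grid_surface(m, origin_x = dem$origin_x,
                                 origin_y = dem$origin_y, cell = dem$cell,
                                 crs_label = dem$crs_label)
  list(slope = mk(slope), NS = mk(ns), WE = mk(we))
}

#' 3x3 focal terrain-variability statistics
#'
#' Per 3x3 window: `SD` = sample (n-1) standard deviation of the nine depths;
#' `TRI` = mean absolute difference between the centre and its eight
#' neighbours; `TPI` = centre minus the mean of the eight neighbours;
#' `roughness` = window max minus min. Cells with incomplete neighbourhoods
#' are nodata.
#'
#' @param dem a [grid_surface] of depths.
#' @param metric one of `"SD"`, `"TRI"`, `"TPI"`, `"roughness"`.
#' @return A [grid_surface].
#' @export
focal_stat <- function(dem, metric = c("SD", "TRI", "TPI", "roughness")) {
  metric <- match.arg(metric)
  v <- dem$values
  offs <- expand.grid(di = -1:1, dj = -1:1)
  neigh <- offs[!(offs$di == 0 & offs$dj == 0), ]
  centre <- v
  shifts <- lapply(seq_len(nrow(neigh)),
                   function(r) shift_mat(v, neigh$di[r], neigh$dj[r]))
  nbr_sum <- Reduce(`+`, shifts)
  out <- switch(metric,
    TRI = Reduce(`+`, lapply(shifts, function(s) abs(centre - s))) / 8,
    TPI = centre - nbr_sum / 8,
    roughness = {
      mx <- Reduce(pmax, shifts, centre)
      mn <- Reduce(pmin, shifts, centre)
      mx - mn
    },
    SD = {
      ## two-pass (centred) form: the textbook sum-of-squares shortcut loses
      ## ~8 digits to cancellation at typical shelf depths
      wmean <- (nbr_sum + centre) / 9
      ss <- Reduce(`+`, lapply(shifts, function(s) (s - wmean)^2)) +
        (centre - wmean)^2
      sqrt(ss / 8)
    })
  grid_surface(out, origin_x = dem$origin_x, origin_y = dem$origin_y,
               cell = dem$cell, crs_label = dem$crs_label)
}

#' Mean curvature from a local quadratic fit
#'
#' Fits `z = a x^2 + b y^2 + c xy + d x + e y + f` to each 3x3 window of the
#' elevation surface (elevation = -depth, local metric coordinates, centre at
#' the origin) by least squares and returns `MNC = -(a + b)` in 1/m, so
#' depressions (concave terrain) come out negative and domes positive.
#'
#' @param dem a [grid_surface] of depths.
#' @return A [grid_surface] of mean curvature.
#' @export
mean_curvature <- function(dem) {
  g <- dem$cell
  xs <- rep(c(-g, 0, g), times = 3)   # column offset (east)
  ys <- rep(c(g, 0, -g), each = 3)    # row offset: first row is north
  X <- cbind(xs^2, ys^2, xs * ys, xs, ys, 1)
  W <- solve(crossprod(X), t(X))      # 6 x 9 least-squares weights
  e <- elev_of(dem)
  acc_a <- matrix(0, nrow(e), ncol(e))
  acc_b <- matrix(0, nrow(e), ncol(e))
  valid <- matrix(TRUE, nrow(e), ncol(e))
  p <- 0L
  for (di in -1:1) for (dj in -1:1) {
    p <- p + 1L
    ## window cell at row offset di, column offset dj; xs/ys above are laid
    ## out row-major north to south, so p indexes (di, dj) in the same order
    sh <- shift_mat(e, di, dj)
    valid <- valid & !is.na(sh)
    sh[is.na(sh)] <- 0
    acc_a <- acc_a + W[1, p] * sh
    acc_b <- acc_b + W[2, p] * sh
  }
  out <- -(acc_a + acc_b)
  out[!valid] <- NA_real_
  grid_surface(out, origin_x = dem$origin_x, origin_y = dem$origin_y,
               cell = dem$cell, crs_label = dem$crs_label)
}

#' Build a multi-resolution terrain stack
#'
#' Smooths the DEM once at native resolution (5x5 Gaussian), resamples
#' bilinearly to each target resolution, and computes the eight derivatives
#' (slope, NS, WE, SD, TRI, TPI, roughness, MNC) per resolution. Depth enters
#' once, at native resolution. Layers are named `{var}_{res}` with `res` in
#' metres (the depth layer is just `depth`).
#'
#' @param dem a [grid_surface] of depths.
#' @param resolutions target cell sizes (m), each >= the native cell.
#' @param source_label provenance label (e.g. `"reference"` or `"uk1"`).
#' @return An object of class `terrain_stack`: list with `layers` (named
#'   list of [grid_surface]), `resolutions`, `source_label`, `native_cell`.
#' @export
build_stack <- function(dem, resolutions = dem$cell * c(1, 3, 5, 8),
                        source_label = "dem") {
  if (any(resolutions < dem$cell - 1e-9))
    stop("resolutions must be >= the native cell size")
  sm <- gaussian_smooth(dem)
  layers <- list(depth = sm)
  for (res in resolutions) {
    d <- resample_bilinear(sm, res)
    hs <- horn_slope_aspect(d)
    res_lab <- format(res, trim = TRUE)
    layers[[paste0("slope_", res_lab)]] <- hs$slope
    layers[[paste0("NS_", res_lab)]] <- hs$NS
    layers[[paste0("WE_", res_lab)]] <- hs$WE
    layers[[paste0("SD_", res_lab)]] <- focal_stat(d, "SD")
    layers[[paste0("TRI_", res_lab)]] <- focal_stat(d, "TRI")
    layers[[paste0("TPI_", res_lab)]] <- focal_stat(d, "TPI")
    layers[[paste0("roughness_", res_lab)]] <- focal_stat(d, "roughness")
    layers[[paste0("MNC_", res_lab)]] <- mean_curvature(d)
  }
  structure(list(layers = layers, resolutions = resolutions,
                 source_label = source_label, native_cell = dem$cell),
            class = "terrain_stack")
}

#' @export
print.terrain_stack <- function(x, ...) {
  cat(sprintf("<terrain_stack> '%s': %d layers at resolutions {%s} m (native %g m)\n",
              x$source_label, length(x$layers),
              paste(x$resolutions, collapse = ", "), x$native_cell))
  invisible(x)
}

#' Write a terrain stack to a directory of ESRI ASCII grids
#'
#' One `.asc` file per layer under `dir/{source_label}/`, plus a JSON
#' manifest listing layers, resolutions and files.
#'
#' @param stack a [terrain_stack].
#' @param dir output directory.
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  sub <- file.path(dir, stack$source_label)
  dir.create(sub, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(stack$layers)) {
    f <- file.path(sub, paste0(nm, ".asc"))
    write_esri_ascii(stack$layers[[nm]], f)
    files[nm] <- f
  }
  manifest <- file.path(sub, "stack.json")
  jsonlite::write_json(list(source = stack$source_label,
                            native_cell = stack$native_cell,
                            resolutions = stack$resolutions,
                            layers = as.list(files)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
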