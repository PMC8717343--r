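#' Distance from grid cells to the nearest survey track
#'
#' Euclidean distance (m) from every cell centre to the nearest track
#' polyline segment.
#'
#' @param grid a [grid_surface] template defining the geometry.
#' @param tracks list of n x 2 polyline coordinate matrices (>= 1).
#' @return A [grid_surface] of distances.
#' @export
distance_to_track <- function(grid, tracks) {
  if (!length(tracks)) stop("need at least one track line")
  cc <- grid_centres(grid)
  qx <- as.vector(cc$X); qy <- as.vector(cc$Y)
  dmin <- rep(Inf, length(qx))
  for (line in tracks) {
    line <- as.matrix(line)
    for (s in seq_len(nrow(line) - 1L)) {
      ax <- line[s, 1]; ay <- line[s, 2]
      bx <- line[s + 1L, 1]; by <- line[s + 1L, 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      t <- if (L2 == 0) rep(0, length(qx))
           else pmin(pmax(((qx - ax) * vx + (qy - ay) * vy) / L2, 0), 1)
      d <- sqrt((qx - (ax + t * vx))^2 + (qy - (ay + t * vy))^2)
      dmin <- pmin(dmin, d)
    }
  }
  grid_surface(matrix(dmin, grid$nrows, grid$ncols), origin_x = grid$origin_x,
               origin_y = grid$origin_y, cell = grid$cell,
               crs_label = grid$crs_label)
}

## default distance bands: half-open (lower, upper] intervals
default_bands <- function() list(c(0, 100), c(100, 200), c(200, 300), c(300, 400))

#' Compare predicted and reference surfaces within distance bands
#'
#' For each half-open distance band `(lower, upper]` from the survey tracks,
#' pairs the jointly valid pixels of the predicted and reference surfaces and
#' reports Pearson r (with two-sided t-test p-value) and the OLS regression
#' of reference on predicted (slope, intercept, R^2). Bands with fewer than
#' 3 valid pixels are reported with `NA` statistics.
#'
#' @param pred,ref co-registered [grid_surface]s (same geometry).
#' @param dist a [grid_surface] of distances to the tracks (same geometry).
#' @param bands list of `c(lower, upper)` band limits in metres.
#' @return data.frame with one row per band: `lower`, `upper`, `n_pixels`,
#'   `pearson_r`, `r_p_value`, `r2`, `ols_slope`, `ols_intercept`.
#' @export
band_compare <- function(pred, ref, dist, bands = default_bands()) {
  check_coregistered(pred, ref); check_coregistered(pred, dist)
  p <- as.vector(pred$values); r <- as.vector(ref$values)
  d <- as.vector(dist$values)
  rows <- lapply(bands, function(b) {
    sel <- is.finite(p) & is.finite(r) & is.finite(d) & d > b[1] & d <= b[2]
    n <- sum(sel)
    if (n < 3)
      return(data.frame(lower = b[1], upper = b[2], n_pixels = n,
                        pearson_r = NA_real_, r_p_value = NA_real_,
                        r2 = NA_real_, ols_slope = NA_real_,
                        ols_intercept = NA_real_))
    ct <- stats::cor.test(p[sel], r[sel])
    fit <- stats::lm.fit(cbind(1, p[sel]), r[sel])
    ssr <- sum(fit$residuals^2)
    sst <- sum((r[sel] - mean(r[sel]))^2)
    data.frame(lower = b[1], upper = b[2], n_pixels = n,
               pearson_r = unname(ct$estimate), r_p_value = ct$p.value,
               r2 = if (sst > 0) 1 - ssr / sst else NA_real_,
               ols_slope = fit$coefficients[2], ols_intercept = fit$coefficients[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-surface agreement statistics
#'
#' Paired statistics over the jointly valid cells of two co-registered
#' surfaces: Pearson r, R^2 of the reference-on-predicted OLS fit, RMSE and
#' bias (mean predicted - reference).
#'
#' @param pred,ref co-registered [grid_surface]s.
#' @return list with `r`, `r2`, `rmse`, `bias`, `n`.
#' @export
surface_compare <- function(pred, ref) {
  check_coregistered(pred, ref)
  p <- as.vector(pred$values); r <- as.vector(ref$values)
  sel <- is.finite(p) & is.finite(r)
  if (!any(sel)) stop("surfaces share no valid cells")
  p <- p[sel]; r <- r[sel]
  rr <- if (stats::sd(p) > 0 && stats::sd(r) > 0) stats::cor(p, r) else NA_real_
  fit <- stats::lm.fit(cbind(1, p), r)
  sst <- sum((r - mean(r))^2)
  list(r = rr,
       r2 = if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_,
       rmse = sqrt(mean((p - r)^2)), bias = mean(p - r), n = length(p))
}

check_coregistered <- function(a, b) {
  if (a$nrows != b$nrows || a$ncols != b$ncols ||
      abs(a$cell - b$cell) > 1e-9 ||
      abs(a$origin_x - b$origin_x) > 1e-6 || abs(a$origin_y - b$origin_y) > 1e-6)
    stop("grids are not co-registered")
  invisible(TRUE)
}
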