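#' Interpolator configuration
#'
#' Bundles an interpolation method and its parameters. Methods: `"idw"`
#' (inverse distance weighting, power `p`), `"rbf_crs"` / `"rbf_m"` (local
#' radial basis functions with completely-regularized-spline or multiquadric
#' basis, shape `delta` and a diagonal-ridge `robustness`), `"ok"`, `"uk1"`,
#' `"uk2"` (ordinary / universal kriging with first- or second-degree local
#' trend; requires a fitted [variogram_model]).
#'
#' @param method one of `"idw"`, `"rbf_crs"`, `"rbf_m"`, `"ok"`, `"uk1"`, `"uk2"`.
#' @param power IDW power (> 0).
#' @param n_neighbors local neighbourhood size.
#' @param delta RBF shape/smoothing parameter (> 0).
#' @param robustness RBF ridge added to the system diagonal (>= 0).
#' @param variogram a [variogram_model] (kriging methods).
#' @return An object of class `interp_config`.
#' @export
interp_config <- function(method, power = 2, n_neighbors = 50, delta = 1,
                          robustness = 0, variogram = NULL) {
  method <- match.arg(method, c("idw", "rbf_crs", "rbf_m", "ok", "uk1", "uk2"))
  trend_degree <- switch(method, ok = 0L, uk1 = 1L, uk2 = 2L, NULL)
  if (method == "idw" && power <= 0) stop("IDW 'power' must be > 0")
  if (n_neighbors < 1) stop("'n_neighbors' must be >= 1")
  if (method %in% c("ok", "uk1", "uk2")) {
    if (is.null(variogram)) stop("kriging requires a fitted 'variogram'")
    if (n_neighbors < trend_basis_size(trend_degree) + 2)
      stop("kriging 'n_neighbors' must be >= trend basis size + 2")
  }
  structure(list(method = method, power = power,
                 n_neighbors = as.integer(n_neighbors), delta = delta,
                 robustness = robustness, variogram = variogram,
                 trend_degree = trend_degree),
            class = "interp_config")
}

#' @export
print.interp_config <- function(x, ...) {
  extra <- switch(x$method,
                  idw = sprintf("power %g", x$power),
                  rbf_crs = , rbf_m = sprintf("delta %g, robustness %g", x$delta, x$robustness),
                  sprintf("trend degree %d", x$trend_degree))
  cat(sprintf("<interp_config> %s (%s), %d neighbours\n", x$method, extra,
              x$n_neighbors))
  invisible(x)
}

config_label <- function(cfg) {
  switch(cfg$method,
         idw = sprintf("idw(p=%g,k=%d)", cfg$power, cfg$n_neighbors),
         rbf_crs = sprintf("rbf_crs(d=%g,r=%g,k=%d)", cfg$delta, cfg$robustness, cfg$n_neighbors),
         rbf_m = sprintf("rbf_m(d=%g,r=%g,k=%d)", cfg$delta, cfg$robustness, cfg$n_neighbors),
         sprintf("%s(k=%d%s)", cfg$method, cfg$n_neighbors,
                 if (cfg$variogram$anisotropy_ratio < 1) ",aniso" else ""))
}

trend_basis_size <- function(degree) c(1L, 3L, 6L)[degree + 1L]

## Monomial trend basis on centred/scaled coordinates.
trend_basis <- function(x, y, degree) {
  switch(degree + 1L,
         cbind(rep(1, length(x))),
         cbind(1, x, y),
         cbind(1, x, y, x^2, y^2, x * y))
}

## ---- point-wise prediction engines ------------------------------------

idw_points <- function(px, py, z, qx, qy, power, k, eps = 1e-9) {
  nn <- nearest_k(qx, qy, px, py, k)
  out <- numeric(length(qx))
  for (q in seq_along(qx)) {
    idx <- nn[q, ]
    d <- sqrt((px[idx] - qx[q])^2 + (py[idx] - qy[q])^2)
    hit <- which(d < eps)
    if (length(hit)) { out[q] <- z[idx[hit[1L]]]; next }
    w <- d^(-power)
    out[q] <- sum(w * z[idx]) / sum(w)
  }
  out
}

rbf_phi <- function(r, basis, delta) {
  ## multiquadric taken negative so the basis is conditionally positive
  ## definite under the linear side conditions (predictions are identical for
  ## an exact interpolant; the sign matters so the smoothing ridge added to
  ## the diagonal regularizes rather than destabilizes the system)
  if (basis == "m") return(-sqrt(r^2 + delta^2))
  ## completely regularized spline (spline-with-tension series):
  ## phi(r) = -(log(x) + E1(x) + Euler gamma), x = (delta r / 2)^2; phi(0) = 0
  x <- (delta * r / 2)^2
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    e1 <- Re(pracma::expint_E1(x[pos]))
    out[pos] <- -(log(x[pos]) + e1 + 0.57721566490153286)
  }
  dim(out) <- dim(r)
  out
}

rbf_points <- function(px, py, z, qx, qy, basis, delta, robustness, k) {
  k <- min(k, length(px))
  if (k < 3) stop("RBF needs a local neighbourhood of >= 3 points")
  nn <- nearest_k(qx, qy, px, py, k)
  out <- rep(NA_real_, length(qx))
  for (q in seq_along(qx)) {
    idx <- nn[q, ]
    lx <- px[idx] - qx[q]; ly <- py[idx] - qy[q]
    sc <- max(sqrt(lx^2 + ly^2), 1e-9)
    D <- sqrt(outer(lx, lx, "-")^2 + outer(ly, ly, "-")^2)
    A <- rbf_phi(D, basis, delta)
    ## dimensionless ridge: scaled by the magnitude of the basis values so a
    ## given robustness means the same amount of smoothing at any site scale
    diag(A) <- diag(A) + robustness * mean(abs(A))
    P <- cbind(1, lx / sc, ly / sc)
    m <- ncol(P)
    M <- rbind(cbind(A, P), cbind(t(P), matrix(0, m, m)))
    rhs <- c(z[idx], rep(0, m))
    sol <- solve_safe(M, rhs)
    if (any(!is.finite(sol$x))) next
    lam <- sol$x[seq_len(k)]; b <- sol$x[k + seq_len(m)]
    d0 <- sqrt(lx^2 + ly^2)
    out[q] <- sum(lam * rbf_phi(d0, basis, delta)) + b[1L]
  }
  out
}

krige_points <- function(px, py, z, qx, qy, vm, degree, k, jitter = 1e-10,
                         want_se = TRUE) {
  k <- min(k, length(px))
  m <- trend_basis_size(degree)
  if (k < m + 2) stop("kriging neighbourhood too small for the trend basis")
  nn <- nearest_k(qx, qy, px, py, k)
  pred <- rep(NA_real_, length(qx))
  se <- rep(NA_real_, length(qx))
  for (q in seq_along(qx)) {
    idx <- nn[q, ]
    lx <- px[idx] - qx[q]; ly <- py[idx] - qy[q]
    sc <- max(sqrt(lx^2 + ly^2), 1e-9)
    G <- vgm_gamma_pairs(vm, outer(lx, lx, "-"), outer(ly, ly, "-"))
    diag(G) <- diag(G) + jitter
    FF <- trend_basis(lx / sc, ly / sc, degree)
    M <- rbind(cbind(G, FF), cbind(t(FF), matrix(0, m, m)))
    g0 <- vgm_gamma_pairs(vm, lx, ly)
    f0 <- drop(trend_basis(0, 0, degree))
    sol <- solve_safe(M, c(g0, f0))
    lam <- sol$x[seq_len(k)]; mu <- sol$x[k + seq_len(m)]
    if (any(!is.finite(lam))) next
    pred[q] <- sum(lam * z[idx])
    if (want_se) se[q] <- sqrt(max(sum(lam * g0) + sum(mu * f0), 0))
  }
  list(pred = pred, se = se)
}

## Dispatch: predict at arbitrary points with a configuration.
interp_points <- function(cfg, s, qx, qy) {
  px <- s$x; py <- s$y; z <- s$depth
  switch(cfg$method,
         idw = list(pred = idw_points(px, py, z, qx, qy, cfg$power, cfg$n_neighbors),
                    se = NULL),
         rbf_crs = list(pred = rbf_points(px, py, z, qx, qy, "crs", cfg$delta,
                                          cfg$robustness, cfg$n_neighbors), se = NULL),
         rbf_m = list(pred = rbf_points(px, py, z, qx, qy, "m", cfg$delta,
                                        cfg$robustness, cfg$n_neighbors), se = NULL),
         krige_points(px, py, z, qx, qy, cfg$variogram, cfg$trend_degree,
                      cfg$n_neighbors))
}

## ---- grid-facing wrappers ----------------------------------------------

#' Interpolate soundings onto a grid
#'
#' Predicts depth at every cell centre of the template grid with the given
#' configuration. Kriging additionally returns the kriging standard error
#' surface.
#'
#' @param s a [sounding_set].
#' @param grid a [grid_surface] template defining the output geometry
#'   (its values are ignored).
#' @param cfg an [interp_config].
#' @return For IDW/RBF a [grid_surface]; for kriging a list with elements
#'   `prediction` and `se`, both [grid_surface]s.
#' @export
interpolate_grid <- function(s, grid, cfg) {
  cc <- grid_centres(grid)
  qx <- as.vector(cc$X); qy <- as.vector(cc$Y)
  res <- interp_points(cfg, s, qx, qy)
  mk <- function(v) grid_surface(matrix(v, grid$nrows, grid$ncols),
                                 origin_x = grid$origin_x, origin_y = grid$origin_y,
                                 cell = grid$cell, crs_label = grid$crs_label)
  if (is.null(res$se)) return(mk(res$pred))
  list(prediction = mk(res$pred), se = mk(res$se))
}

#' @rdname interpolate_grid
#' @param power IDW power.
#' @param n_neighbors neighbourhood size.
#' @export
idw_predict <- function(s, grid, power = 2, n_neighbors = 50) {
  interpolate_grid(s, grid, interp_config("idw", power = power,
                                          n_neighbors = n_neighbors))
}

#' @rdname interpolate_grid
#' @param basis `"crs"` or `"m"` (multiquadric).
#' @param delta RBF shape parameter.
#' @param robustness diagonal ridge.
#' @export
rbf_predict <- function(s, grid, basis = c("crs", "m"), delta = 1,
                        robustness = 0, n_neighbors = 50) {
  basis <- match.arg(basis)
  interpolate_grid(s, grid, interp_config(paste0("rbf_", basis), delta = delta,
                                          robustness = robustness,
                                          n_neighbors = n_neighbors))
}

#' @rdname interpolate_grid
#' @param vm a fitted [variogram_model].
#' @param trend_degree 0 (ordinary), 1 or 2 (universal kriging).
#' @export
krige_predict <- function(s, grid, vm, trend_degree = 0, n_neighbors = 100) {
  method <- c("ok", "uk1", "uk2")[trend_degree + 1L]
  interpolate_grid(s, grid, interp_config(method, n_neighbors = n_neighbors,
                                          variogram = vm))
}

## ---- cross-validation ----------------------------------------------------

#' Leave-one-out cross-validation of an interpolator
#'
#' Predicts every sounding from all others under the configuration (the
#' variogram, where present, is fitted once beforehand and reused across
#' folds) and reports the residuals, RMSE and — for kriging — the average
#' kriging standard error (ASE) at the held-out points. The selection score
#' is the family's model-choice criterion: RMSE for IDW and RBF,
#' |ASE - RMSE| for kriging.
#'
#' @param s a [sounding_set] with >= 10 records.
#' @param cfg an [interp_config].
#' @return An object of class `cv_report` with fields `config`, `label`,
#'   `residuals` (predicted - observed, m), `rmse`, `ase` (kriging only),
#'   `selection_score`, `n`.
#' @export
loocv <- function(s, cfg) {
  n <- nrow(s)
  if (n < 10) stop("LOOCV needs >= 10 points")
  px <- s$x; py <- s$y; z <- s$depth
  k <- min(cfg$n_neighbors, n - 1L)
  ## (k+1)-NN in the full set: self is always the zero-distance neighbour
  nn <- nearest_k(px, py, px, py, k + 1L)
  pred <- rep(NA_real_, n)
  ses <- rep(NA_real_, n)
  kriging <- cfg$method %in% c("ok", "uk1", "uk2")
  for (i in seq_len(n)) {
    idx <- setdiff(nn[i, ], i)[seq_len(k)]
    sub <- list(x = px[idx], y = py[idx], depth = z[idx])
    cfg_i <- cfg
    cfg_i$n_neighbors <- k
    res <- interp_points(cfg_i, sub, px[i], py[i])
    pred[i] <- res$pred
    if (kriging) ses[i] <- res$se
  }
  resid <- pred - z
  rmse <- sqrt(mean(resid^2, na.rm = TRUE))
  ase <- if (kriging) mean(ses, na.rm = TRUE) else NULL
  score <- if (kriging) abs(ase - rmse) else rmse
  structure(list(config = cfg, label = config_label(cfg), residuals = resid,
                 rmse = rmse, ase = ase, selection_score = score, n = n),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: n %d, RMSE %.4f m", x$label, x$n, x$rmse))
  if (!is.null(x$ase))
    cat(sprintf(", ASE %.4f m, |ASE-RMSE| %.4f", x$ase, x$selection_score))
  cat("\n")
  invisible(x)
}

#' Optimize RBF shape and robustness by LOOCV RMSE
#'
#' Grid search over `(delta, robustness)` candidates minimizing leave-one-out
#' RMSE; on large sounding sets the search runs on a deterministic random
#' subsample for speed (subsample seed recorded in the result). Ties resolve
#' to the smallest delta, then the smallest robustness.
#'
#' @param s a [sounding_set].
#' @param basis `"crs"` or `"m"`.
#' @param n_neighbors neighbourhood size.
#' @param delta_grid,robustness_grid candidate values (non-empty).
#' @param max_points LOOCV subsample cap.
#' @param seed subsample seed.
#' @return The winning [interp_config], with the search table in attribute
#'   `"search"` and the subsample seed in `"subsample_seed"`.
#' @export
optimize_rbf <- function(s, basis = c("crs", "m"), n_neighbors = 50,
                         delta_grid, robustness_grid = c(0, 0.1, 1),
                         max_points = 2000L, seed = 42L) {
  basis <- match.arg(basis)
  if (!length(delta_grid) || !length(robustness_grid))
    stop("parameter grids must be non-empty")
  sub <- s
  if (nrow(s) > max_points) {
    idx <- with_seed(seed, sort(sample.int(nrow(s), max_points)))
    sub <- ss_update(as.data.frame(s)[idx, , drop = FALSE], s,
                     sprintf("loocv_subsample(n=%d, seed=%d)", max_points, seed))
  }
  grid <- expand.grid(delta = sort(delta_grid),
                      robustness = sort(robustness_grid))
  grid$rmse <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cfg <- interp_config(paste0("rbf_", basis), delta = grid$delta[r],
                         robustness = grid$robustness[r],
                         n_neighbors = n_neighbors)
    grid$rmse[r] <- loocv(sub, cfg)$rmse
  }
  ord <- order(grid$rmse, grid$delta, grid$robustness)
  best <- grid[ord[1L], ]
  out <- interp_config(paste0("rbf_", basis), delta = best$delta,
                       robustness = best$robustness, n_neighbors = n_neighbors)
  attr(out, "search") <- grid
  attr(out, "subsample_seed") <- seed
  out
}

#' Rank cross-validation reports and pick the best interpolator
#'
#' Within each method family (IDW, RBF, kriging) configurations are ranked by
#' the family's selection score (RMSE for IDW/RBF, |ASE - RMSE| for kriging)
#' ascending; across families the overall winner is the configuration with
#' the lowest RMSE.
#'
#' @param reports list of [loocv] `cv_report`s (>= 1).
#' @return An object of class `interp_selection`: a data.frame `table` (one
#'   row per report with family rank), `best_per_family` (list of reports),
#'   and `best` (overall-winner report).
#' @export
select_best <- function(reports) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  if (!length(reports)) stop("no cross-validation reports supplied")
  fam <- vapply(reports, function(r)
    switch(r$config$method, idw = "idw", rbf_crs = , rbf_m = "rbf", "kriging"),
    character(1))
  tab <- data.frame(label = vapply(reports, `[[`, character(1), "label"),
                    family = fam,
                    method = vapply(reports, function(r) r$config$method, character(1)),
                    rmse = vapply(reports, `[[`, numeric(1), "rmse"),
                    ase = vapply(reports, function(r)
                      if (is.null(r$ase)) NA_real_ else r$ase, numeric(1)),
                    selection_score = vapply(reports, `[[`, numeric(1),
                                             "selection_score"))
  tab$family_rank <- stats::ave(tab$selection_score, tab$family,
                                FUN = function(v) rank(v, ties.method = "first"))
  best_per_family <- lapply(split(seq_len(nrow(tab)), tab$family), function(ix)
    reports[[ix[which.min(tab$selection_score[ix])]]])
  best_candidates <- vapply(best_per_family, `[[`, numeric(1), "rmse")
  best <- best_per_family[[which.min(best_candidates)]]
  structure(list(table = tab[order(tab$family, tab$family_rank), ],
                 best_per_family = best_per_family, best = best),
            class = "interp_selection")
}

#' @export
print.interp_selection <- function(x, ...) {
  cat("<interp_selection>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("overall best (lowest RMSE): %s (RMSE %.4f m)\n",
              x$best$label, x$best$rmse))
  invisible(x)
}
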