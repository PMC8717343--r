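#' Empirical semivariogram of a sounding set
#'
#' Computes the classical Matheron estimator
#' `gamma(h) = sum((z_i - z_j)^2) / (2 N(h))` over point pairs binned by
#' separation distance, omnidirectionally and (optionally) by direction.
#' Directions are compass bearings of the pair separation vector folded to
#' `[0, 180)`; a pair enters a directional variogram when its bearing is
#' within `tolerance` of the direction.
#'
#' @param s a [sounding_set] (or data.frame with `x`, `y`, `depth`).
#' @param lag_width lag bin width (m).
#' @param max_lag maximum separation considered (m).
#' @param directions numeric vector of compass directions (degrees from
#'   north) for directional variograms, or NULL for omnidirectional only.
#' @param tolerance angular tolerance (degrees) for directional binning.
#' @param max_pairs cap on the number of pairs used (random subsample, seeded
#'   deterministically) to bound memory/time on large sets.
#' @param detrend_degree 0 (none), 1 or 2: compute the variogram of the
#'   residuals of a global polynomial trend of that degree in (x, y). The
#'   residual variogram is the standard input for universal kriging, where
#'   the trend is carried by the kriging system rather than the variogram.
#' @return A list of `variogram_empirical` objects (omnidirectional first),
#'   each with a data.frame `bins` of `lag_centre`, `semivariance`,
#'   `pair_count`, and fields `direction`, `tolerance`.
#' @export
empirical_variogram <- function(s, lag_width = 50, max_lag = 1500,
                                directions = NULL, tolerance = 22.5,
                                max_pairs = 2e6, detrend_degree = 0) {
  stopifnot_scalar(lag_width, "lag_width", positive = TRUE)
  stopifnot_scalar(max_lag, "max_lag", positive = TRUE)
  n <- nrow(s)
  if (n < 30 && n != 2) stop("need >= 30 points for a variogram")
  s <- as.data.frame(s)[c("x", "y", "depth")]
  if (detrend_degree > 0) {
    ## residuals of a global polynomial trend (centred/scaled coordinates)
    std <- function(v) (v - mean(v)) / max(stats::sd(v), 1e-12)
    X <- trend_basis(std(s$x), std(s$y), as.integer(detrend_degree))
    s$depth <- stats::lm.fit(X, s$depth)$residuals
  }
  npairs <- n * (n - 1) / 2
  if (npairs <= max_pairs) {
    i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
    j <- sequence(rev(seq_len(n - 1L)), from = 2:n)
  } else {
    ## too many pairs to enumerate: random pair subsample (deterministic)
    m <- as.integer(max_pairs)
    ij <- with_seed(20543L, cbind(sample.int(n, m, replace = TRUE),
                                  sample.int(n, m, replace = TRUE)))
    keep <- ij[, 1] != ij[, 2]
    i <- ij[keep, 1]; j <- ij[keep, 2]
  }
  dx <- s$x[j] - s$x[i]
  dy <- s$y[j] - s$y[i]
  h <- sqrt(dx^2 + dy^2)
  ok <- h > 0 & h <= max_lag
  dx <- dx[ok]; dy <- dy[ok]; h <- h[ok]
  sq <- (s$depth[j][ok] - s$depth[i][ok])^2
  bearing <- (atan2(dx, dy) * 180 / pi) %% 180
  bin <- pmin(floor(h / lag_width), ceiling(max_lag / lag_width) - 1L)
  one <- function(sel, direction) {
    if (!any(sel)) return(NULL)
    b <- bin[sel]
    cnt <- tapply(rep(1, sum(sel)), b, sum)
    ssum <- tapply(sq[sel], b, sum)
    lev <- as.integer(names(cnt))
    bins <- data.frame(lag_centre = (lev + 0.5) * lag_width,
                       semivariance = as.numeric(ssum) / (2 * as.numeric(cnt)),
                       pair_count = as.integer(cnt))
    bins <- bins[order(bins$lag_centre), , drop = FALSE]
    rownames(bins) <- NULL
    structure(list(bins = bins, direction = direction, tolerance = tolerance),
              class = "variogram_empirical")
  }
  out <- list(one(rep(TRUE, length(h)), "omnidirectional"))
  for (d in directions) {
    dd <- d %% 180
    ang <- pmin(abs(bearing - dd), 180 - abs(bearing - dd))
    ve <- one(ang <= tolerance, dd)
    if (is.null(ve)) warning(sprintf("no pairs in direction %g; dropped", dd))
    else out <- c(out, list(ve))
  }
  out
}

#' @export
print.variogram_empirical <- function(x, ...) {
  cat(sprintf("<variogram_empirical> %s (tol %g deg), %d bins, %d pairs\n",
              x$direction, x$tolerance, nrow(x$bins), sum(x$bins$pair_count)))
  invisible(x)
}

#' Gaussian variogram model
#'
#' Semivariance model `gamma(h) = c0 + c * (1 - exp(-3 (h/a)^2))` with
#' effective range `a` (the distance at which gamma reaches 95% of the total
#' sill), optionally with geometric anisotropy: lag vectors are rotated into
#' the (major, minor) axes and the minor component stretched by
#' `1/anisotropy_ratio` before evaluating the isotropic model, so the range
#' along the major axis is `a` and along the minor axis `a * ratio`.
#'
#' @param nugget nugget variance c0 (m^2, >= 0).
#' @param partial_sill partial sill c (m^2, >= 0).
#' @param range_eff effective range a (m, > 0) along the major axis.
#' @param anisotropy_angle degrees from north of the major axis.
#' @param anisotropy_ratio minor/major range ratio in (0, 1].
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(nugget, partial_sill, range_eff,
                            anisotropy_angle = 0, anisotropy_ratio = 1) {
  if (nugget < 0 || partial_sill < 0) stop("variances must be >= 0")
  stopifnot_scalar(range_eff, "range_eff", positive = TRUE)
  if (anisotropy_ratio <= 0 || anisotropy_ratio > 1)
    stop("'anisotropy_ratio' must be in (0, 1]")
  structure(list(model = "gaussian", nugget = nugget,
                 partial_sill = partial_sill, range_eff = range_eff,
                 anisotropy_angle = anisotropy_angle %% 180,
                 anisotropy_ratio = anisotropy_ratio),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> gaussian: nugget %.4g, partial sill %.4g m^2, effective range %.4g m\n",
              x$nugget, x$partial_sill, x$range_eff))
  if (x$anisotropy_ratio < 1)
    cat(sprintf("  anisotropy: major axis %g deg from north, ratio %.3g\n",
                x$anisotropy_angle, x$anisotropy_ratio))
  invisible(x)
}

#' Evaluate a variogram model at lag distances
#'
#' Returns `c0 + c * (1 - exp(-3 (h/a)^2))` (the continuous-from-above form,
#' equal to the nugget at h = 0). Supply `dx`, `dy` instead of `h` to apply
#' the model's geometric anisotropy.
#'
#' @param object a [variogram_model].
#' @param h lag distances (m), or NULL when `dx`/`dy` are given.
#' @param dx,dy lag vector components (m), used with anisotropy.
#' @param ... unused.
#' @return Numeric vector of semivariances (m^2).
#' @export
predict.variogram_model <- function(object, h = NULL, dx = NULL, dy = NULL, ...) {
  if (is.null(h)) {
    h <- aniso_lag(dx, dy, object$anisotropy_angle, object$anisotropy_ratio)
  }
  object$nugget + object$partial_sill * (1 - exp(-3 * (h / object$range_eff)^2))
}

## Semivariance used inside kriging systems: gamma(0) = 0 exactly (no nugget
## discontinuity on the diagonal), gamma(h>0) from the fitted model.
vgm_gamma_pairs <- function(vm, dx, dy) {
  h <- aniso_lag(dx, dy, vm$anisotropy_angle, vm$anisotropy_ratio)
  g <- vm$nugget + vm$partial_sill * (1 - exp(-3 * (h / vm$range_eff)^2))
  g[h <= 0] <- 0
  g
}

## WLS fit of the isotropic Gaussian model to one empirical variogram using
## Cressie weights N(h)/gamma_model(h)^2. Returns list(c0, c, a, objective).
fit_gaussian_wls <- function(bins) {
  h <- bins$lag_centre; gh <- bins$semivariance; N <- bins$pair_count
  total <- stats::quantile(gh, 0.9, names = FALSE)
  c0_0 <- max(min(gh), 1e-8)
  c_0 <- max(total - c0_0, 1e-8)
  a_cand <- h[which(gh >= c0_0 + 0.95 * c_0)[1]]
  if (is.na(a_cand)) a_cand <- max(h) / 2
  obj <- function(par) {
    c0 <- par[1]; cc <- par[2]; a <- par[3]
    gm <- c0 + cc * (1 - exp(-3 * (h / a)^2))
    gm <- pmax(gm, 1e-12)
    sum(N * (gh - gm)^2 / gm^2)
  }
  starts <- list(c(c0_0, c_0, a_cand),
                 c(c0_0 / 10, total, max(h) / 3),
                 c(1e-6, total, max(h) / 5))
  best <- NULL
  for (st in starts) {
    ## the range is not identifiable beyond the data support and the sill not
    ## far above the empirical ceiling; bound both to keep WLS well-posed
    fit <- tryCatch(
      stats::nlminb(st, obj, lower = c(0, 1e-12, min(h) / 10),
                    upper = c(max(gh) * 2, max(gh) * 3, 1.5 * max(h)),
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best))
    stop("variogram fit failed to converge; bins:\n",
         paste(utils::capture.output(print(bins)), collapse = "\n"))
  list(c0 = best$par[1], c = best$par[2], a = best$par[3],
       objective = best$objective)
}

#' Fit a Gaussian variogram model to empirical variograms
#'
#' Weighted least squares (Cressie weights `N(h) / gamma(h)^2`) fit of the
#' Gaussian model. With `anisotropic = TRUE`, each directional empirical
#' variogram is fitted separately; the major-axis direction is the one with
#' the maximal fitted range, the anisotropy ratio is the minor/major range
#' ratio (clipped to (0, 1]), and the nugget/sill are taken from the
#' omnidirectional fit.
#'
#' @param emp a `variogram_empirical` or list of them (as returned by
#'   [empirical_variogram]); the omnidirectional entry must be present.
#' @param anisotropic fit geometric anisotropy from the directional entries?
#' @return A [variogram_model].
#' @export
fit_variogram <- function(emp, anisotropic = FALSE) {
  if (inherits(emp, "variogram_empirical")) emp <- list(emp)
  dirs <- vapply(emp, function(e) as.character(e$direction), character(1))
  omni <- emp[[match("omnidirectional", dirs)]]
  if (is.null(omni)) stop("omnidirectional empirical variogram required")
  usable <- omni$bins[omni$bins$pair_count >= 1, , drop = FALSE]
  if (nrow(usable) < 4) stop("need >= 4 usable bins to fit a variogram")
  base <- fit_gaussian_wls(usable)
  angle <- 0; ratio <- 1
  if (anisotropic) {
    dn <- which(dirs != "omnidirectional")
    if (length(dn) < 2)
      stop("anisotropic fit needs >= 2 directional variograms")
    ## directional fits: nugget and sill pinned at the omnidirectional
    ## estimates, only the range free — directional bins have far fewer pairs
    ## and a fully free fit is poorly identified
    ranges <- vapply(dn, function(k) {
      b <- emp[[k]]$bins
      if (nrow(b) < 4) return(NA_real_)
      h <- b$lag_centre; gh <- b$semivariance; N <- b$pair_count
      obj <- function(a) {
        gm <- pmax(base$c0 + base$c * (1 - exp(-3 * (h / a)^2)), 1e-12)
        sum(N * (gh - gm)^2 / gm^2)
      }
      ## ranges much shorter than the first populated lag are unidentifiable
      ## (all such bins already sit at the sill); bounding below by half that
      ## lag keeps survey geometries with wide across-track gaps from
      ## reporting an arbitrarily strong anisotropy
      stats::optimize(obj, c(min(h) / 2, 1.5 * max(h)))$minimum
    }, numeric(1))
    if (all(is.na(ranges))) stop("no directional variogram had enough bins")
    dird <- as.numeric(dirs[dn])
    angle <- dird[which.max(ranges)]
    ratio <- min(ranges, na.rm = TRUE) / max(ranges, na.rm = TRUE)
    ratio <- min(max(ratio, 1e-6), 1)
    base$a <- max(ranges, na.rm = TRUE)
  }
  variogram_model(nugget = base$c0, partial_sill = base$c, range_eff = base$a,
                  anisotropy_angle = angle, anisotropy_ratio = ratio)
}
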