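#' Synthetic shelf seafloor scenario
#'
#' Describes a synthetic continental-shelf seafloor: a deterministic
#' across-shore depth ramp plus a zero-mean anisotropic Gaussian random field
#' (Gaussian covariance `C(h) = sill * exp(-3 (h/a)^2)`, so `a` is the
#' effective range at 95% of the sill) plus independent nugget noise. The
#' coast runs parallel to the x axis along the northern edge; depth increases
#' southwards. Defaults emulate a ~35 km x 5 km shelf ramping from 20 m at the
#' shoreward edge to 130 m offshore, with the anisotropy major axis parallel
#' to the coast (90 degrees from north) and an effective range inside the
#' 400-750 m band typical of shelf bathymetry at this scale.
#'
#' @param extent_x,extent_y domain size in metres (x is alongshore).
#' @param cell grid cell size in metres.
#' @param depth_at_shore depth (m, positive down) at the northern (shore) edge.
#' @param depth_gradient across-shore depth gradient (m per m southwards).
#' @param field_sill variance (m^2) of the random relief field.
#' @param field_range_major effective range (m) along the major axis.
#' @param anisotropy_angle degrees from north of the major axis (clockwise).
#' @param anisotropy_ratio minor/major range ratio in (0, 1].
#' @param nugget independent per-cell noise variance (m^2).
#' @param seed integer seed for the field realization.
#' @return An object of class `seafloor_scenario`.
#' @export
seafloor_scenario <- function(extent_x = 35000, extent_y = 5000, cell = 25,
                              depth_at_shore = 20,
                              depth_gradient = 110 / 5000,
                              field_sill = 4, field_range_major = 600,
                              anisotropy_angle = 90, anisotropy_ratio = 0.5,
                              nugget = 0.01, seed = 1L) {
  stopifnot_scalar(extent_x, "extent_x", positive = TRUE)
  stopifnot_scalar(extent_y, "extent_y", positive = TRUE)
  stopifnot_scalar(cell, "cell", positive = TRUE)
  stopifnot_scalar(field_range_major, "field_range_major", positive = TRUE)
  if (field_sill < 0) stop("'field_sill' must be >= 0")
  if (nugget < 0) stop("'nugget' must be >= 0")
  if (anisotropy_ratio <= 0 || anisotropy_ratio > 1)
    stop("'anisotropy_ratio' must be in (0, 1]")
  structure(list(extent_x = extent_x, extent_y = extent_y, cell = cell,
                 depth_at_shore = depth_at_shore, depth_gradient = depth_gradient,
                 field_sill = field_sill, field_range_major = field_range_major,
                 anisotropy_angle = anisotropy_angle,
                 anisotropy_ratio = anisotropy_ratio,
                 nugget = nugget, seed = as.integer(seed)),
            class = "seafloor_scenario")
}

#' @export
print.seafloor_scenario <- function(x, ...) {
  cat(sprintf("<seafloor_scenario> %g x %g m @ %g m, depth %g m + %g m/m ramp\n",
              x$extent_x, x$extent_y, x$cell, x$depth_at_shore, x$depth_gradient))
  cat(sprintf("  GRF: sill %g m^2, range %g m, angle %g deg, ratio %g, nugget %g m^2, seed %d\n",
              x$field_sill, x$field_range_major, x$anisotropy_angle,
              x$anisotropy_ratio, x$nugget, x$seed))
  invisible(x)
}

## Effective isotropic lag under geometric anisotropy: lags are rotated into
## (major, minor) axes and the minor component stretched by 1/ratio, so the
## major-axis effective range is `a` and the minor-axis range is `a * ratio`.
aniso_lag <- function(dx, dy, angle_deg, ratio) {
  th <- angle_deg * pi / 180
  h_maj <- dx * sin(th) + dy * cos(th)
  h_min <- dx * cos(th) - dy * sin(th)
  sqrt(h_maj^2 + (h_min / ratio)^2)
}

## Gaussian covariance with effective range a (95% decay at h = a).
gauss_cov <- function(h, sill, a) sill * exp(-3 * (h / a)^2)

#' Simulate a synthetic seafloor DEM
#'
#' Realizes the scenario's Gaussian random field by circulant embedding on a
#' doubled grid (exact for stationary covariance up to truncation of small
#' negative embedding eigenvalues, which are clipped), adds the deterministic
#' across-shore ramp and independent nugget noise. Deterministic for a fixed
#' scenario seed.
#'
#' @param scenario a [seafloor_scenario].
#' @return A [grid_surface] of depths (m, positive down).
#' @export
generate_seafloor <- function(scenario) {
  sc <- scenario
  g <- grid_from_extent(sc$extent_x, sc$extent_y, sc$cell)
  nr <- g$nrows; nc <- g$ncols
  cc <- grid_centres(g)
  ramp <- sc$depth_at_shore + sc$depth_gradient * (g$origin_y - cc$Y)
  field <- matrix(0, nr, nc)
  with_seed(sc$seed, {
    if (sc$field_sill > 0) {
      field <- grf_circulant(nr, nc, sc$cell, sc$field_sill,
                             sc$field_range_major, sc$anisotropy_angle,
                             sc$anisotropy_ratio)
    }
    if (sc$nugget > 0)
      field <- field + matrix(stats::rnorm(nr * nc, sd = sqrt(sc$nugget)), nr, nc)
  })
  grid_surface(ramp + field, origin_x = g$origin_x, origin_y = g$origin_y,
               cell = g$cell)
}

## Circulant-embedding simulation of a stationary anisotropic Gaussian field
## on an nr x nc grid with spacing `cell`. Embeds on the doubled torus; small
## negative eigenvalues of the embedding are clipped to zero (warned when the
## deficit is material).
grf_circulant <- function(nr, nc, cell, sill, range_major, angle, ratio) {
  M <- 2L * nr; N <- 2L * nc
  ## minimal-image (torus) lags
  di <- c(0:(nr), if (nr > 1) (nr - 1):1) [seq_len(M)]
  dj <- c(0:(nc), if (nc > 1) (nc - 1):1) [seq_len(N)]
  dy <- matrix(di * cell, M, N)               # row index steps are northing steps
  dx <- matrix(dj * cell, M, N, byrow = TRUE)
  h <- aniso_lag(dx, dy, angle, ratio)
  C <- gauss_cov(h, sill, range_major)
  lam <- Re(stats::fft(C))
  neg <- lam < 0
  if (any(neg)) {
    deficit <- -sum(lam[neg]) / sum(lam[!neg])
    if (deficit > 0.01)
      warning(sprintf("circulant embedding clipped %.2f%% negative mass; field variance may be slightly low",
                      100 * deficit))
    lam[neg] <- 0
  }
  z <- matrix(stats::rnorm(M * N), M, N) + 1i * matrix(stats::rnorm(M * N), M, N)
  f <- stats::fft(sqrt(lam / (M * N)) * z)
  Re(f)[seq_len(nr), seq_len(nc)]
}

#' Survey design for a synthetic singlebeam survey
#'
#' Parallel shore-parallel transects spaced across-shore, soundings at fixed
#' along-track spacing, with Gaussian depth noise, occasional spikes, and a
#' sinusoidal tide riding on the recorded depths. Defaults follow a 500 m
#' transect / 40 m along-track survey of a semi-diurnal tide regime.
#'
#' @param transect_spacing across-shore spacing between transects (m).
#' @param along_track_spacing sounding spacing along a transect (m).
#' @param depth_noise_sd Gaussian depth noise standard deviation (m).
#' @param spike_rate probability that a sounding is replaced by a spike.
#' @param spike_magnitude absolute spike offset (m), sign random.
#' @param tide_amplitude tide amplitude (m).
#' @param tide_period tide period (hours).
#' @param vessel_speed survey speed (m/s).
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(transect_spacing = 500, along_track_spacing = 40,
                          depth_noise_sd = 0.2, spike_rate = 0.002,
                          spike_magnitude = 25, tide_amplitude = 0.8,
                          tide_period = 12.42, vessel_speed = 2.5) {
  stopifnot_scalar(transect_spacing, "transect_spacing", positive = TRUE)
  stopifnot_scalar(along_track_spacing, "along_track_spacing", positive = TRUE)
  if (depth_noise_sd < 0) stop("'depth_noise_sd' must be >= 0")
  if (spike_rate < 0 || spike_rate >= 1) stop("'spike_rate' must be in [0, 1)")
  structure(list(transect_spacing = transect_spacing,
                 along_track_spacing = along_track_spacing,
                 depth_noise_sd = depth_noise_sd, spike_rate = spike_rate,
                 spike_magnitude = spike_magnitude,
                 tide_amplitude = tide_amplitude, tide_period = tide_period,
                 vessel_speed = vessel_speed),
            class = "survey_design")
}

#' Sample a singlebeam survey over a DEM
#'
#' Lays shore-parallel transects at the design spacing (edges inclusive,
#' boustrophedon steaming order for consistent timestamps), samples the DEM by
#' bilinear interpolation at each sounding position, and records raw depths as
#' true depth + tide(t) + Gaussian noise, with spikes of random sign injected
#' at the design rate. The true spike labels are kept in the `spike` column so
#' despiking can be scored on synthetic data.
#'
#' @param dem a [grid_surface] of depths.
#' @param design a [survey_design].
#' @param seed integer seed.
#' @return List with `soundings` (a [sounding_set] with columns
#'   `x, y, t, depth` plus `transect`, `true_depth`, `spike`), `tide`
#'   (a [tide_series]), and `tracks` (list of 2x2 segment endpoint matrices).
#' @export
sample_survey <- function(dem, design, seed = 1L) {
  d <- design
  ex <- dem$ncols * dem$cell
  ey <- dem$nrows * dem$cell
  ys <- seq(dem$origin_y, by = -d$transect_spacing,
            length.out = max(1L, floor(ey / d$transect_spacing) + 1L))
  if (length(ys) == 1L && d$transect_spacing > ey)
    warning("transect spacing exceeds across-shore extent; single transect produced")
  ## clamp transects to cell-centre band so bilinear sampling is interior
  cc <- grid_centres(dem)
  ys <- pmin(pmax(ys, min(cc$y)), max(cc$y))
  xs0 <- seq(dem$origin_x, by = d$along_track_spacing,
             length.out = floor(ex / d$along_track_spacing) + 1L)
  xs0 <- pmin(pmax(xs0, min(cc$x)), max(cc$x))
  recs <- vector("list", length(ys))
  tracks <- vector("list", length(ys))
  t_cursor <- 0
  for (k in seq_along(ys)) {
    xs <- if (k %% 2L == 1L) xs0 else rev(xs0)
    tt <- t_cursor + cumsum(c(0, abs(diff(xs)))) / d$vessel_speed
    t_cursor <- tt[length(tt)] + d$transect_spacing / d$vessel_speed
    recs[[k]] <- data.frame(x = xs, y = ys[k], t = tt, transect = k)
    tracks[[k]] <- rbind(c(min(xs), ys[k]), c(max(xs), ys[k]))
  }
  pts <- do.call(rbind, recs)
  true_depth <- grid_bilinear(dem, pts$x, pts$y)
  phase <- 0; tide_h <- function(t) 0
  n <- nrow(pts)
  raw <- true_depth
  spike <- logical(n)
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    period_s <- d$tide_period * 3600
    tide_h <- function(t) d$tide_amplitude * sin(2 * pi * t / period_s + phase)
    raw <- true_depth + tide_h(pts$t) + stats::rnorm(n, sd = d$depth_noise_sd)
    if (d$spike_rate > 0) {
      spike <- stats::runif(n) < d$spike_rate
      raw[spike] <- raw[spike] + sample(c(-1, 1), sum(spike), replace = TRUE) * d$spike_magnitude
    }
  })
  t_grid <- seq(-600, max(pts$t) + 600, by = 600)
  tide <- tide_series(data.frame(t = t_grid, height = tide_h(t_grid)),
                      datum_offset = 0)
  s <- sounding_set(data.frame(x = pts$x, y = pts$y, t = pts$t, depth = raw,
                               transect = pts$transect,
                               true_depth = true_depth, spike = spike),
                    provenance = sprintf("sample_survey(seed=%d)", as.integer(seed)))
  list(soundings = s, tide = tide, tracks = tracks)
}

#' Sample random station locations
#'
#' Uniform rejection sampling over the extent with a minimum pairwise
#' separation, emulating drop-camera deployment positions.
#'
#' @param extent_x,extent_y domain size (m).
#' @param n number of stations.
#' @param min_separation minimum pairwise distance (m).
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempt budget per point.
#' @return data.frame with columns `x`, `y`.
#' @export
sample_stations <- function(extent_x, extent_y, n = 500, min_separation = 200,
                            seed = 1L, max_tries = 200L) {
  if (n < 1) stop("'n' must be >= 1")
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        px <- stats::runif(1, 0, extent_x)
        py <- stats::runif(1, 0, extent_y)
        if (min_separation <= 0 || length(xs) == 0 ||
            min((xs - px)^2 + (ys - py)^2) >= min_separation^2) {
          xs <- c(xs, px); ys <- c(ys, py); placed <- TRUE; break
        }
      }
      if (!placed)
        stop(sprintf("could not place station %d with min_separation %g after %d tries",
                     i, min_separation, max_tries))
    }
    data.frame(x = xs, y = ys)
  })
}

#' Species response parameters for synthetic occurrence data
#'
#' Occurrence is Bernoulli with
#' `logit p = intercept - beta_depth * ((depth - depth_opt) / depth_tol)^2 +
#' sum(beta_terrain * standardized layer)`. When `target_prevalence` is set,
#' the intercept is re-calibrated (bisection on the expected prevalence over
#' the supplied stations) to match it within 0.02.
#'
#' @param name species label.
#' @param intercept baseline log-odds.
#' @param depth_opt optimal depth (m).
#' @param depth_tol depth tolerance scale (m, > 0).
#' @param beta_depth weight of the quadratic depth response.
#' @param beta_terrain named numeric vector of weights on standardized
#'   terrain layers (names must match stack layer names), or NULL.
#' @param target_prevalence optional prevalence in (0,1) to calibrate to.
#' @return An object of class `species_params`.
#' @export
species_params <- function(name, intercept = 0, depth_opt = 100, depth_tol = 15,
                           beta_depth = 0, beta_terrain = NULL,
                           target_prevalence = NULL) {
  if (depth_tol <= 0) stop("'depth_tol' must be > 0")
  if (!is.null(target_prevalence) &&
      (target_prevalence <= 0 || target_prevalence >= 1))
    stop("'target_prevalence' must be in (0, 1)")
  structure(list(name = name, intercept = intercept, depth_opt = depth_opt,
                 depth_tol = depth_tol, beta_depth = beta_depth,
                 beta_terrain = beta_terrain,
                 target_prevalence = target_prevalence),
            class = "species_params")
}

#' Simulate presence/absence records at stations
#'
#' Draws Bernoulli occurrence at each station from the species' logistic
#' response to depth and (standardized) terrain layers extracted from the
#' stack.
#'
#' @param stack a [terrain_stack].
#' @param stations data.frame with `x`, `y` columns, or a [station_table]
#'   already carrying extracted features.
#' @param params a [species_params].
#' @param seed integer seed.
#' @return A [station_table] with the species presence column added and the
#'   linear-predictor probability kept in attribute `"true_prob"`.
#' @export
simulate_species <- function(stack, stations, params, seed = 1L) {
  tab <- if (inherits(stations, "station_table")) stations
         else extract_features(stack, stations)
  feats <- attr(tab, "feature_names")
  if (!("depth" %in% feats)) stop("stack must provide a 'depth' layer")
  depth <- tab[["depth"]]
  lin <- -params$beta_depth * ((depth - params$depth_opt) / params$depth_tol)^2
  if (!is.null(params$beta_terrain)) {
    missing <- setdiff(names(params$beta_terrain), feats)
    if (length(missing))
      stop("unknown terrain layer(s): ", paste(missing, collapse = ", "),
           "; available: ", paste(feats, collapse = ", "))
    for (nm in names(params$beta_terrain)) {
      v <- tab[[nm]]
      s <- stats::sd(v)
      z <- if (is.finite(s) && s > 0) (v - mean(v)) / s else rep(0, length(v))
      lin <- lin + params$beta_terrain[[nm]] * z
    }
  }
  b0 <- params$intercept
  if (!is.null(params$target_prevalence)) {
    target <- params$target_prevalence
    f <- function(b) mean(stats::plogis(b + lin)) - target
    lo <- -30; hi <- 30
    b0 <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  p <- stats::plogis(b0 + lin)
  pres <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  tab[[params$name]] <- pres
  attr(tab, "species") <- c(attr(tab, "species"), params$name)
  attr(tab, "true_prob") <- p
  attr(tab, "calibrated_intercept") <- b0
  tab
}

#' Tide height series
#'
#' @param samples data.frame with strictly increasing `t` (s) and `height`
#'   (m above chart datum).
#' @param datum_offset chart datum to vertical datum offset (m).
#' @return An object of class `tide_series`.
#' @export
tide_series <- function(samples, datum_offset = 0) {
  if (!all(diff(samples$t) > 0)) stop("tide times must be strictly increasing")
  structure(list(samples = samples, datum_offset = datum_offset),
            class = "tide_series")
}

#' Write track polylines as WKT LINESTRING text
#'
#' @param tracks list of n x 2 coordinate matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks_wkt <- function(tracks, path) {
  wkt <- vapply(tracks, function(m) {
    sprintf("LINESTRING (%s)",
            paste(sprintf("%.3f %.3f", m[, 1], m[, 2]), collapse = ", "))
  }, character(1))
  writeLines(wkt, path)
  invisible(path)
}
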