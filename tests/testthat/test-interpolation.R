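test_that("IDW matches hand-computed weights and the exact-hit rule", {
  g0 <- point_grid(0, 0)
  s <- ss(c(1, 2), c(0, 0), c(0, 3))
  expect_equal(idw_predict(s, g0, power = 1, n_neighbors = 2)$values[1, 1], 1.0)
  expect_equal(idw_predict(s, g0, power = 2, n_neighbors = 2)$values[1, 1], 0.6)
  ## single data point dominates everywhere
  expect_equal(idw_predict(ss(5, 5, 5), g0, 2, 5)$values[1, 1], 5)
  ## exact hit returns the data value
  gh <- point_grid(1, 0)
  expect_equal(idw_predict(s, gh, 2, 2)$values[1, 1], 0)
})

test_that("IDW is bounded by neighbourhood extremes and tends to NN as p grows", {
  set.seed(4)
  s <- ss(runif(40, 0, 100), runif(40, 0, 100), runif(40, 10, 20))
  g <- grid_surface(matrix(0, 6, 6), origin_x = 5, origin_y = 95, cell = 15)
  pr <- idw_predict(s, g, power = 2, n_neighbors = 10)
  expect_true(all(pr$values >= 10 & pr$values <= 20))
  ## p = 50 proxy for the nearest-neighbour limit: where the nearest point is
  ## clearly nearest (second distance >= 1.3x), its weight dominates
  pr50 <- idw_predict(s, g, power = 50, n_neighbors = 10)
  cc <- grid_centres(g)
  for (i in seq_along(cc$X)) {
    d <- sort(sqrt((s$x - as.vector(cc$X)[i])^2 + (s$y - as.vector(cc$Y)[i])^2))
    if (d[2] / d[1] < 1.3) next
    nn_val <- s$depth[which.min((s$x - as.vector(cc$X)[i])^2 +
                                  (s$y - as.vector(cc$Y)[i])^2)]
    expect_equal(as.vector(pr50$values)[i], nn_val, tolerance = 1e-3)
  }
})

test_that("RBF reproduces planes exactly and interpolates data points", {
  set.seed(2)
  px <- runif(30, -5, 5); py <- runif(30, -5, 5)
  plane <- ss(px, py, 2 * px + 3)
  for (b in c("m", "crs")) {
    d <- if (b == "m") 1 else 0.1
    r <- rbf_predict(plane, point_grid(0, 0), basis = b, delta = d,
                     robustness = 0, n_neighbors = 30)
    expect_lt(abs(r$values[1, 1] - 3), 1e-6)
  }
  wig <- ss(px, py, sin(px) * py)
  at1 <- rbf_predict(wig, point_grid(px[1], py[1]), basis = "m", delta = 1,
                     robustness = 0, n_neighbors = 30)
  expect_lt(abs(at1$values[1, 1] - sin(px[1]) * py[1]), 1e-6)
})

test_that("local multiquadric agrees with an independent global solve", {
  ## oracle: one dense system phi(r) = sqrt(r^2 + d^2) over all 50 points with
  ## a linear polynomial part, solved directly
  set.seed(9)
  n <- 50
  px <- runif(n, 0, 1000); py <- runif(n, 0, 1000)
  z <- 30 + 0.01 * px + 2 * sin(px / 200) * cos(py / 250)
  delta <- 5
  D <- sqrt(outer(px, px, "-")^2 + outer(py, py, "-")^2)
  A <- sqrt(D^2 + delta^2)
  P <- cbind(1, px, py)
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(M, c(z, rep(0, 3)))
  qx <- runif(40, 100, 900); qy <- runif(40, 100, 900)
  d0 <- sqrt(outer(qx, px, "-")^2 + outer(qy, py, "-")^2)
  oracle <- as.vector(sqrt(d0^2 + delta^2) %*% sol[1:n] +
                        cbind(1, qx, qy) %*% sol[n + 1:3])
  local <- bathysdm:::rbf_points(px, py, z, qx, qy, "m", delta, 0, n)
  expect_lt(max(abs(local - oracle)), 0.05)
})

test_that("kriging honours the unbiasedness constraint and exactness", {
  vm <- variogram_model(nugget = 0, partial_sill = 4, range_eff = 10)
  s <- ss(c(-3, -1, 1, 3, 0), c(2, -2, 2, -2, 3), c(1, 2, 3, 4, 10))
  ## weights sum to 1 <=> adding a constant shifts predictions by it
  g0 <- point_grid(0.3, 0.4)
  p1 <- krige_predict(s, g0, vm, 0, 5)$prediction$values[1, 1]
  s2 <- s; s2$depth <- s2$depth + 100
  p2 <- krige_predict(s2, g0, vm, 0, 5)$prediction$values[1, 1]
  expect_equal(p2 - p1, 100, tolerance = 1e-7)
  ## constant field reproduced exactly
  sc <- s; sc$depth <- rep(7, 5)
  expect_equal(krige_predict(sc, g0, vm, 0, 5)$prediction$values[1, 1], 7,
               tolerance = 1e-7)
  ## exact interpolator with zero nugget, se 0 at data points
  gd <- point_grid(-3, 2)
  k <- krige_predict(s, gd, vm, 0, 5)
  expect_equal(k$prediction$values[1, 1], 1, tolerance = 1e-6)
  expect_lt(k$se$values[1, 1], 1e-4)
})

test_that("pure-nugget ordinary kriging equals the neighbourhood mean", {
  vm <- variogram_model(nugget = 2, partial_sill = 1e-12, range_eff = 100)
  z <- c(1, 2, 3, 4, 10)
  s <- ss(c(-3, -1, 1, 3, 0), c(2, -2, 2, -2, 3), z)
  k <- krige_predict(s, point_grid(0, 0), vm, 0, 5)
  expect_equal(k$prediction$values[1, 1], mean(z), tolerance = 1e-7)
})

test_that("kriging predictions are translation invariant", {
  vm <- variogram_model(0.01, 4, 300)
  set.seed(5)
  s <- ss(runif(30, 0, 500), runif(30, 0, 500), rnorm(30, 50, 2))
  g <- point_grid(250, 250)
  p0 <- krige_predict(s, g, vm, 1, 20)$prediction$values[1, 1]
  sT <- s; sT$x <- sT$x + 1e5; sT$y <- sT$y + 2e5
  gT <- point_grid(250 + 1e5, 250 + 2e5)
  pT <- krige_predict(sT, gT, vm, 1, 20)$prediction$values[1, 1]
  expect_lt(abs(p0 - pT), 1e-9)
})

test_that("LOOCV residuals match a naive per-point re-implementation (IDW p=3)", {
  set.seed(8)
  n <- 30
  s <- ss(runif(n, 0, 500), runif(n, 0, 500), rnorm(n, 40, 3))
  k <- 8
  rep <- loocv(s, interp_config("idw", power = 3, n_neighbors = k))
  naive <- vapply(seq_len(n), function(i) {
    d <- sqrt((s$x[-i] - s$x[i])^2 + (s$y[-i] - s$y[i])^2)
    z <- s$depth[-i]
    o <- order(d)[1:k]
    w <- d[o]^(-3)
    sum(w * z[o]) / sum(w) - s$depth[i]
  }, numeric(1))
  expect_equal(rep$residuals, naive, tolerance = 1e-12)
  expect_equal(rep$rmse, sqrt(mean(naive^2)), tolerance = 1e-12)
})

test_that("LOOCV of an exact interpolator on smooth noiseless data is ~zero", {
  ## plane data: kriging with any variogram and a degree-1 trend nails it
  set.seed(10)
  s <- ss(runif(40, 0, 400), runif(40, 0, 400), numeric(40))
  s$depth <- 20 + 0.01 * s$x + 0.02 * s$y
  vm <- variogram_model(0, 1, 200)
  rep <- loocv(s, interp_config("uk1", n_neighbors = 12, variogram = vm))
  expect_lt(rep$rmse, 1e-6)
})

test_that("kriging standard errors are calibrated on self-consistent data", {
  ## data simulated from the variogram used to krige: |ASE-RMSE|/RMSE small
  cal <- vapply(1:10, function(sd) {
    sc <- seafloor_scenario(extent_x = 2400, extent_y = 2400, cell = 30,
                            field_sill = 4, field_range_major = 500,
                            anisotropy_ratio = 1, nugget = 0.1,
                            depth_gradient = 0, depth_at_shore = 50, seed = sd)
    dem <- generate_seafloor(sc)
    cc <- grid_centres(dem)
    idx <- with(list(), {set.seed(sd); sample(length(dem$values), 250)})
    s <- ss(as.vector(cc$X)[idx], as.vector(cc$Y)[idx],
            as.vector(dem$values)[idx])
    vm <- variogram_model(nugget = 0.1, partial_sill = 4, range_eff = 500)
    r <- loocv(s, interp_config("ok", n_neighbors = 20, variogram = vm))
    abs(r$ase - r$rmse) / r$rmse
  }, numeric(1))
  expect_lt(mean(cal), 0.25)
})

test_that("optimize_rbf prefers no smoothing on exact data and smoothing on noise", {
  f <- function(x, y) 50 + 0.01 * x + 3 * sin(x / 300) * cos(y / 300)
  noiseless <- vapply(1:5, function(sd) {
    set.seed(sd)
    x <- runif(100, 0, 1000); y <- runif(100, 0, 1000)
    optimize_rbf(ss(x, y, f(x, y)), "m", 20, delta_grid = 5,
                 robustness_grid = c(0, 1e-3, 1e-2, 0.05), seed = sd)$robustness
  }, numeric(1))
  expect_true(all(noiseless == 0))
  noisy <- vapply(1:10, function(sd) {
    set.seed(sd)
    x <- runif(120, 0, 1000); y <- runif(120, 0, 1000)
    optimize_rbf(ss(x, y, f(x, y) + rnorm(120, sd = 0.5)), "m", 20,
                 delta_grid = c(1, 5, 20),
                 robustness_grid = c(0, 1e-3, 1e-2, 0.05), seed = sd)$robustness
  }, numeric(1))
  expect_gte(sum(noisy > 0), 8)
  ## single-candidate grids return that candidate
  single <- optimize_rbf(ss(1:20, rep(0, 20), rnorm(20, 50)), "m", 5,
                         delta_grid = 2, robustness_grid = 0.1)
  expect_equal(single$delta, 2)
  expect_equal(single$robustness, 0.1)
})

test_that("selection ranks by family score and picks the lowest overall RMSE", {
  mk <- function(method, rmse, ase = NULL) {
    structure(list(config = list(method = method), label = method,
                   residuals = numeric(0), rmse = rmse, ase = ase,
                   selection_score = if (is.null(ase)) rmse else abs(ase - rmse),
                   n = 10), class = "cv_report")
  }
  r <- select_best(list(mk("idw", 0.40), mk("idw", 0.33)))
  expect_equal(r$best$rmse, 0.33)
  ## kriging ranked by |ASE-RMSE| regardless of raw RMSE order
  k1 <- mk("ok", 0.30, ase = 0.40)    # score 0.10
  k2 <- mk("uk1", 0.35, ase = 0.38)   # score 0.03 -> family winner
  r2 <- select_best(list(k1, k2))
  expect_equal(r2$best_per_family$kriging$config$method, "uk1")
  ## single report is its own winner
  expect_equal(select_best(list(mk("idw", 0.5)))$best$rmse, 0.5)
  expect_error(select_best(list()), "no cross-validation")
})
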