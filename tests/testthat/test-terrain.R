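## analytic depth grids: depth = -elevation
elev_grid <- function(nr, nc, cell, f) {
  g <- fun_grid(nr, nc, cell, function(X, Y) -f(X, Y))
  g
}

test_that("Horn slope and aspect match hand-evaluated planes", {
  ## elevation rising east at gradient 2 (cell 1): slope atan(2), aspect 270
  g <- elev_grid(7, 7, 1, function(X, Y) 2 * X)
  hs <- horn_slope_aspect(g)
  expect_equal(hs$slope$values[4, 4], atan(2) * 180 / pi, tolerance = 1e-9)
  expect_equal(hs$WE$values[4, 4], -1, tolerance = 1e-9)
  expect_equal(hs$NS$values[4, 4], 0, tolerance = 1e-9)
  ## elevation rising north at gradient 1: slope 45, aspect 180 (south-facing down)
  g2 <- elev_grid(7, 7, 1, function(X, Y) Y)
  hs2 <- horn_slope_aspect(g2)
  expect_equal(hs2$slope$values[4, 4], 45, tolerance = 1e-9)
  expect_equal(hs2$NS$values[4, 4], -1, tolerance = 1e-9)
  expect_equal(hs2$WE$values[4, 4], 0, tolerance = 1e-9)
  ## flat: slope 0 and the NS=WE=0 convention; edges are nodata
  g3 <- grid_surface(matrix(5, 6, 6), cell = 2)
  hs3 <- horn_slope_aspect(g3)
  expect_true(all(hs3$slope$values[2:5, 2:5] == 0))
  expect_true(all(hs3$NS$values[2:5, 2:5] == 0 & hs3$WE$values[2:5, 2:5] == 0))
  expect_true(all(is.na(hs3$slope$values[1, ])))
})

test_that("northness and eastness lie on the unit circle where sloped", {
  dem <- generate_seafloor(test_scenario(31, extent_x = 1500, extent_y = 1000))
  hs <- horn_slope_aspect(dem)
  sl <- hs$slope$values; ns <- hs$NS$values; we <- hs$WE$values
  ok <- !is.na(sl) & sl > 0
  expect_true(all(abs(ns[ok]^2 + we[ok]^2 - 1) < 1e-9))
  expect_true(all(abs(ns[!is.na(ns)]) <= 1) && all(abs(we[!is.na(we)]) <= 1))
})

test_that("focal statistics match the impulse and plane closed forms", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  d <- grid_surface(m, cell = 1)
  expect_equal(focal_stat(d, "TRI")$values[3, 3], 1)
  expect_equal(focal_stat(d, "TPI")$values[3, 3], 1)
  expect_equal(focal_stat(d, "roughness")$values[3, 3], 1)
  expect_equal(focal_stat(d, "SD")$values[3, 3], stats::sd(c(1, rep(0, 8))))
  ## planes have TPI 0; constants have SD/TRI/roughness 0
  pl <- fun_grid(6, 6, 2, function(X, Y) 0.3 * X - 0.1 * Y)
  expect_true(all(abs(focal_stat(pl, "TPI")$values[2:5, 2:5]) < 1e-12))
  cst <- grid_surface(matrix(4, 5, 5), cell = 1)
  for (mt in c("SD", "TRI", "roughness"))
    expect_true(all(focal_stat(cst, mt)$values[2:4, 2:4] == 0))
})

test_that("mean curvature is -(a+b) of the fitted quadratic with the depth sign convention", {
  ## elevation bowl x^2 + y^2 -> MNC -2 (concave); dome -> +2
  bowl <- elev_grid(7, 7, 1, function(X, Y) X^2 + Y^2)
  dome <- elev_grid(7, 7, 1, function(X, Y) -(X^2 + Y^2))
  expect_equal(mean_curvature(bowl)$values[4, 4], -2, tolerance = 1e-9)
  expect_equal(mean_curvature(dome)$values[4, 4], 2, tolerance = 1e-9)
  pl <- elev_grid(7, 7, 1, function(X, Y) 3 + 0.5 * X - 0.2 * Y)
  expect_true(all(abs(mean_curvature(pl)$values[2:6, 2:6]) < 1e-9))
})

test_that("Gaussian smoothing preserves planes and reproduces the kernel impulse", {
  cst <- grid_surface(matrix(3, 7, 7), cell = 1)
  expect_equal(gaussian_smooth(cst)$values, cst$values)
  pl <- fun_grid(9, 9, 1, function(X, Y) X + 2 * Y)
  sm <- gaussian_smooth(pl)
  expect_equal(sm$values[3:7, 3:7], pl$values[3:7, 3:7], tolerance = 1e-9)
  imp <- grid_surface(matrix(0, 5, 5), cell = 1); imp$values[3, 3] <- 1
  w1 <- exp(-(-2:2)^2 / 2); K <- outer(w1, w1); K <- K / sum(K)
  expect_equal(gaussian_smooth(imp)$values[3, 3], K[3, 3], tolerance = 1e-12)
})

test_that("bilinear resampling reproduces planes at the new cell centres", {
  g3 <- fun_grid(30, 30, 3, function(X, Y) X + 2 * Y)
  g9 <- resample_bilinear(g3, 9)
  cc <- grid_centres(g9)
  interior <- 2:(g9$nrows - 1)
  expect_equal(g9$values[interior, interior],
               (cc$X + 2 * cc$Y)[interior, interior], tolerance = 1e-9)
  ## identity and constant cases
  expect_identical(resample_bilinear(g3, 3), g3)
  cst <- grid_surface(matrix(7, 12, 12), cell = 3)
  expect_true(all(resample_bilinear(cst, 6)$values == 7))
})

test_that("stack layer counts follow depth + 8 derivatives per resolution", {
  dem <- grid_surface(matrix(rnorm(400), 20, 20), cell = 3)
  expect_length(build_stack(dem, 3)$layers, 9)
  dem2 <- grid_surface(matrix(rnorm(3600), 60, 60), cell = 3)
  expect_length(build_stack(dem2, c(3, 9, 15, 25))$layers, 33)
  expect_error(build_stack(dem, 1), "native")
  ## a flat DEM has all-zero derivative layers
  st <- build_stack(grid_surface(matrix(50, 20, 20), cell = 3), c(3, 9))
  for (nm in setdiff(names(st$layers), "depth")) {
    v <- st$layers[[nm]]$values
    expect_true(all(abs(v[!is.na(v)]) < 1e-9), label = nm)
  }
})

test_that("derivatives are invariant to a constant depth shift", {
  dem <- generate_seafloor(test_scenario(32, extent_x = 1500, extent_y = 1000))
  st1 <- build_stack(dem, dem$cell * c(1, 3))
  dem2 <- dem; dem2$values <- dem2$values + 100
  st2 <- build_stack(dem2, dem$cell * c(1, 3))
  for (nm in setdiff(names(st1$layers), "depth"))
    expect_equal(st2$layers[[nm]]$values, st1$layers[[nm]]$values,
                 tolerance = 1e-9, label = nm)
  expect_equal(st2$layers$depth$values, st1$layers$depth$values + 100)
})
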