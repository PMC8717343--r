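## Shared fixtures: everything is generated in code at test time.

## Small anisotropic shelf scenario used by the desk-scale property tests.
test_scenario <- function(seed, extent_x = 4000, extent_y = 2500, ...) {
  seafloor_scenario(extent_x = extent_x, extent_y = extent_y, cell = 25,
                    seed = seed, ...)
}

## Survey -> QC'd sounding set over a scenario's DEM; returns everything.
test_survey <- function(seed, scenario = test_scenario(seed),
                        design = survey_design()) {
  dem <- generate_seafloor(scenario)
  svy <- sample_survey(dem, design, seed = seed + 1000L)
  s <- despike(tide_correct(svy$soundings, svy$tide))
  list(dem = dem, survey = svy, soundings = s)
}

## Simple sounding set constructor for hand examples.
ss <- function(x, y, depth, t = seq_along(x)) {
  sounding_set(data.frame(x = x, y = y, t = t, depth = depth))
}

## 1x1 grid whose single cell centre sits at (cx, cy).
point_grid <- function(cx = 0, cy = 0, cell = 1) {
  grid_surface(matrix(0, 1, 1), origin_x = cx - cell / 2,
               origin_y = cy + cell / 2, cell = cell)
}

## Grid whose values are a function of cell-centre coordinates.
fun_grid <- function(nr, nc, cell, f) {
  g <- grid_surface(matrix(0, nr, nc), cell = cell)
  cc <- grid_centres(g)
  g$values <- f(cc$X, cc$Y)
  g
}
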