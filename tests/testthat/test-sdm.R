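## build a station_table directly from a feature matrix and labels
mk_table <- function(X, y, species = "sp") {
  X <- as.data.frame(X)
  tab <- cbind(data.frame(x = seq_len(nrow(X)), y = 0), X)
  tab[[species]] <- y
  structure(tab, feature_names = names(X), species = species,
            n_dropped = 0L, class = c("station_table", "data.frame"))
}

test_that("feature extraction picks the exact cell values and drops off-grid stations", {
  dem <- generate_seafloor(test_scenario(51, extent_x = 1500, extent_y = 1000))
  st <- build_stack(dem, dem$cell * c(1, 3))
  expect_length(st$layers, 17)
  cc <- grid_centres(st$layers$depth)
  stations <- data.frame(x = c(cc$X[5, 5], -100), y = c(cc$Y[5, 5], 200))
  tab <- extract_features(st, stations)
  expect_equal(nrow(tab), 1)
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_equal(tab$depth, st$layers$depth$values[5, 5])
  expect_equal(tab$slope_75, st$layers$slope_75$values[
    bathysdm:::grid_rowcol(st$layers$slope_75, tab$x, tab$y)])
  expect_length(attr(tab, "feature_names"), 17)
})

test_that("random forest separates a separable toy problem and errors on one class", {
  set.seed(1)
  n <- 120
  x1 <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  y <- rep(c(0, 1), each = n / 2)
  tab <- mk_table(data.frame(f1 = x1, f2 = rnorm(n)), y)
  fit <- suppressWarnings(fit_rf(tab, "sp", seed = 1))
  expect_equal(fit$holdout_auc, 1.0)
  ## residuals are observed minus predicted probability
  expect_true(all(abs(fit$residuals) <= 1))
  expect_equal(fit$residuals,
               fit$y[fit$test_idx] -
                 predict(fit$model, fit$data[fit$test_idx, ], type = "prob")[, "1"],
               ignore_attr = TRUE)
  expect_error(suppressWarnings(fit_rf(mk_table(data.frame(f = rnorm(40)),
                                                rep(1, 40)), "sp")),
               "single class")
})

test_that("labels shuffled independently of features give chance-level AUC", {
  set.seed(2)
  aucs <- vapply(1:10, function(sd) {
    n <- 160
    X <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
    y <- rbinom(n, 1, 0.5)
    suppressWarnings(fit_rf(mk_table(X, y), "sp", seed = sd))$holdout_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("cross-validated AUC returns one value per stratified fold, deterministically", {
  set.seed(3)
  n <- 150
  X <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X$f1))
  tab <- mk_table(X, y)
  a <- cv_auc(tab, "sp", folds = 5, seed = 4)
  expect_length(as.numeric(a), 5)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(attr(a, "mean_auc"), mean(as.numeric(a)))
  expect_identical(as.numeric(a), as.numeric(cv_auc(tab, "sp", folds = 5, seed = 4)))
  expect_error(cv_auc(mk_table(X, c(rep(0, n - 2), 1, 1)), "sp", folds = 5),
               "stratify")
})

test_that("Welch comparison of fold AUCs handles identical and separated inputs", {
  same <- compare_auc(c(0.8, 0.82, 0.81, 0.79, 0.8), c(0.8, 0.82, 0.81, 0.79, 0.8))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  ## constant identical vectors: degenerate case t=0, p=1
  flat <- compare_auc(rep(0.9, 5), rep(0.9, 5))
  expect_equal(flat$p_value, 1)
  sep <- compare_auc(c(0.9, 0.9, 0.9, 0.9, 0.9) + c(1, -1, 2, -2, 0) * 1e-3,
                     c(0.5, 0.5, 0.5, 0.5, 0.5) + c(-1, 1, -2, 2, 0) * 1e-3)
  expect_lt(sep$p_value, 0.01)
  expect_error(compare_auc(c(0.8, 0.9), c(0.7, 0.8, 0.9)), "equal-length")
})

test_that("permutation importance ranks signal over pure noise", {
  set.seed(5)
  n <- 200
  X <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, plogis(3 * X$signal))
  fit <- suppressWarnings(fit_rf(mk_table(X, y), "sp", seed = 5))
  imp <- rf_importance(fit, seed = 6)
  expect_equal(imp$variable[1], "signal")
  expect_lt(max(abs(imp$importance[imp$variable != "signal"])), 0.06)
  expect_gt(imp$importance[1], 0.1)
})

test_that("partial dependence is flat for unused features and monotone for monotone effects", {
  set.seed(6)
  n <- 250
  ## `inert` is constant, so no tree can split on it: its curve must be flat
  X <- data.frame(driver = runif(n, -2, 2), inert = rep(0.5, n))
  y <- rbinom(n, 1, plogis(3 * X$driver))
  fit <- suppressWarnings(fit_rf(mk_table(X, y), "sp", seed = 7))
  pd_flat <- partial_dependence(fit, "inert")
  expect_lt(diff(range(pd_flat$response)), 0.01)
  pd_mono <- partial_dependence(fit, "driver")
  expect_true(all(pd_mono$response >= 0 & pd_mono$response <= 1))
  expect_gt(abs(stats::cor(pd_mono$value, pd_mono$response, method = "spearman")),
            0.8)
  expect_error(partial_dependence(fit, "absent"), "unknown")
})

test_that("probability surfaces stay in [0,1] and respond to the driving layer", {
  dem <- generate_seafloor(test_scenario(52, extent_x = 2000, extent_y = 1500))
  st <- build_stack(dem, dem$cell)
  stn <- sample_stations(2000, 1500, n = 250, min_separation = 0, seed = 52)
  deep <- stats::quantile(st$layers$depth$values, 0.8, na.rm = TRUE)
  tab <- simulate_species(st, stn, species_params("deep_sp", depth_opt = deep,
                                                  depth_tol = 10, beta_depth = 6,
                                                  target_prevalence = 0.35),
                          seed = 53)
  fit <- suppressWarnings(fit_rf(tab, "deep_sp", seed = 54))
  prob <- predict_surface(fit, st)
  v <- prob$values
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  dq <- stats::quantile(st$layers$depth$values, c(0.25, 0.75), na.rm = TRUE)
  expect_gt(mean(v[st$layers$depth$values >= dq[2]], na.rm = TRUE),
            mean(v[st$layers$depth$values <= dq[1]], na.rm = TRUE))
  expect_error(predict_surface(fit, build_stack(dem, dem$cell * 3)), "missing")
})
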