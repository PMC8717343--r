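#' Extract terrain features at station locations
#'
#' Joins every stack layer to the stations by nearest cell. Stations falling
#' outside a layer's extent or on nodata are dropped (count logged in
#' attribute `"n_dropped"`). Feature order is deterministic: the stack's
#' layer order (variable, then resolution).
#'
#' @param stack a [terrain_stack].
#' @param stations data.frame with columns `x`, `y` (and optionally existing
#'   species columns, which are preserved).
#' @return An object of class `station_table` (a data.frame of `x`, `y`,
#'   preserved columns and one column per layer) with attributes
#'   `feature_names`, `species`, `n_dropped`.
#' @export
extract_features <- function(stack, stations) {
  st <- as.data.frame(stations)
  feats <- names(stack$layers)
  vals <- matrix(NA_real_, nrow(st), length(feats),
                 dimnames = list(NULL, feats))
  for (k in seq_along(feats)) {
    g <- stack$layers[[k]]
    rc <- grid_rowcol(g, st$x, st$y)
    ok <- !is.na(rc[, "row"])
    vals[ok, k] <- g$values[rc[ok, , drop = FALSE]]
  }
  keep <- rowSums(is.na(vals)) == 0L
  n_dropped <- sum(!keep)
  out <- cbind(st[keep, , drop = FALSE], as.data.frame(vals[keep, , drop = FALSE]))
  rownames(out) <- NULL
  prev_species <- intersect(attr(stations, "species"), names(out))
  structure(out, feature_names = feats, species = prev_species,
            n_dropped = n_dropped, class = c("station_table", "data.frame"))
}

#' @export
print.station_table <- function(x, ...) {
  sp <- attr(x, "species")
  cat(sprintf("<station_table> %d stations, %d features%s\n", nrow(x),
              length(attr(x, "feature_names")),
              if (length(sp)) paste0(", species: ", paste(sp, collapse = ", "))
              else ""))
  if (isTRUE(attr(x, "n_dropped") > 0))
    cat(sprintf("  (%d stations dropped off-grid/nodata)\n", attr(x, "n_dropped")))
  invisible(x)
}

## rank-free AUC via pROC (quiet, fixed direction: higher score = presence)
auc_of <- function(obs, prob) {
  as.numeric(pROC::auc(pROC::roc(response = obs, predictor = prob,
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

## stratified index split: fraction `frac` of each class into the train set
stratified_split <- function(y, frac) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, round(frac * length(idx)))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

## stratified fold labels 1..k
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a random-forest presence/absence model with a 70/30 holdout
#'
#' Stratified random 70/30 split; a 500-tree random-forest classifier
#' (`mtry = floor(sqrt(n_features))`) is fitted on the training portion, the
#' probability of presence predicted for the reserved 30%, and the holdout
#' AUC and residuals (observed - predicted probability; positive values are
#' underpredictions) computed.
#'
#' @param table a [station_table] containing the species column.
#' @param species species column name.
#' @param split_fraction training fraction (default 0.7).
#' @param seed integer seed.
#' @param source label for the bathymetry source the features came from.
#' @return An object of class `sdm_result` with the fitted model, holdout
#'   AUC, residuals, and the data needed for importance/partial-dependence.
#' @export
fit_rf <- function(table, species, split_fraction = 0.7, seed = 1L,
                   source = "dem") {
  feats <- attr(table, "feature_names")
  if (!(species %in% names(table))) stop("unknown species column: ", species)
  y <- table[[species]]
  if (length(unique(y)) < 2)
    stop("species '", species, "' has a single class; cannot model")
  if (sum(y == 1) < 35 || sum(y == 0) < 35)
    warning(sprintf("species '%s' has < 35 presences or absences (%d/%d); model may be unreliable",
                    species, sum(y == 1), sum(y == 0)))
  X <- as.data.frame(table)[, feats, drop = FALSE]
  yf <- factor(y, levels = c(0, 1))
  with_seed(seed, {
    train <- stratified_split(y, split_fraction)
    test <- setdiff(seq_along(y), train)
    rf <- randomForest::randomForest(x = X[train, , drop = FALSE],
                                     y = yf[train], ntree = 500,
                                     mtry = max(1L, floor(sqrt(length(feats)))))
    prob <- predict(rf, X[test, , drop = FALSE], type = "prob")[, "1"]
    structure(list(species = species, source = source, model = rf,
                   feature_names = feats, data = X, y = y,
                   train_idx = train, test_idx = test,
                   holdout_auc = auc_of(yf[test], prob),
                   residuals = y[test] - prob,
                   test_xy = as.data.frame(table)[test, c("x", "y")],
                   seed = as.integer(seed)),
              class = "sdm_result")
  })
}

#' @export
print.sdm_result <- function(x, ...) {
  cat(sprintf("<sdm_result> %s on '%s': holdout AUC %.3f (%d train / %d test, prevalence %.2f)\n",
              x$species, x$source, x$holdout_auc, length(x$train_idx),
              length(x$test_idx), mean(x$y)))
  invisible(x)
}

#' Stratified k-fold cross-validated AUC
#'
#' Stratified folds (each containing both classes); one random forest per
#' fold, AUC on each held-out fold.
#'
#' @param table a [station_table].
#' @param species species column name.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Numeric vector of fold AUCs with attribute `"mean_auc"`.
#' @export
cv_auc <- function(table, species, folds = 5L, seed = 1L) {
  feats <- attr(table, "feature_names")
  y <- table[[species]]
  if (min(table(y)) < folds)
    stop("class too rare to stratify into ", folds, " folds")
  X <- as.data.frame(table)[, feats, drop = FALSE]
  yf <- factor(y, levels = c(0, 1))
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      rf <- randomForest::randomForest(x = X[tr, , drop = FALSE], y = yf[tr],
                                       ntree = 500,
                                       mtry = max(1L, floor(sqrt(length(feats)))))
      prob <- predict(rf, X[!tr, , drop = FALSE], type = "prob")[, "1"]
      auc_of(yf[!tr], prob)
    }, numeric(1))
    structure(aucs, mean_auc = mean(aucs))
  })
}

#' Welch t-test between two sets of fold AUCs
#'
#' Two-sided Welch (unequal-variance) two-sample t-test, used to compare the
#' cross-validated accuracy of models built on different bathymetry sources.
#' Degenerate inputs (both samples constant and equal) return `t = 0, p = 1`.
#'
#' @param aucs_a,aucs_b equal-length numeric vectors of fold AUCs (>= 2).
#' @return list with `t_statistic`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_auc <- function(aucs_a, aucs_b) {
  if (length(aucs_a) != length(aucs_b) || length(aucs_a) < 2)
    stop("need two equal-length fold AUC vectors of length >= 2")
  res <- tryCatch(stats::t.test(aucs_a, aucs_b, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(aucs_a), mean(aucs_b))))
      return(list(t_statistic = 0, p_value = 1,
                  mean_a = mean(aucs_a), mean_b = mean(aucs_b)))
    stop("t-test failed on degenerate unequal inputs")
  }
  list(t_statistic = unname(res$statistic), p_value = res$p.value,
       mean_a = mean(aucs_a), mean_b = mean(aucs_b))
}

#' Permutation variable importance
#'
#' Mean drop in held-out AUC when a variable is permuted (10 permutations per
#' variable by default), measured on the holdout portion of a fitted
#' [fit_rf] model; model-agnostic and robust with correlated multi-scale
#' features.
#'
#' @param result an `sdm_result`.
#' @param n_perm permutations per variable.
#' @param seed integer seed.
#' @return data.frame of `variable`, `importance` (AUC drop), sorted
#'   descending.
#' @export
rf_importance <- function(result, n_perm = 10L, seed = 1L) {
  X <- result$data[result$test_idx, , drop = FALSE]
  yf <- factor(result$y[result$test_idx], levels = c(0, 1))
  base_prob <- predict(result$model, X, type = "prob")[, "1"]
  base_auc <- auc_of(yf, base_prob)
  with_seed(seed, {
    imp <- vapply(result$feature_names, function(v) {
      drops <- vapply(seq_len(n_perm), function(r) {
        Xp <- X
        Xp[[v]] <- sample(Xp[[v]])
        base_auc - auc_of(yf, predict(result$model, Xp, type = "prob")[, "1"])
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    out <- data.frame(variable = result$feature_names, importance = unname(imp))
    out[order(-out$importance), ]
  })
}

#' Partial dependence of the predicted probability on one variable
#'
#' Classical partial dependence: the variable is clamped to each grid value
#' (equally spaced quantiles between 2.5% and 97.5% of its observed
#' distribution) and the predicted probability averaged over the training
#' data.
#'
#' @param result an `sdm_result`.
#' @param variable feature name.
#' @param grid_points number of evaluation points.
#' @return data.frame with columns `value`, `response`.
#' @export
partial_dependence <- function(result, variable, grid_points = 20L) {
  if (!(variable %in% result$feature_names))
    stop("unknown variable: ", variable)
  X <- result$data[result$train_idx, , drop = FALSE]
  qs <- stats::quantile(X[[variable]], probs = seq(0.025, 0.975,
                                                   length.out = grid_points),
                        names = FALSE)
  resp <- vapply(qs, function(v) {
    Xc <- X
    Xc[[variable]] <- v
    mean(predict(result$model, Xc, type = "prob")[, "1"])
  }, numeric(1))
  data.frame(value = qs, response = resp)
}

#' Predict a probability-of-presence surface
#'
#' Evaluates the fitted model at every native-resolution cell, extracting
#' each layer by nearest cell at the cell centre; nodata in any feature
#' propagates to the output.
#'
#' @param result an `sdm_result`.
#' @param stack a [terrain_stack] providing all model features.
#' @return A [grid_surface] of probabilities in `[0, 1]`.
#' @export
predict_surface <- function(result, stack) {
  missing <- setdiff(result$feature_names, names(stack$layers))
  if (length(missing))
    stop("stack is missing model feature(s): ", paste(missing, collapse = ", "))
  base <- stack$layers[["depth"]]
  cc <- grid_centres(base)
  pts <- data.frame(x = as.vector(cc$X), y = as.vector(cc$Y))
  feat <- matrix(NA_real_, nrow(pts), length(result$feature_names),
                 dimnames = list(NULL, result$feature_names))
  for (nm in result$feature_names) {
    g <- stack$layers[[nm]]
    rc <- grid_rowcol(g, pts$x, pts$y)
    ok <- !is.na(rc[, "row"])
    feat[ok, nm] <- g$values[rc[ok, , drop = FALSE]]
  }
  ok <- rowSums(is.na(feat)) == 0L
  prob <- rep(NA_real_, nrow(pts))
  if (any(ok))
    prob[ok] <- predict(result$model, as.data.frame(feat[ok, , drop = FALSE]),
                        type = "prob")[, "1"]
  grid_surface(matrix(prob, base$nrows, base$ncols), origin_x = base$origin_x,
               origin_y = base$origin_y, cell = base$cell,
               crs_label = base$crs_label)
}
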