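#' Default experiment configuration
#'
#' Returns the full experiment configuration as a nested list: the synthetic
#' scenario and survey design, QC parameters, interpolation search grids
#' (IDW powers 0.5-6 by 0.5 with 50/100/150-point neighbourhoods, RBF CRS and
#' multiquadric with shape/ridge grids, kriging with 100/150 neighbourhoods),
#' the terrain resolution ladder, distance bands, species set and SDM
#' settings. Any subset can be overridden from a YAML file; unspecified
#' entries keep these defaults.
#'
#' @param seed master seed for the experiment.
#' @return Nested configuration list.
#' @export
default_experiment_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(
      scenario = list(extent_x = 35000, extent_y = 5000, cell = 25,
                      depth_at_shore = 20, depth_gradient = 110 / 5000,
                      field_sill = 4, field_range_major = 600,
                      anisotropy_angle = 90, anisotropy_ratio = 0.5,
                      nugget = 0.01),
      design = list(transect_spacing = 500, along_track_spacing = 40,
                    depth_noise_sd = 0.2, spike_rate = 0.002,
                    spike_magnitude = 25, tide_amplitude = 0.8,
                    tide_period = 12.42, vessel_speed = 2.5),
      stations = list(n = 500, min_separation = 200)),
    qc = list(block_k = 1, despike_window = 5, despike_factor = 6),
    variogram = list(lag_width = 50, max_lag = 1500,
                     directions = c(0, 45, 90, 135), anisotropic = TRUE,
                     detrend_degree = 1),
    interpolation = list(
      idw = list(powers = seq(0.5, 6, by = 0.5), neighborhoods = c(50, 100, 150)),
      rbf = list(bases = c("crs", "m"), neighborhoods = c(50, 100, 150),
                 delta_crs = c(0.001, 0.02, 0.1), delta_m = c(1, 5, 20),
                 robustness = c(0, 0.01, 0.1)),
      kriging = list(trend_degrees = c(0, 1, 2), neighborhoods = c(100, 150)),
      loocv_max_points = 2000),
    terrain = list(resolution_multipliers = c(1, 3, 5, 8)),
    bands = list(c(0, 100), c(100, 200), c(200, 300), c(300, 400)),
    species = list(
      list(name = "depth_specialist", beta_depth = 6, depth_opt = NA,
           depth_tol = 15, target_prevalence = 0.3),
      list(name = "generalist", beta_depth = 0, target_prevalence = 0.7)),
    sdm = list(folds = 5, split_fraction = 0.7, importance_permutations = 10))
}

## Recursive override of defaults by a user config list.
merge_config <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]])
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; entries override [default_experiment_config].
#' @return Full configuration list.
#' @export
read_experiment_config <- function(path) {
  user <- yaml::read_yaml(path)
  seed <- if (!is.null(user$seed)) user$seed else 1L
  merge_config(default_experiment_config(seed), user)
}

config_hash <- function(cfg, stage) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  writeLines(c(stage, js), f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

## Stage cache: recompute unless an RDS keyed by the config hash exists.
stage_cached <- function(outdir, name, hash, compute, log = TRUE) {
  cache <- file.path(outdir, "cache")
  dir.create(cache, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(cache, paste0(name, "_", substr(hash, 1, 12), ".rds"))
  if (file.exists(f)) {
    if (log) message(sprintf("[%s] cache hit (%s)", name, basename(f)))
    return(readRDS(f))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- compute()
  saveRDS(res, f)
  if (log) message(sprintf("[%s] computed in %.1f s", name,
                           proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full synthetic SBES-vs-reference experiment
#'
#' Orchestrates every stage from one configuration: synthetic seafloor and
#' survey, sounding QC, variogram fitting, LOOCV over the configured
#' interpolator grids with selection of the best method per family, DEM
#' production, multi-resolution terrain stacks for the reference and each
#' interpolated DEM, distance-banded surface agreement, species simulation,
#' and random-forest SDMs per species and bathymetry source with fold-AUC
#' comparison. All stage outputs are written under `outdir` (tables as CSV,
#' rasters as ESRI ASCII, a JSON manifest with file hashes); stages are
#' cached keyed by the configuration hash, so a rerun with an unchanged
#' configuration reloads bit-identical results.
#'
#' @param config configuration list (see [default_experiment_config]) or a
#'   path to a YAML file.
#' @param outdir output directory.
#' @param quiet suppress stage log messages.
#' @return An `experiment_report` list: `selection` (CV selection), `bands`
#'   (band-comparison table), `aucs` (per species x source fold AUCs),
#'   `comparisons` (Welch tests reference vs each source), `importance`,
#'   `summary` (sounding QC summary), `variogram`, `manifest`.
#' @export
run_experiment <- function(config = default_experiment_config(), outdir,
                           quiet = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- !quiet
  seed <- config$seed
  sc_cfg <- config$synth$scenario

  ## -- synthetic truth -----------------------------------------------------
  synth <- stage_cached(outdir, "synth", config_hash(config["synth"], seed), function() {
    scen <- do.call(seafloor_scenario, c(sc_cfg, list(seed = derive_seed(seed, "seafloor"))))
    dem <- generate_seafloor(scen)
    des <- do.call(survey_design, config$synth$design)
    svy <- sample_survey(dem, des, seed = derive_seed(seed, "survey"))
    stn <- sample_stations(sc_cfg$extent_x, sc_cfg$extent_y,
                           n = config$synth$stations$n,
                           min_separation = config$synth$stations$min_separation,
                           seed = derive_seed(seed, "stations"))
    stn$id <- seq_len(nrow(stn))
    list(scenario = scen, dem = dem, survey = svy, stations = stn)
  }, log)
  write_esri_ascii(synth$dem, file.path(outdir, "reference_dem.asc"))
  write_soundings_csv(synth$survey$soundings, file.path(outdir, "soundings_raw.csv"))
  write_tide_csv(synth$survey$tide, file.path(outdir, "tide.csv"))
  write_tracks_wkt(synth$survey$tracks, file.path(outdir, "tracks.wkt"))
  utils::write.csv(synth$stations, file.path(outdir, "stations.csv"),
                   row.names = FALSE)

  ## -- QC -------------------------------------------------------------------
  qc <- stage_cached(outdir, "qc", config_hash(config[c("synth", "qc")], seed), function() {
    s <- synth$survey$soundings
    if (config$qc$block_k > 1) s <- block_average(s, config$qc$block_k)
    s <- tide_correct(s, synth$survey$tide)
    s <- despike(s, config$qc$despike_window, config$qc$despike_factor)
    list(soundings = s, summary = summarize_soundings(s))
  }, log)
  write_soundings_csv(qc$soundings, file.path(outdir, "soundings_qc.csv"))

  ## -- variogram -------------------------------------------------------------
  vg <- stage_cached(outdir, "variogram",
                     config_hash(config[c("synth", "qc", "variogram")], seed), function() {
    emp <- empirical_variogram(qc$soundings, lag_width = config$variogram$lag_width,
                               max_lag = config$variogram$max_lag,
                               directions = config$variogram$directions,
                               detrend_degree = config$variogram$detrend_degree)
    fit <- fit_variogram(emp, anisotropic = isTRUE(config$variogram$anisotropic))
    list(empirical = emp, model = fit)
  }, log)
  jsonlite::write_json(unclass(vg$model), file.path(outdir, "variogram.json"),
                       auto_unbox = TRUE, digits = NA)

  ## -- LOOCV over all interpolator configurations ---------------------------
  sel <- stage_cached(outdir, "selection",
                      config_hash(config[c("synth", "qc", "variogram", "interpolation")], seed),
                      function() {
    s <- qc$soundings
    cap <- config$interpolation$loocv_max_points
    if (nrow(s) > cap) {
      idx <- with_seed(derive_seed(seed, "loocv_subsample"),
                       sort(sample.int(nrow(s), cap)))
      s <- ss_update(as.data.frame(s)[idx, , drop = FALSE], s,
                     sprintf("loocv_subsample(n=%d)", cap))
    }
    configs <- list()
    ic <- config$interpolation
    for (p in ic$idw$powers) for (k in ic$idw$neighborhoods)
      configs <- c(configs, list(interp_config("idw", power = p, n_neighbors = k)))
    for (b in ic$rbf$bases) for (k in ic$rbf$neighborhoods) {
      dg <- if (b == "crs") ic$rbf$delta_crs else ic$rbf$delta_m
      opt <- optimize_rbf(s, basis = b, n_neighbors = k, delta_grid = dg,
                          robustness_grid = ic$rbf$robustness,
                          max_points = min(cap, 500L),
                          seed = derive_seed(seed, "rbf_opt"))
      configs <- c(configs, list(opt))
    }
    for (d in ic$kriging$trend_degrees) for (k in ic$kriging$neighborhoods)
      configs <- c(configs, list(
        interp_config(c("ok", "uk1", "uk2")[d + 1], n_neighbors = k,
                      variogram = vg$model)))
    reports <- lapply(configs, function(cf) loocv(s, cf))
    select_best(reports)
  }, log)
  utils::write.csv(sel$table, file.path(outdir, "cv_selection.csv"),
                   row.names = FALSE)

  ## -- DEMs from the best configuration per family ---------------------------
  dems <- stage_cached(outdir, "dems",
                       config_hash(config[c("synth", "qc", "variogram", "interpolation")],
                                   paste0(seed, "dems")), function() {
    out <- list()
    for (fam in names(sel$best_per_family)) {
      cfg <- sel$best_per_family[[fam]]$config
      res <- interpolate_grid(qc$soundings, synth$dem, cfg)
      out[[fam]] <- if (is.list(res) && !inherits(res, "grid_surface"))
        res$prediction else res
    }
    out
  }, log)
  for (fam in names(dems))
    write_esri_ascii(dems[[fam]], file.path(outdir, paste0("dem_", fam, ".asc")))

  ## -- terrain stacks ---------------------------------------------------------
  stacks <- stage_cached(outdir, "terrain",
                         config_hash(config[c("synth", "qc", "interpolation", "terrain")],
                                     seed), function() {
    resol <- sc_cfg$cell * config$terrain$resolution_multipliers
    st <- list(reference = build_stack(synth$dem, resol, "reference"))
    for (fam in names(dems))
      st[[fam]] <- build_stack(dems[[fam]], resol, fam)
    st
  }, log)

  ## -- surface agreement by distance band ------------------------------------
  bands_tab <- stage_cached(outdir, "bands",
                            config_hash(config, paste0(seed, "bands")), function() {
    dist <- distance_to_track(synth$dem, synth$survey$tracks)
    rows <- lapply(names(dems), function(fam) {
      bc <- band_compare(dems[[fam]], synth$dem, dist, config$bands)
      overall <- surface_compare(dems[[fam]], synth$dem)
      bc$source <- fam
      bc$overall_r2 <- overall$r2
      bc$overall_rmse <- overall$rmse
      bc
    })
    do.call(rbind, rows)
  }, log)
  utils::write.csv(bands_tab, file.path(outdir, "band_comparison.csv"),
                   row.names = FALSE)

  ## -- species simulation + SDM comparison ------------------------------------
  sdm_res <- stage_cached(outdir, "sdm", config_hash(config, paste0(seed, "sdm")),
                          function() {
    ref_tab <- extract_features(stacks$reference, synth$stations)
    deep_default <- stats::quantile(ref_tab$depth, 0.85, names = FALSE)
    sp_tabs <- ref_tab
    species_names <- character(0)
    for (sp in config$species) {
      opt <- sp$depth_opt
      if (is.null(opt) || is.na(opt)) opt <- deep_default
      par <- species_params(sp$name,
                            depth_opt = opt,
                            depth_tol = if (is.null(sp$depth_tol)) 15 else sp$depth_tol,
                            beta_depth = if (is.null(sp$beta_depth)) 0 else sp$beta_depth,
                            target_prevalence = sp$target_prevalence)
      sp_tabs <- simulate_species(stacks$reference, sp_tabs, par,
                                  seed = derive_seed(seed, paste0("species_", sp$name)))
      species_names <- c(species_names, sp$name)
    }
    auc_rows <- list(); cmp_rows <- list(); importances <- list()
    fold_sets <- list()
    for (sp in species_names) {
      for (src in names(stacks)) {
        tab <- extract_features(stacks[[src]], synth$stations)
        tab <- merge_species(tab, sp_tabs, sp)
        aucs <- cv_auc(tab, sp, folds = config$sdm$folds,
                       seed = derive_seed(seed, paste0("cv_", sp, "_", src)))
        fold_sets[[paste(sp, src, sep = "|")]] <- as.numeric(aucs)
        auc_rows[[paste(sp, src)]] <- data.frame(
          species = sp, source = src, mean_auc = attr(aucs, "mean_auc"),
          t(as.numeric(aucs)))
        if (src == "reference") {
          fit <- fit_rf(tab, sp, split_fraction = config$sdm$split_fraction,
                        seed = derive_seed(seed, paste0("rf_", sp)),
                        source = src)
          imp <- rf_importance(fit, n_perm = config$sdm$importance_permutations,
                               seed = derive_seed(seed, paste0("imp_", sp)))
          imp$species <- sp
          importances[[sp]] <- imp
        }
      }
      for (src in setdiff(names(stacks), "reference")) {
        cmp <- compare_auc(fold_sets[[paste(sp, "reference", sep = "|")]],
                           fold_sets[[paste(sp, src, sep = "|")]])
        cmp_rows[[paste(sp, src)]] <- data.frame(
          species = sp, source = src, t_statistic = cmp$t_statistic,
          p_value = cmp$p_value, mean_auc_reference = cmp$mean_a,
          mean_auc_source = cmp$mean_b)
      }
    }
    list(aucs = do.call(rbind, auc_rows),
         comparisons = do.call(rbind, cmp_rows),
         importance = do.call(rbind, importances),
         station_table = sp_tabs)
  }, log)
  utils::write.csv(sdm_res$aucs, file.path(outdir, "auc_table.csv"),
                   row.names = FALSE)
  utils::write.csv(sdm_res$comparisons, file.path(outdir, "auc_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(sdm_res$importance, file.path(outdir, "importance.csv"),
                   row.names = FALSE)

  ## -- manifest ---------------------------------------------------------------
  arts <- list.files(outdir, pattern = "\\.(csv|asc|json|wkt)$", full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest <- list(config_hash = config_hash(config, "experiment"),
                   seed = seed,
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   package_version = as.character(utils::packageVersion("bathysdm")),
                   files = as.list(tools::md5sum(arts)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(selection = sel, bands = bands_tab, aucs = sdm_res$aucs,
                 comparisons = sdm_res$comparisons,
                 importance = sdm_res$importance, summary = qc$summary,
                 variogram = vg$model, manifest = manifest, outdir = outdir),
            class = "experiment_report")
}

## Attach the simulated presence column of `sp` from the reference station
## table onto a per-source feature table, matching stations by id.
merge_species <- function(tab, sp_tabs, sp) {
  m <- match(tab$id, sp_tabs$id)
  keep <- !is.na(m)
  out <- as.data.frame(tab)[keep, , drop = FALSE]
  out[[sp]] <- sp_tabs[[sp]][m[keep]]
  structure(out, feature_names = attr(tab, "feature_names"),
            species = unique(c(attr(tab, "species"), sp)),
            n_dropped = attr(tab, "n_dropped") + sum(!keep),
            class = c("station_table", "data.frame"))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  soundings after QC: n = %d, mean depth %.2f m, skewness %.3f\n",
              x$summary$n, x$summary$mean, x$summary$skewness))
  cat(sprintf("  best interpolator: %s (RMSE %.4f m)\n",
              x$selection$best$label, x$selection$best$rmse))
  cat(sprintf("  SDM mean AUCs:\n"))
  for (r in seq_len(nrow(x$aucs)))
    cat(sprintf("    %-18s %-10s %.3f\n", x$aucs$species[r], x$aucs$source[r],
                x$aucs$mean_auc[r]))
  invisible(x)
}
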