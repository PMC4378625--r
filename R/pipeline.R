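## Pipeline plumbing: run configuration, provenance-stamped CSV I/O, and the
## simulate -> extract -> fit -> report workflow wiring the modules
## together. Every output table carries a provenance header (configuration
## hash and seed) so a run can be reproduced byte for byte.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with defaults. Calibration
#' defaults are the camera constants (side factor 0.273 mm2/px, top-view
#' factor `9.937e-5 * Y_ax + 0.061936` mm2/px); segmentation defaults use a
#' radius-1 disc for erosion and dilation and a 5-pixel minimum component;
#' hue bands default to green `[80, 160)` and yellow `[40, 80)` degrees.
#'
#' @param n_plants number of plants simulated.
#' @param n_timepoints imaged timepoints per plant.
#' @param model_name generating growth model for the simulated trajectories.
#' @param params generating parameters (leaf area, mm2).
#' @param times observation days.
#' @param noise_cv trajectory noise coefficient of variation.
#' @param candidates candidate models for selection.
#' @param band_draws draws for population prediction intervals.
#' @param seed master seed; all stage seeds derive from it.
#' @param calibration a [camera_calibration()].
#' @param segmentation list with `erosion_radius`, `dilation_radius`,
#'   `min_component_px`.
#' @param bands a [hue_bands()].
#' @param rolling_loss mean proportional afternoon area loss for the
#'   diurnal simulation.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_plants = 4L, n_timepoints = 4L,
                       model_name = "logistic3",
                       params = list(Asym = 3000, tmid = 35, k = 5),
                       times = seq(14, 42, by = 2),
                       noise_cv = 0.05,
                       candidates = c("exponential", "power_law",
                                      "logistic3", "gompertz"),
                       band_draws = 300L,
                       seed = 20110301L,
                       calibration = camera_calibration(),
                       segmentation = list(erosion_radius = 1,
                                           dilation_radius = 1,
                                           min_component_px = 5),
                       bands = hue_bands(),
                       rolling_loss = 0.22) {
  candidates <- match.arg(candidates, growth_model_names(), several.ok = TRUE)
  model_name <- match.arg(model_name, growth_model_names())
  check_growth_params(model_name, params)
  cfg <- list(n_plants = as.integer(n_plants),
              n_timepoints = as.integer(n_timepoints),
              model_name = model_name, params = params, times = times,
              noise_cv = noise_cv, candidates = candidates,
              band_draws = as.integer(band_draws), seed = as.integer(seed),
              calibration = calibration, segmentation = segmentation,
              bands = bands, rolling_loss = rolling_loss)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields override the [run_config()] defaults; unknown keys are an
#' error so typos fail before any stage runs.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(unclass(config)), collapse = ""))
}

#' Write a data.frame as CSV with a provenance header
#'
#' @param df data.frame.
#' @param path output path.
#' @param config the `run_config` of the producing run (hashed into the
#'   header), or `NULL`.
#' @param seed the seed recorded in the header.
#' @return invisibly, `path`.
#' @export
write_provenance_csv <- function(df, path, config = NULL, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- if (is.null(config)) "none" else config_hash(config)
  writeLines(sprintf("# phenoshoot config_hash=%s seed=%s", hash, seed), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-stamped CSV
#'
#' @param path CSV path written by [write_provenance_csv()].
#' @return data.frame; the provenance line is attached as attribute
#'   `provenance`.
#' @export
read_provenance_csv <- function(path) {
  lines <- readLines(path)
  prov <- grep("^#", lines, value = TRUE)
  df <- read.csv(text = paste(grep("^#", lines, value = TRUE,
                                   invert = TRUE), collapse = "\n"))
  attr(df, "provenance") <- prov
  df
}

stage_log <- function(logenv, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  logenv$lines <- c(logenv$lines, line)
  invisible(line)
}

#' Run the full phenotyping pipeline
#'
#' Executes simulate -> extract -> fit -> report:
#' \enumerate{
#'   \item \strong{simulate}: growth trajectories from the configured model,
#'     one rendered image set per plant per timepoint (plant geometry scaled
#'     to the trajectory), diurnal leaf-area pairs and a watering log;
#'   \item \strong{extract}: segmentation of every image set and the full
#'     trait record, including the calibrated projected leaf area;
#'   \item \strong{fit}: candidate growth models fitted to the pooled
#'     trajectories with robustness screening, AIC ranking and population
#'     prediction intervals for the selected model;
#'   \item \strong{report}: per-plant RGR variants, the leaf-rolling
#'     statistic, water-use efficiency, and the validation regression of
#'     pipeline-projected against ground-truth drawn area.
#' }
#' A stage failure halts the run with a stage-named error; outputs of
#' completed stages remain on disk.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for the CSV artifacts.
#' @return invisibly, a list with the stage outputs (`traits`, `series`,
#'   `selection`, `band`, `report`) and the log lines.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("pheno_")) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logenv <- new.env(parent = emptyenv())
  logenv$lines <- character(0)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  ## --- simulate ---------------------------------------------------------
  sim <- run_stage("simulate", {
    tspec <- trajectory_spec(config$model_name, config$params, config$times,
                             noise_cv = config$noise_cv,
                             n_plants = config$n_plants, seed = config$seed)
    series <- generate_growth_series(tspec)
    t_img <- round(seq(1, length(config$times),
                       length.out = config$n_timepoints))
    sets <- list(); meta <- list()
    for (i in seq_len(config$n_plants)) {
      pid <- sprintf("plant_%03d", i)
      for (j in t_img) {
        sz <- series$value[series$plant_id == pid][j]
        ## geometry scales with the trajectory: leaf length ~ sqrt(area)
        spec <- plant_spec(
          n_leaves = 4L + (j %/% 2L),
          leaf_length_px = max(12L, round(sqrt(sz))),
          leaf_width_px = 5,
          stem_height_px = max(20L, round(1.6 * sqrt(sz))),
          ligule_height_px = max(8L, round(0.5 * sqrt(sz))),
          senescent_fraction = 0.04,
          seed = config$seed + 1000L * i + j)
        key <- sprintf("%s_t%02d", pid, j)
        sets[[key]] <- generate_plant_images(spec)
        meta[[key]] <- data.frame(plant_id = pid, time = config$times[j])
      }
    }
    diurnal <- with_seed(config$seed + 77L, {
      loss <- pmin(0.9, pmax(0, rnorm(config$n_plants, config$rolling_loss,
                                      0.01)))
      generate_diurnal_pair(
        area_predawn = 1000 + 150 * seq_len(config$n_plants), loss)
    })
    water <- with_seed(config$seed + 78L, generate_watering_log(
      daily_transpiration = pmax(0, rnorm(28, 60, 8)), evaporation = 12,
      n_days = 28))
    write_provenance_csv(series, file.path(out_dir, "trajectories.csv"),
                         config, config$seed)
    write_provenance_csv(diurnal, file.path(out_dir, "diurnal_pairs.csv"),
                         config, config$seed)
    write_provenance_csv(water, file.path(out_dir, "watering_log.csv"),
                         config, config$seed)
    stage_log(logenv, "simulate",
                      sprintf("%d plants, %d trajectories rows, %d image sets",
                              config$n_plants, nrow(series), length(sets)))
    list(series = series, sets = sets, meta = meta, diurnal = diurnal,
         water = water)
  })

  ## --- extract ----------------------------------------------------------
  traits <- run_stage("extract", {
    rows <- lapply(names(sim$sets), function(key) {
      set <- sim$sets[[key]]
      masks <- segment_image_set(
        set,
        erosion_radius = config$segmentation$erosion_radius,
        dilation_radius = config$segmentation$dilation_radius,
        min_component_px = config$segmentation$min_component_px)
      for (v in names(masks)) if (masks[[v]]$empty)
        stage_log(logenv, "extract",
                          sprintf("%s/%s: empty mask flagged", key, v))
      tr <- shoot_traits(masks, set, config$calibration, config$bands)
      truth_masks <- lapply(names(set$masks), function(v)
        plant_mask(set$masks[[v]], v))
      names(truth_masks) <- names(set$masks)
      drawn <- projected_leaf_area(truth_masks$top, truth_masks$side0,
                                   truth_masks$side90, config$calibration)
      cbind(sim$meta[[key]], tr, drawn_area = drawn)
    })
    out <- do.call(rbind, rows)
    write_provenance_csv(out, file.path(out_dir, "traits.csv"),
                         config, config$seed)
    stage_log(logenv, "extract", sprintf("%d trait rows", nrow(out)))
    out
  })

  ## --- fit --------------------------------------------------------------
  fit_out <- run_stage("fit", {
    sel <- select_growth_model(list(all = sim$series),
                               candidates = config$candidates,
                               band_draws = config$band_draws,
                               seed = config$seed)
    for (m in sel$report$model[!sel$report$robust])
      stage_log(logenv, "fit", sprintf("%s: non-convergence recorded", m))
    best <- sel$fits[[sel$selected]][["all"]]
    band <- prediction_band(best, config$times, n_draws = config$band_draws,
                            seed = config$seed)
    write_provenance_csv(sel$report, file.path(out_dir, "model_selection.csv"),
                         config, config$seed)
    write_provenance_csv(band, file.path(out_dir, "prediction_band.csv"),
                         config, config$seed)
    stage_log(logenv, "fit", sprintf("selected %s", sel$selected))
    list(selection = sel, band = band)
  })

  ## --- report -----------------------------------------------------------
  report <- run_stage("report", {
    rv <- rgr_variants(sim$series)
    roll <- leaf_rolling(sim$diurnal)
    wu <- wue(final_biomass_g = 6.4, water_log = sim$water)
    vp <- validate_projection(traits$projected_leaf_area, traits$drawn_area)
    summary_df <- data.frame(
      quantity = c("mean_rgr_individual", "mean_rgr_leaf_area",
                   "leaf_rolling_pct", "leaf_rolling_p", "wue_g_per_kg",
                   "projection_slope", "projection_r2", "selected_model"),
      value = c(mean(rv$rgr_individual), mean(rv$rgr_leaf_area),
                roll$mean_pct_increase, roll$p_value, wu$wue_g_per_kg,
                vp$slope, vp$r2, fit_out$selection$selected))
    write_provenance_csv(rv, file.path(out_dir, "rgr_variants.csv"),
                         config, config$seed)
    write_provenance_csv(summary_df, file.path(out_dir, "report.csv"),
                         config, config$seed)
    stage_log(logenv, "report", "summary written")
    list(rgr_variants = rv, rolling = roll, wue = wu, projection = vp,
         summary = summary_df)
  })

  writeLines(logenv$lines, file.path(out_dir, "pipeline.log"))
  invisible(list(traits = traits, series = sim$series,
                 selection = fit_out$selection, band = fit_out$band,
                 report = report, log = logenv$lines, out_dir = out_dir))
}
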