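#' End-to-end pipeline configuration
#'
#' Bundles the settings of all stages: cohort generation, phantom
#' construction, quantification, calibration and agreement. Phantoms default
#' to a small grid so a full run stays desk-scale; the phantom target
#' fraction for each animal is its drawn adipose fraction.
#'
#' @param n cohort size
#' @param seed master seed; per-stage seeds are derived from it
#' @param cohort a [cohort_params()] object
#' @param phantom_grid grid shape (slices, rows, cols) used per animal
#' @param fp_plan false-positive classes injected into each phantom
#' @param fp_mode `"oracle"` or `"rules"` false-positive removal
#' @param hu_range_override optional c(hu_min, hu_max) to use instead of the
#'   adipose truncation range of the phantom HU model
#' @param candidates impedance index candidates for model selection
#' @param split_seed seed of the 2/3-1/3 split (default derived from `seed`)
#' @param multiplier,power,alpha agreement settings
#' @param out_dir output directory (created if needed)
#' @param quiet suppress stage log messages
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(n = 30, seed = 1, cohort = cohort_params(),
                            phantom_grid = c(64L, 48L, 48L),
                            fp_plan = c("A", "B", "C", "D", "table"),
                            fp_mode = c("oracle", "rules"),
                            hu_range_override = NULL,
                            candidates = c("SCL2/R50", "CCL2/R50",
                                           "SCL2/Rinf", "SCL2/R0"),
                            split_seed = NULL,
                            multiplier = 1.96, power = 0.80, alpha = 0.05,
                            out_dir = tempfile("turtlebis_run_"),
                            quiet = FALSE) {
  fp_mode <- match.arg(fp_mode)
  if (!is.numeric(seed) || seed != floor(seed)) stopf("`seed` must be an integer")
  structure(list(n = n, seed = as.integer(seed), cohort = cohort,
                 phantom_grid = as.integer(phantom_grid), fp_plan = fp_plan,
                 fp_mode = fp_mode, hu_range_override = hu_range_override,
                 candidates = candidates,
                 split_seed = if (is.null(split_seed)) as.integer(seed) + 1L
                              else as.integer(split_seed),
                 multiplier = multiplier, power = power, alpha = alpha,
                 out_dir = out_dir, quiet = quiet),
            class = "pipeline_config")
}

pipe_log <- function(config, stage, fmt, ...) {
  if (!isTRUE(config$quiet))
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(config, stage, fun) {
  tryCatch(fun(), error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full calibration pipeline
#'
#' Executes the five stages end to end: (1) simulate a cohort,
#' (2) build one CT phantom per animal at its drawn adipose fraction and
#' regenerate the animal's impedance from the phantom's voxelized truth (so
#' BIS and CT describe the same body), (3) quantify adipose tissue from each
#' phantom by HU thresholding plus false-positive removal, (4) calibrate the
#' nonadipose-mass model on a seeded 2/3 split with AICc selection among the
#' candidate indices, and (5) run the agreement battery of the test-set
#' predictions against the CT reference. All artifacts (cohort CSV, NIfTI
#' volumes and label masks, model and agreement JSON, report) are written to
#' `config$out_dir` with a manifest of MD5 checksums; runs are reproducible
#' from (config, seed).
#'
#' @param config a [pipeline_config()]
#' @return a list of class `pipeline_result`: `manifest`, `cohort`,
#'   `quantified`, `ranking`, `split`, `agreement` (kg and percent scale),
#'   `report`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  art <- function(name) file.path(config$out_dir, name)

  # stage 1: cohort
  cohort <- run_stage(config, "simulate-cohort", function() {
    generate_cohort(config$n, config$cohort, seed = config$seed)
  })
  write_cohort(cohort, art("cohort.csv"))
  stages$`simulate-cohort` <- "cohort.csv"
  pipe_log(config, "simulate-cohort", "n = %d animals", nrow(cohort))

  # stage 2: phantoms + impedance consistent with voxelized truth
  phantoms <- run_stage(config, "simulate-ct", function() {
    lapply(seq_len(nrow(cohort)), function(i) {
      build_phantom(phantom_spec(
        grid_shape = config$phantom_grid,
        target_at_fraction = cohort$true_at_fraction[i],
        fp_plan = config$fp_plan,
        hu_model = config$cohort_hu_model %||% default_hu_model(),
        seed = config$seed * 1000L + i))
    })
  })
  f_vox <- vapply(phantoms, function(p) p$truth$true_at_fraction_voxelized, 0)
  cohort <- run_stage(config, "simulate-ct", function() {
    regenerate_impedance(cohort, f_vox, config$cohort,
                         seed = config$seed + 7L)
  })
  vol_files <- character(0)
  for (i in seq_along(phantoms)) {
    vf <- sprintf("volume_%03d.nii", i)
    mf <- sprintf("truth_%03d.nii", i)
    write_ct_volume(phantoms[[i]]$volume, art(vf))
    write_mask_labels(phantoms[[i]]$truth, art(mf))
    vol_files <- c(vol_files, vf, mf)
  }
  write_cohort(cohort, art("cohort.csv"))
  stages$`simulate-ct` <- vol_files
  pipe_log(config, "simulate-ct", "%d phantoms on a %s grid",
           length(phantoms), paste(config$phantom_grid, collapse = "x"))

  # stage 3: quantification
  quantified <- run_stage(config, "quantify-ct", function() {
    rng <- if (!is.null(config$hu_range_override)) {
      hu_range(config$hu_range_override[1], config$hu_range_override[2])
    } else {
      ar <- (config$cohort_hu_model %||% default_hu_model())$adipose$range
      hu_range(ar[1], ar[2])
    }
    lapply(seq_along(phantoms), function(i) {
      ph <- phantoms[[i]]
      cand <- threshold_segment(ph$volume, rng)
      masks <- remove_false_positives(
        cand, volume = ph$volume, mode = config$fp_mode,
        truth = ph$truth, git_mask = ph$truth$git_region)
      if (config$fp_mode == "rules") # keep table/outside removals honest
        masks$final_adipose <- masks$final_adipose & ph$truth$body_mask
      quantify(masks, ph$truth$body_mask, ph$volume, cohort$body_mass[i])
    })
  })
  cohort$at_fraction_ct <- vapply(quantified, `[[`, 0, "at_fraction")
  cohort$nonat_ct <- vapply(quantified, `[[`, 0, "nonat_mass")
  write_cohort(cohort, art("cohort.csv"))
  comp <- data.frame(id = cohort$id,
                     at_fraction = cohort$at_fraction_ct,
                     at_mass = vapply(quantified, `[[`, 0, "at_mass"),
                     nonat_mass = cohort$nonat_ct)
  jsonlite::write_json(comp, art("composition.json"), digits = NA)
  stages$`quantify-ct` <- c("cohort.csv", "composition.json")
  pipe_log(config, "quantify-ct", "mode = %s, mean adipose fraction %.3f",
           config$fp_mode, mean(cohort$at_fraction_ct))

  # stage 4: calibration with split validation
  ranking <- run_stage(config, "calibrate", function() {
    select_model(cohort, config$candidates)
  })
  split <- run_stage(config, "calibrate", function() {
    split_validate(cohort, ranking$models[[1]]$index_spec,
                   seed = config$split_seed)
  })
  models_json <- lapply(ranking$models, function(m)
    m[c("index_spec", "coefficients", "r2", "rmse", "f_stat", "aicc", "n_fit")])
  jsonlite::write_json(models_json, art("models.json"), digits = NA,
                       auto_unbox = TRUE)
  stages$calibrate <- "models.json"
  pipe_log(config, "calibrate", "best index %s (AICc %.1f), split %d/%d",
           ranking$models[[1]]$index_spec, ranking$models[[1]]$aicc,
           length(split$fit_ids), nrow(cohort))

  # stage 5: agreement of test-set predictions vs CT reference
  agreement <- run_stage(config, "agree", function() {
    per_candidate <- lapply(config$candidates, function(spec) {
      sv <- split_validate(cohort, spec, seed = config$split_seed)
      tp <- sv$test_predictions
      kg <- agreement_report(tp$at_mass_ref, tp$at_mass_pred,
                             config$multiplier, config$alpha, config$power)
      pct <- agreement_report(100 * tp$at_mass_ref / tp$body_mass,
                              100 * tp$at_mass_pred / tp$body_mass,
                              config$multiplier, config$alpha, config$power)
      list(index_spec = parse_index_spec(spec)$label, model = sv$model,
           kg = kg, pct = pct)
    })
    names(per_candidate) <- vapply(per_candidate, `[[`, "", "index_spec")
    per_candidate
  })
  report <- write_report(agreement, art("report"))
  stages$agree <- c("report.json", "report.txt")
  pipe_log(config, "agree", "best-index bias %.3f kg, LOA [%.3f, %.3f]",
           agreement[[1]]$kg$ba$bias, agreement[[1]]$kg$ba$loa_lower,
           agreement[[1]]$kg$ba$loa_upper)

  files <- unique(unlist(stages))
  manifest <- list(
    package_version = as.character(utils::packageVersion("turtleBIS")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[c("n", "phantom_grid", "fp_plan", "fp_mode", "candidates",
                      "split_seed", "multiplier", "power", "alpha")],
    stages = lapply(stages, function(f)
      as.list(tools::md5sum(file.path(config$out_dir, f)))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  structure(list(manifest = manifest, cohort = cohort,
                 quantified = quantified, ranking = ranking, split = split,
                 agreement = agreement, report = report,
                 out_dir = config$out_dir),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabular agreement report
#'
#' One row per index candidate with the published table's column set, on
#' both kg and percent scales, rounded to 2 decimals as printed. Written as
#' plain text and JSON (the JSON keeps full precision and round-trips
#' exactly).
#'
#' @param results named list of per-candidate results (each with `model`,
#'   `kg`, `pct` agreement reports), as produced by [run_pipeline()]
#' @param path_base output path without extension (writes `.txt` and
#'   `.json`); NULL to skip writing
#' @return the report data.frame (full precision), invisibly when written
#' @export
write_report <- function(results, path_base = NULL) {
  if (length(results) == 0) stopf("empty results")
  rows <- lapply(results, function(r) {
    co <- r$model$coefficients
    data.frame(
      index_spec = r$index_spec,
      intercept = co[["intercept"]], index = co[["index"]],
      body_mass = co[["body_mass"]], time = co[["time"]],
      r2 = r$model$r2, rmse = r$model$rmse,
      bias_kg = r$kg$ba$bias, sd_kg = r$kg$ba$sd_diff,
      loa_lower_kg = r$kg$ba$loa_lower, loa_upper_kg = r$kg$ba$loa_upper,
      max_allowed_diff_kg = r$kg$max_allowed_diff,
      bias_pct = r$pct$ba$bias, sd_pct = r$pct$ba$sd_diff,
      loa_lower_pct = r$pct$ba$loa_lower, loa_upper_pct = r$pct$ba$loa_upper,
      ccc = r$kg$ccc, pearson_r = r$kg$pearson_r,
      mape_median = r$kg$mape_median)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path_base)) {
    pretty <- tab
    num <- vapply(pretty, is.numeric, TRUE)
    pretty[num] <- lapply(pretty[num], round, 2)
    txt <- utils::capture.output(print(pretty, row.names = FALSE))
    writeLines(txt, paste0(path_base, ".txt"))
    jsonlite::write_json(tab, paste0(path_base, ".json"), digits = NA)
    return(invisible(tab))
  }
  tab
}
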