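#' Default configuration for a fully synthetic run
#'
#' A single flat list mirroring every stage's parameters; merge your
#' overrides over it. All randomness in a run flows from `seed`: each
#' stage derives its own sub-seed (master seed plus a fixed stage offset)
#' so stages are independently reproducible.
#'
#' @param ... named overrides of the defaults.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_lat = 8L, n_lon = 8L, years = 2003:2007, steps_per_day = 8L,
    seed = 1L,
    # per cell-day occurrence law: threshold -beta0/beta1 = 3 kPa sits in
    # the far tail of the synthetic VPD climate, so fire is rare per cell
    # (~0.2 burns/cell/year) as in real burned-area products and the
    # five-year exclusion leaves a live quasi-absence pool
    beta0 = -30, beta1 = 10,
    # pre-period burn climate matches the in-period rarity (~0.2
    # burns/cell/year), so the five-year exclusion behaves consistently
    # across the study-period boundary
    history_years = 5L, history_rate = 5e-4,
    bias_shift = 0.3, bias_scale = 1.2, future_delta = 0.5,
    n_quantiles = 99L, by_month = FALSE,
    zero_fraction = 0.1, refine = 4L,
    future_label = "2081-2100", scenario = "RCP8.5")
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 101L, vpd = 211L, sample = 307L, fit = 401L,
               bias_correct = 503L, exceedance = 601L, exposure = 701L)
  cfg$seed + unname(offsets[stage])
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the synthetic pipeline end to end
#'
#' Executes the stages in dependency order — simulate climate and fires,
#' daily-maximum VPD, presence/absence sampling, per-stratum threshold
#' fitting, quantile-mapping bias correction of a distorted GCM-like
#' series, exceedance-day climatologies and their change, and population
#' and biomass exposure — writing each stage's artifact as CSV into
#' `outdir` plus a JSON manifest recording the config, its hash, the seed
#' and every file written.
#'
#' A completed run is idempotent: if the manifest exists and records the
#' same config hash, the run returns immediately without recomputation
#' unless `force = TRUE`.
#'
#' @param config a config list (see [default_config()]) or the path of a
#'   YAML file holding one.
#' @param outdir output directory (created if needed).
#' @param force recompute even over a completed identical run.
#' @return the manifest, invisibly (list: config hash, seed, artifacts).
#' @export
run_pipeline <- function(config = default_config(), outdir, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- do.call(default_config, config)
  cfg$years <- as.integer(cfg$years[1L]):as.integer(cfg$years[length(cfg$years)])
  hash <- config_hash(cfg)
  manifest_path <- file.path(outdir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, hash) &&
        all(file.exists(file.path(outdir, unlist(old$artifacts)))))
      return(invisible(old))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0L)
  put <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(outdir, name)
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------------
  spec <- world_spec(cfg$n_lat, cfg$n_lon, cfg$years, cfg$steps_per_day,
                     seed = stage_seed(cfg, "simulate"))
  law <- fire_law(cfg$beta0, cfg$beta1)
  stratum_map <- matrix("S1", cfg$n_lat, cfg$n_lon)
  sim <- run_stage("simulate", simulate_climate(spec))
  pop_fine <- simulate_density_raster(spec, "population", cfg$zero_fraction,
                                      cfg$refine)
  agb_fine <- simulate_density_raster(spec, "biomass", cfg$zero_fraction,
                                      cfg$refine)
  write_raster_csv(pop_fine, put("population_fine.csv"))
  write_raster_csv(agb_fine, put("biomass_fine.csv"))

  # -- vpd --------------------------------------------------------------------
  vpd_daily <- run_stage("vpd", daily_max_vpd(sim$temperature, sim$dewpoint,
                                              "dewpoint"))
  write_climate_grid(vpd_daily, put("vpd_daily.csv"))

  fires <- run_stage("simulate", simulate_fire_occurrence(
    vpd_daily, law, seed = stage_seed(cfg, "simulate") + 1L,
    stratum_map = stratum_map,
    history_years = cfg$history_years, history_rate = cfg$history_rate))
  write_fire_events(fires, put("fire_events.csv"), cfg$years)

  # -- sample -----------------------------------------------------------------
  samples <- run_stage("sample", {
    pres <- match_presences(fires, vpd_daily)
    abs_ <- sample_quasi_absences(pres, vpd_daily, stratum_map,
                                  seed = stage_seed(cfg, "sample"),
                                  history = attr(fires, "history"))
    assemble_samples(pres, abs_, seed = stage_seed(cfg, "sample") + 1L)
  })
  write_samples(samples, put("samples.csv"))

  # -- fit --------------------------------------------------------------------
  fits <- run_stage("fit", fit_strata(samples))
  write_model_table(fits, put("threshold_models.csv"))
  thr <- stats::setNames(vapply(fits$fits, `[[`, numeric(1L), "vpd_p50"),
                         names(fits$fits))

  # -- bias-correct -----------------------------------------------------------
  gcm <- run_stage("bias_correct", {
    g <- simulate_gcm_like(vpd_daily, cfg$bias_shift, cfg$bias_scale,
                           cfg$future_delta)
    list(hist_corr = bias_correct_grid(g$historical, vpd_daily, g$historical,
                                       n_quantiles = cfg$n_quantiles,
                                       by_month = cfg$by_month),
         fut_corr = bias_correct_grid(g$historical, vpd_daily, g$future,
                                      n_quantiles = cfg$n_quantiles,
                                      by_month = cfg$by_month))
  })
  write_climate_grid(gcm$hist_corr, put("vpd_hist_corrected.csv"))
  write_climate_grid(gcm$fut_corr, put("vpd_future_corrected.csv"))

  # -- exceedance -------------------------------------------------------------
  if (is.null(thr) || length(thr) == 0L)
    stop("pipeline stage 'exceedance' failed: no fitted thresholds available")
  thr_map <- threshold_map(stratum_map, thr)
  exc <- run_stage("exceedance", {
    present <- exceedance_days(gcm$hist_corr, thr_map)
    future <- exceedance_days(gcm$fut_corr, thr_map)
    list(present = present, future = future,
         change = change_in_exceedance(future, present))
  })
  write_raster_csv(exc$present, put("exceedance_present.csv"))
  write_raster_csv(exc$future, put("exceedance_future.csv"))
  write_raster_csv(exc$change, put("exceedance_change.csv"))

  # -- exposure ---------------------------------------------------------------
  expo <- run_stage("exposure", {
    pop <- resample_density(pop_fine, cfg$n_lat, cfg$n_lon)
    agb <- resample_density(agb_fine, cfg$n_lat, cfg$n_lon)
    list(person_days = exposure(exc$change, pop, "population"),
         tonne_days = exposure(exc$change, agb, "biomass"))
  })
  write_raster_csv(expo$person_days, put("exposure_person_days.csv"))
  write_raster_csv(expo$tonne_days, put("exposure_tonne_days.csv"))

  manifest <- list(config = cfg, config_hash = hash, seed = cfg$seed,
                   scenario = cfg$scenario, future_epoch = cfg$future_label,
                   artifacts = as.list(artifacts))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate a pipeline artifact file against its expected schema
#'
#' Schema checks for the plain-text artifact formats: climate-grid CSVs
#' (header block with variable, units and calendar), fire-event CSVs,
#' occurrence-sample CSVs, model tables and rasters. Problems are
#' reported, never silently coerced.
#'
#' @param path file to check.
#' @param expected_format one of `"climate_csv"`, `"events_csv"`,
#'   `"samples_csv"`, `"model_csv"`, `"raster_csv"`.
#' @return character vector of human-readable problems; empty if valid.
#' @export
validate_io <- function(path, expected_format = c("climate_csv", "events_csv",
                                                  "samples_csv", "model_csv",
                                                  "raster_csv")) {
  expected_format <- match.arg(expected_format)
  if (!file.exists(path)) return(sprintf("file does not exist: %s", path))
  problems <- character(0L)
  need_cols <- function(df, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      sprintf("missing column(s): %s", paste(miss, collapse = ", "))
    else character(0L)
  }
  tryCatch({
    if (expected_format == "climate_csv") {
      hdr <- readLines(path, n = 6L)
      for (key in c("var", "units", "years", "steps_per_day", "lat", "lon"))
        if (!any(startsWith(hdr, paste0("# ", key, ":"))))
          problems <- c(problems, sprintf("header missing '%s' attribute", key))
      if (length(problems) == 0L) {
        df <- utils::read.csv(path, comment.char = "#", nrows = 5L)
        problems <- c(problems,
                      need_cols(df, c("lat_idx", "lon_idx", "t_idx", "value")))
      }
    } else if (expected_format == "events_csv") {
      df <- utils::read.csv(path, nrows = 50L)
      problems <- c(problems, need_cols(
        df, c("cell_lat_idx", "cell_lon_idx", "date", "stratum")))
      if ("date" %in% names(df) && nrow(df) &&
          any(!grepl("^\\d{4}-\\d{2}-\\d{2}$", df$date)))
        problems <- c(problems, "dates are not ISO-8601 (YYYY-MM-DD)")
    } else if (expected_format == "samples_csv") {
      df <- utils::read.csv(path, nrows = 50L)
      problems <- c(problems,
                    need_cols(df, c("vpd_kpa", "burned", "year", "stratum")))
      if ("burned" %in% names(df) && nrow(df) && !all(df$burned %in% 0:1))
        problems <- c(problems, "column 'burned' is not 0/1")
      if ("vpd_kpa" %in% names(df) && nrow(df) && any(df$vpd_kpa < 0))
        problems <- c(problems, "negative VPD values")
    } else if (expected_format == "model_csv") {
      df <- utils::read.csv(path, nrows = 50L)
      problems <- c(problems, need_cols(
        df, c("stratum", "beta0", "beta1", "vpd_p50", "se", "ci_lo", "ci_hi",
              "auc", "tpr", "dev_expl", "n")))
    } else {
      df <- utils::read.csv(path, nrows = 5L)
      if (!all(vapply(df, is.numeric, logical(1L))))
        problems <- c(problems, "raster contains non-numeric columns")
    }
  }, error = function(e)
    problems <<- c(problems, sprintf("unreadable (%s): %s",
                                     conditionMessage(e), path)))
  problems
}
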