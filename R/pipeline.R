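#' Run the full recommendation pipeline on in-memory objects
#'
#' The three-step chain for one or more plots: (1) estimate AGB at each
#' observed stage from reflectance via EVI2 and the HLM; (2) assimilate the
#' estimates into the crop model by particle swarm search; (3) run the
#' assimilated model over the topdressing-N grid, derive the economic target
#' yield, and recommend the lowest rate attaining it.
#'
#' @param spectra Data frame with plot_id, date, nir, red, gdd (HLM-scale
#'   covariate).
#' @param weather Validated weather frame.
#' @param soil A [soil_init()].
#' @param mgmt Either one [management_plan()] shared by all plots or a named
#'   list of plans keyed by plot_id.
#' @param cultivar Baseline [cultivar_params()].
#' @param coeffs HLM coefficients for AGB estimation.
#' @param specs Assimilation parameter specs.
#' @param config [swarm_config()]; per-plot seeds are derived from
#'   `config$seed` so plots are independent but reproducible.
#' @param grid Topdressing-N grid, kg ha-1.
#' @param prices [economic_params()].
#' @param model Crop-model function.
#' @return A `pipeline_result`: `per_plot` data frame (plot_id, agb_jointing,
#'   n_optimum, target_yield, n_recommended, expected_yield, expected_E,
#'   best_cost, infeasible), plus `assimilations` and `curves` lists keyed by
#'   plot_id.
#' @export
run_pipeline <- function(spectra, weather, soil, mgmt, cultivar =
                           cultivar_params(),
                         coeffs = hlm_published(),
                         specs = default_parameter_specs(),
                         config = swarm_config(), grid = n_search_grid(),
                         prices = economic_params(),
                         model = get_crop_model("surrogate")) {
  stopifnot(all(c("plot_id", "date", "nir", "red", "gdd") %in%
                  names(spectra)))
  plot_ids <- unique(spectra$plot_id)
  per_plot <- list(); assims <- list(); curves <- list()
  for (j in seq_along(plot_ids)) {
    pid <- plot_ids[j]
    sp <- spectra[spectra$plot_id == pid, , drop = FALSE]
    agb_est <- hlm_predict(evi2(sp$nir, sp$red), sp$gdd, coeffs)
    if (any(agb_est <= 0)) {
      stop("pipeline stage agb-estimation: non-positive AGB estimate for ",
           "plot ", pid)
    }
    obs <- data.frame(date = as.Date(sp$date), agb = agb_est)
    pm <- if (inherits(mgmt, "management_plan")) mgmt else mgmt[[pid]]
    if (is.null(pm)) stop("pipeline: no management plan for plot ", pid)
    cfg <- config
    cfg$seed <- (config$seed + 104729L * j) %% 2147483647L
    ar <- tryCatch(
      assimilate(obs, weather, soil, pm, cultivar, specs = specs,
                 config = cfg, model = model),
      error = function(e) stop("pipeline stage assimilation failed for ",
                               "plot ", pid, ": ", conditionMessage(e)))
    curve <- tryCatch(
      yield_response_curve(weather, soil, ar$mgmt, ar$cultivar, grid = grid,
                           prices = prices, model = model),
      error = function(e) stop("pipeline stage recommendation failed for ",
                               "plot ", pid, ": ", conditionMessage(e)))
    opt <- economic_optimum(curve)
    rec <- recommend_n(curve, opt$target_yield)
    jdate <- ar$simulation$stage_dates[["jointing"]]
    agb_j <- if (!is.na(jdate)) {
      ar$simulation$days$agb[match(jdate, ar$simulation$days$date)]
    } else NA_real_
    per_plot[[pid]] <- data.frame(
      plot_id = pid, agb_jointing = agb_j,
      n_optimum = opt$n_optimum, target_yield = opt$target_yield,
      n_recommended = rec$n_recommended,
      expected_yield = rec$yield_kg_ha,
      expected_E = economic_benefit(rec$yield_kg_ha, rec$n_recommended,
                                    prices),
      best_cost = ar$best_cost, infeasible = rec$infeasible)
    assims[[pid]] <- ar; curves[[pid]] <- curve
  }
  structure(list(per_plot = do.call(rbind,
                                    c(per_plot, list(make.row.names = FALSE))),
                 assimilations = assims, curves = curves,
                 seed = config$seed),
            class = "pipeline_result")
}

#' Run the pipeline from files and write reports
#'
#' File-level front end of [run_pipeline()]: reads weather CSV, JSON
#' soil/management config and spectra CSV, runs the chain, and writes a JSON
#' report (with config hash and seed for provenance) plus a per-plot CSV.
#'
#' @param weather_path,config_path,obs_path Input files.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param specs Parameter specs (or path to a JSON spec file).
#' @param config Optional [swarm_config()] (seed overridden by `seed`).
#' @param grid,prices Recommendation settings.
#' @return The `pipeline_result`, invisibly; writes `report.json` and
#'   `recommendations.csv` under `out_dir`.
#' @export
run_pipeline_files <- function(weather_path, config_path, obs_path, out_dir,
                               seed = 1L, specs = default_parameter_specs(),
                               config = NULL, grid = n_search_grid(),
                               prices = economic_params()) {
  weather <- read_weather_csv(weather_path)
  cfg <- read_config_json(config_path)
  spectra <- read_observations_csv(obs_path)
  if (is.character(specs)) specs <- read_parameter_specs_json(specs)
  if (is.null(config)) config <- swarm_config(seed = as.integer(seed))
  else config$seed <- as.integer(seed)
  res <- run_pipeline(spectra, weather, cfg$soil, cfg$mgmt, cfg$cultivar,
                      specs = specs, config = config, grid = grid,
                      prices = prices)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  provenance <- list(seed = as.integer(seed),
                     config_hash = config_hash(list(
                       specs = specs, config = unclass(config),
                       grid = grid, prices = unclass(prices))),
                     inputs = list(weather = basename(weather_path),
                                   config = basename(config_path),
                                   observations = basename(obs_path)))
  report <- list(provenance = provenance,
                 per_plot = res$per_plot,
                 best_parameters = lapply(res$assimilations, function(a)
                   as.list(a$best_position)),
                 best_cost = lapply(res$assimilations, function(a)
                   a$best_cost))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(res$per_plot, file.path(out_dir, "recommendations.csv"),
                   row.names = FALSE)
  invisible(res)
}
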