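#' Beijing-like climate profile for the weather generator
#'
#' Parameters of a warm-temperate, semi-humid continental monsoon climate
#' (the trial site): sinusoidal annual temperature cycle with AR(1)
#' anomalies, Markov-chain rain occurrence with gamma amounts rescaled to a
#' seasonal total drawn from the site's annual range (400-620 mm), and
#' sunshine hours consistent with astronomical daylength.
#'
#' @param latitude Degrees north.
#' @param tmean_annual,tmean_amplitude Annual mean temperature and seasonal
#'   half-amplitude, degC.
#' @param diurnal_range Mean tmax - tmin, degC.
#' @param anomaly_sd,anomaly_rho AR(1) temperature anomaly parameters.
#' @param precip_annual_range Annual precipitation range, mm.
#' @param p_wet_after_dry,p_wet_after_wet Rain-occurrence Markov chain.
#' @param rain_shape Gamma shape of daily rain amounts.
#' @return A `climate_profile` list.
#' @export
climate_profile_beijing <- function(latitude = 40.17, tmean_annual = 12.5,
                                    tmean_amplitude = 14.5,
                                    diurnal_range = 10,
                                    anomaly_sd = 2.5, anomaly_rho = 0.7,
                                    precip_annual_range = c(400, 620),
                                    p_wet_after_dry = 0.18,
                                    p_wet_after_wet = 0.45,
                                    rain_shape = 0.8) {
  structure(list(latitude = latitude, tmean_annual = tmean_annual,
                 tmean_amplitude = tmean_amplitude,
                 diurnal_range = diurnal_range, anomaly_sd = anomaly_sd,
                 anomaly_rho = anomaly_rho,
                 precip_annual_range = precip_annual_range,
                 p_wet_after_dry = p_wet_after_dry,
                 p_wet_after_wet = p_wet_after_wet,
                 rain_shape = rain_shape),
            class = "climate_profile")
}

#' Generate a synthetic daily weather series
#'
#' Deterministic per seed. Daily mean temperature follows a sinusoid peaking
#' in late July plus AR(1) anomalies; tmax/tmin sit half a diurnal range
#' above/below the mean (tmax >= tmin by construction). Rain occurrence is a
#' two-state Markov chain; gamma amounts are rescaled so the series total,
#' prorated to a full year, lands inside the profile's annual range. Sunshine
#' hours are a weather-dependent fraction of daylength, from which global
#' radiation follows via the Angstrom-Prescott formula.
#'
#' @param season_start First day (Date or ISO string).
#' @param n_days Number of days (>= 1).
#' @param profile A [climate_profile_beijing()]-style profile.
#' @param seed Integer seed.
#' @return Weather data frame: date, tmax, tmin, precip, sunshine_hours,
#'   srad.
#' @export
generate_weather <- function(season_start, n_days,
                             profile = climate_profile_beijing(),
                             seed = 1L) {
  stopifnot(n_days >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  dates <- as.Date(season_start) + seq_len(n_days) - 1
  doy <- as.integer(format(dates, "%j"))
  tmean_clim <- profile$tmean_annual -
    profile$tmean_amplitude * cos(2 * pi * (doy - 205 + 182.5) / 365)

  anom <- numeric(n_days)
  eps <- stats::rnorm(n_days, 0, profile$anomaly_sd)
  for (i in seq_len(n_days)) {
    anom[i] <- if (i == 1) eps[1] else profile$anomaly_rho * anom[i - 1] +
      sqrt(1 - profile$anomaly_rho^2) * eps[i]
  }
  tmean <- tmean_clim + anom
  half <- profile$diurnal_range / 2
  tmax <- tmean + half
  tmin <- tmean - half

  wet <- logical(n_days)
  u <- stats::runif(n_days)
  for (i in seq_len(n_days)) {
    p <- if (i == 1 || !wet[i - 1]) profile$p_wet_after_dry else
      profile$p_wet_after_wet
    wet[i] <- u[i] < p
  }
  amounts <- numeric(n_days)
  nwet <- sum(wet)
  if (nwet > 0) {
    amounts[wet] <- stats::rgamma(nwet, shape = profile$rain_shape, rate = 1)
    target_annual <- stats::runif(1, profile$precip_annual_range[1],
                                  profile$precip_annual_range[2])
    target <- target_annual * n_days / 365
    amounts <- amounts * target / sum(amounts)
  }

  dl <- daylength_hours(doy, profile$latitude)
  frac <- pmin(1, pmax(0.05, stats::rbeta(n_days, 4, 2) * ifelse(wet, 0.4, 1)))
  sunshine <- frac * dl
  ra <- extraterrestrial_radiation(doy, profile$latitude)
  data.frame(date = dates, tmax = round(tmax, 2), tmin = round(tmin, 2),
             precip = round(amounts, 2),
             sunshine_hours = round(sunshine, 2),
             srad = round(solar_radiation_angstrom(pmin(sunshine, dl), dl, ra),
                          3))
}

#' Multi-treatment experiment design
#'
#' Defaults reproduce the modeling trials: 2 varieties x 4 N rates
#' (0/90/180/270 kg ha-1) x 4 replicates = 32 plots, sampled at 4 growth
#' stages = 128 AGB samples per season. Topdressing fractions parameterize
#' the validation trial.
#'
#' @param varieties Number of varieties.
#' @param n_rates Season N totals per treatment, kg ha-1 (split equally
#'   between basal and jointing topdressing).
#' @param replicates Replicates per variety x rate.
#' @param stages_sampled Number of sampled growth stages.
#' @param topdressing_fractions Fractions of the recommended rate for the
#'   validation trial.
#' @return An `experiment_design` list with derived `n_plots`, `n_samples`.
#' @export
experiment_design <- function(varieties = 2,
                              n_rates = c(0, 90, 180, 270),
                              replicates = 4, stages_sampled = 4,
                              topdressing_fractions =
                                c(0, 0.25, 0.50, 0.75, 1.00, 1.25)) {
  n_plots <- varieties * length(n_rates) * replicates
  structure(list(varieties = varieties, n_rates = n_rates,
                 replicates = replicates, stages_sampled = stages_sampled,
                 topdressing_fractions = topdressing_fractions,
                 n_plots = n_plots,
                 n_samples = n_plots * stages_sampled),
            class = "experiment_design")
}

#' Observation noise model
#'
#' @param agb_obs_cv Coefficient of variation of destructive AGB sampling
#'   (multiplicative lognormal; default 5%).
#' @param reflectance_sd Additive Gaussian noise on NIR/red reflectance
#'   (default 0.005).
#' @param soil_spatial_cv Plot-to-plot lognormal CV on initial mineral N and
#'   water capacity (default 10%).
#' @return A `noise_model` list.
#' @export
noise_model <- function(agb_obs_cv = 0.05, reflectance_sd = 0.005,
                        soil_spatial_cv = 0.10) {
  if (any(c(agb_obs_cv, reflectance_sd, soil_spatial_cv) < 0)) {
    stop("noise_model: all components must be non-negative")
  }
  structure(list(agb_obs_cv = agb_obs_cv, reflectance_sd = reflectance_sd,
                 soil_spatial_cv = soil_spatial_cv),
            class = "noise_model")
}

#' Noise-free noise model (the "noiseless mode" of the generator)
#' @return A [noise_model()] with all components zero.
#' @export
noise_model_none <- function() noise_model(0, 0, 0)

# Thermal-time covariate scale for the HLM: the published coefficients yield
# plausible AGB when the covariate is cumulative GDD (degC d) divided by 15.
#' @rdname generate_experiment
#' @export
hlm_gdd_scale <- function() 1 / 15

# Invert EVI2 for NIR at a chosen red reflectance.
invert_evi2 <- function(v, red) {
  if (any(v >= 2.49)) stop("EVI2 value not representable")
  (v * (1 + 2.4 * red) + 2.5 * red) / (2.5 - v)
}

default_mgmt_for_rate <- function(sowing_date, rate, jointing_date,
                                  latitude = 40.17, plant_density = 350) {
  sowing_date <- as.Date(sowing_date)
  irr <- data.frame(
    date = sowing_date + c(45, 170, 200),
    amount = c(50, 50, 50))
  fert <- data.frame(
    date = c(sowing_date, as.Date(jointing_date)),
    amount = c(rate / 2, rate / 2),
    type = c("basal", "topdress"))
  management_plan(sowing_date, plant_density = plant_density,
                  irrigation_events = irr, fertilization_events = fert,
                  latitude = latitude)
}

#' Generate a complete synthetic field experiment
#'
#' Runs the growth surrogate for every plot of the design under plot-level
#' lognormal soil heterogeneity, samples AGB at the surrogate's four
#' phenophase dates (jointing/stem elongation, flag leaf, flowering, grain
#' filling) with multiplicative noise, and synthesizes NIR/red reflectance
#' pairs by inverting the published HLM at the truth AGB (plus reflectance
#' noise), so the evi2 -> hlm_predict round trip approximates truth. The
#' thermal-time covariate attached to the spectra is cumulative GDD times
#' [hlm_gdd_scale()].
#'
#' @param design An [experiment_design()].
#' @param weather Weather frame; generated with `seed` when NULL.
#' @param soil Baseline [soil_init()], perturbed per plot.
#' @param noise A [noise_model()].
#' @param seed Integer seed driving all randomness.
#' @param season_start Sowing date.
#' @param n_days Weather length when weather is generated internally
#'   (default 300, enough to reach maturity at any seed).
#' @return List: `plots` (plot_id, variety, n_rate, replicate, yield,
#'   agb_jointing, soil_n_factor), `agb_obs` (plot_id, date, stage,
#'   agb_measured), `spectra` (plot_id, date, stage, nir, red, gdd,
#'   agb_truth), `truth` (list of simulation outputs), `mgmt` (list of
#'   management plans), `weather`, `soil`, `design`, `gdd_scale`.
#' @export
generate_experiment <- function(design = experiment_design(), weather = NULL,
                                soil = soil_init(), noise = noise_model(),
                                seed = 1L, season_start = "2017-10-01",
                                n_days = 300) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (is.null(weather)) {
    weather <- generate_weather(season_start, n_days,
                                seed = as.integer(seed) + 7919L)
  }
  weather <- validate_weather(weather)
  season_start <- as.Date(season_start)

  # one reference run to locate phenophase dates for event scheduling
  ref_mgmt <- default_mgmt_for_rate(season_start, 180, season_start + 170)
  ref <- simulate_season(weather, soil, ref_mgmt, cultivar_params())
  jointing <- ref$stage_dates[["jointing"]]
  anthesis <- ref$stage_dates[["anthesis"]]
  maturity <- ref$stage_dates[["maturity"]]
  if (anyNA(c(jointing, anthesis, maturity))) {
    stop("reference season did not reach maturity; extend the weather series")
  }
  stage_dates <- sort(unique(c(
    jointing,
    jointing + round(as.numeric(anthesis - jointing) / 2), # flag leaf
    anthesis,                                              # flowering
    anthesis + round(as.numeric(maturity - anthesis) / 2)  # grain filling
  )))[seq_len(design$stages_sampled)]
  stage_names <- c("jointing", "flag_leaf", "flowering",
                   "grain_filling")[seq_len(design$stages_sampled)]

  grid <- expand.grid(replicate = seq_len(design$replicates),
                      n_rate = design$n_rates,
                      variety = seq_len(design$varieties))
  grid <- grid[, c("variety", "n_rate", "replicate")]
  grid$plot_id <- sprintf("P%d_N%d_R%d", grid$variety,
                          match(grid$n_rate, design$n_rates), grid$replicate)

  # mild variety contrast in photosynthesis factor
  variety_slpf <- c(1.0, 0.95)[seq_len(design$varieties)]

  coeffs <- hlm_published()
  gdd_scale <- hlm_gdd_scale()
  plots <- list(); truth <- list(); mgmts <- list()
  agb_obs <- list(); spectra <- list()

  for (r in seq_len(nrow(grid))) {
    pid <- grid$plot_id[r]
    sf <- if (noise$soil_spatial_cv > 0) {
      stats::rlnorm(1, -noise$soil_spatial_cv^2 / 2, noise$soil_spatial_cv)
    } else 1
    wf <- if (noise$soil_spatial_cv > 0) {
      stats::rlnorm(1, -noise$soil_spatial_cv^2 / 2, noise$soil_spatial_cv)
    } else 1
    psoil <- soil_init(no3_n = soil$no3_n * sf, nh4_n = soil$nh4_n * sf,
                       organic_matter = soil$organic_matter,
                       water_holding_capacity =
                         soil$water_holding_capacity * wf,
                       initial_water =
                         min(soil$initial_water, soil$water_holding_capacity *
                               wf))
    cv <- cultivar_params(slpf = variety_slpf[grid$variety[r]])
    mgmt <- default_mgmt_for_rate(season_start, grid$n_rate[r], jointing)
    sim <- simulate_season(weather, psoil, mgmt, cv)
    truth[[pid]] <- sim; mgmts[[pid]] <- mgmt

    di <- match(stage_dates, sim$days$date)
    agb_t <- sim$days$agb[di]
    gdd_t <- sim$days$gdd[di]
    obs_noise <- if (noise$agb_obs_cv > 0) {
      stats::rlnorm(length(di), -noise$agb_obs_cv^2 / 2, noise$agb_obs_cv)
    } else rep(1, length(di))
    agb_obs[[pid]] <- data.frame(
      plot_id = pid, date = stage_dates, stage = stage_names,
      gdd = gdd_t, agb_measured = agb_t * obs_noise)

    # reflectance synthesis: invert the HLM at truth AGB
    g <- gdd_t * gdd_scale
    b0 <- coeffs$g00 + coeffs$g01 * g
    b1 <- coeffs$g10 + coeffs$g11 * g
    if (any(b1 <= 0.5)) {
      stop("HLM slope too small at a sampling stage; gdd scale misconfigured")
    }
    v <- (agb_t - b0) / b1
    red <- pmin(0.30, pmax(0.03, 0.30 - 0.25 * pmin(pmax(v, 0), 1)))
    nir <- invert_evi2(v, red)
    if (noise$reflectance_sd > 0) {
      nir <- nir + stats::rnorm(length(nir), 0, noise$reflectance_sd)
      red <- red + stats::rnorm(length(red), 0, noise$reflectance_sd)
    }
    nir <- pmin(1, pmax(0, nir)); red <- pmin(1, pmax(0.001, red))
    spectra[[pid]] <- data.frame(
      plot_id = pid, date = stage_dates, stage = stage_names,
      nir = nir, red = red, gdd = g, agb_truth = agb_t)

    plots[[pid]] <- data.frame(
      plot_id = pid, variety = grid$variety[r], n_rate = grid$n_rate[r],
      replicate = grid$replicate[r], yield = sim$yield,
      agb_jointing = sim$days$agb[match(jointing, sim$days$date)],
      soil_n_factor = sf)
  }

  list(plots = do.call(rbind, c(plots, list(make.row.names = FALSE))),
       agb_obs = do.call(rbind, c(agb_obs, list(make.row.names = FALSE))),
       spectra = do.call(rbind, c(spectra, list(make.row.names = FALSE))),
       truth = truth, mgmt = mgmts, weather = weather, soil = soil,
       design = design, gdd_scale = gdd_scale,
       stage_dates = stats::setNames(stage_dates, stage_names),
       jointing_date = jointing, seed = as.integer(seed))
}

#' Generate a topdressing validation trial
#'
#' For each plot, applies each fraction of that plot's recommended rate as
#' the jointing topdressing (on top of the trial's basal dressing) and
#' reports yield and net economic benefit per treatment — the analogue of a
#' fraction-of-recommendation validation experiment.
#'
#' @param experiment Output of [generate_experiment()].
#' @param recommended Named numeric vector: recommended topdressing N
#'   (kg ha-1) per plot_id.
#' @param fractions Treatment fractions, default the design's.
#' @param basal_n Basal dressing, kg ha-1 (default 90); either one value
#'   common to all plots or a vector named by plot_id.
#' @param prices An [economic_params()].
#' @return Data frame: plot_id, fraction, treatment, n_topdress, yield
#'   (t ha-1), benefit (CNY ha-1).
#' @export
generate_topdressing_trial <- function(experiment, recommended,
                                       fractions = NULL, basal_n = 90,
                                       prices = economic_params()) {
  if (is.null(fractions)) fractions <- experiment$design$topdressing_fractions
  ids <- names(recommended)
  if (is.null(ids) || !all(ids %in% names(experiment$mgmt))) {
    stop("recommended must be named by plot_id")
  }
  rows <- list()
  for (pid in ids) {
    mgmt <- experiment$mgmt[[pid]]
    soil <- experiment$soil
    basal <- if (length(basal_n) > 1 || !is.null(names(basal_n))) {
      if (!pid %in% names(basal_n)) stop("no basal_n for plot ", pid)
      basal_n[[pid]]
    } else basal_n
    for (fr in fractions) {
      ntd <- fr * recommended[[pid]]
      fe <- data.frame(date = c(mgmt$sowing_date, experiment$jointing_date),
                       amount = c(basal, ntd),
                       type = c("basal", "topdress"))
      m2 <- mgmt; m2$fertilization_events <- fe
      sim <- simulate_season(experiment$weather, soil, m2, cultivar_params())
      rows[[length(rows) + 1]] <- data.frame(
        plot_id = pid, fraction = fr,
        treatment = paste0("T", match(fr, fractions) - 1),
        n_topdress = ntd, yield = sim$yield,
        benefit = economic_benefit(sim$yield * 1000, basal + ntd, prices))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
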