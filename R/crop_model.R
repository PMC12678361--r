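#' Initial soil conditions
#'
#' @param no3_n,nh4_n Initial mineral N in the 0-30 cm layer, mg kg-1.
#' @param organic_matter Soil organic matter, g kg-1.
#' @param water_holding_capacity Plant-available water capacity, mm.
#' @param initial_water Water stored at sowing, mm (<= capacity).
#' @return A `soil_init` list.
#' @export
soil_init <- function(no3_n = 9.0, nh4_n = 11.3, organic_matter = 18,
                      water_holding_capacity = 180, initial_water = 150) {
  vals <- c(no3_n, nh4_n, organic_matter, water_holding_capacity,
            initial_water)
  if (any(vals < 0)) stop("soil_init: all fields must be non-negative")
  if (initial_water > water_holding_capacity) {
    stop("soil_init: initial_water exceeds water_holding_capacity")
  }
  structure(list(no3_n = no3_n, nh4_n = nh4_n,
                 organic_matter = organic_matter,
                 water_holding_capacity = water_holding_capacity,
                 initial_water = initial_water),
            class = "soil_init")
}

#' Season management plan
#'
#' @param sowing_date Date (or ISO string) of sowing.
#' @param plant_density Plants m-2 (field trials use 300-400).
#' @param irrigation_events Data frame `date`, `amount` (mm); may be empty.
#' @param fertilization_events Data frame `date`, `amount` (kg N ha-1),
#'   `type` ("basal" or "topdress"); the topdress event at the jointing stage
#'   is the quantity the recommendation step varies.
#' @param latitude Site latitude, degrees north.
#' @return A `management_plan` list.
#' @export
management_plan <- function(sowing_date, plant_density = 350,
                            irrigation_events = NULL,
                            fertilization_events = NULL,
                            latitude = 40.17) {
  sowing_date <- as.Date(sowing_date)
  empty <- function(cols) {
    out <- data.frame(date = as.Date(character()), amount = numeric())
    if ("type" %in% cols) out$type <- character()
    out
  }
  if (is.null(irrigation_events)) irrigation_events <- empty("da")
  if (is.null(fertilization_events)) fertilization_events <- empty("type")
  irrigation_events$date <- as.Date(irrigation_events$date)
  fertilization_events$date <- as.Date(fertilization_events$date)
  if (is.null(fertilization_events$type)) fertilization_events$type <- "basal"
  if (any(irrigation_events$amount < 0) ||
      any(fertilization_events$amount < 0)) {
    stop("management_plan: event amounts must be non-negative")
  }
  if (plant_density <= 0) stop("management_plan: plant_density must be > 0")
  structure(list(sowing_date = sowing_date, plant_density = plant_density,
                 irrigation_events = irrigation_events,
                 fertilization_events = fertilization_events,
                 latitude = latitude),
            class = "management_plan")
}

#' Cultivar (genotype) parameters
#'
#' The four genotype traits re-estimated by assimilation: photoperiod
#' sensitivity (p1d), phyllochron interval (phint), root depth growth rate
#' (rdgs) and a photosynthesis/soil-fertility factor (slpf).
#'
#' @param p1d Photoperiod parameter, calibration range 30-70.
#' @param phint Phyllochron interval, range 90-120; scales all phenophase
#'   thermal-time thresholds.
#' @param rdgs Root depth growth rate, range 2.5-3.5.
#' @param slpf Photosynthesis factor, range 0.8-1.0.
#' @param check "error" rejects out-of-range values (direct mode); "clamp"
#'   silently clips them (assimilation mode, where swarm excursions must not
#'   crash the model).
#' @return A `cultivar_params` list.
#' @export
cultivar_params <- function(p1d = 50, phint = 100, rdgs = 3.0, slpf = 1.0,
                            check = c("error", "clamp")) {
  check <- match.arg(check)
  rng <- list(p1d = c(30, 70), phint = c(90, 120),
              rdgs = c(2.5, 3.5), slpf = c(0.8, 1.0))
  vals <- list(p1d = p1d, phint = phint, rdgs = rdgs, slpf = slpf)
  for (nm in names(vals)) {
    lo <- rng[[nm]][1]; hi <- rng[[nm]][2]
    if (vals[[nm]] < lo || vals[[nm]] > hi) {
      if (check == "error") {
        stop("cultivar_params: ", nm, " = ", vals[[nm]],
             " outside [", lo, ", ", hi, "]")
      }
      vals[[nm]] <- min(max(vals[[nm]], lo), hi)
    }
  }
  structure(vals, class = "cultivar_params")
}

#' Run the daily winter-wheat growth surrogate for one season
#'
#' A deterministic process-based surrogate for a CERES-type wheat model. Each
#' day it (i) accumulates thermal time, (ii) advances the phenophase when
#' development time crosses phint-scaled thresholds, with development slowed
#' under short photoperiods in proportion to p1d, (iii) computes potential
#' growth as radiation-use efficiency times intercepted PAR (Beer's law on a
#' biomass-driven LAI) times slpf, (iv) updates a soil water bucket
#' (rain + irrigation - transpiration) with root-depth-limited extraction,
#' (v) updates a mineral-N pool (initialized from NO3+NH4, incremented by
#' fertilization and mineralization, depleted by uptake) with daily crop N
#' demand from a critical dilution curve, and (vi) realizes
#' actual growth = potential x min(water factor, N factor). Yield is the
#' potential harvest index, scaled down by mean grain-fill stress, times
#' final AGB.
#'
#' @param weather Daily weather covering at least sowing to maturity; see
#'   [validate_weather()].
#' @param soil A [soil_init()] object.
#' @param mgmt A [management_plan()] object.
#' @param cultivar A [cultivar_params()] object.
#' @param constants Constants table, by default [crop_constants()].
#' @return A `simulation_output` list: `days` data frame (date, gdd
#'   cumulative degC d, agb t ha-1, stage, water_stress, n_stress, soil_water
#'   mm, soil_n kg ha-1), `yield` t ha-1 (dry basis), `stage_dates` named
#'   Date vector for emergence/jointing/anthesis/maturity, `n_uptake`
#'   cumulative kg ha-1, `n_applied` kg ha-1, `n_mineralized` kg ha-1.
#' @export
#' @examples
#' w <- generate_weather("2017-10-01", 260, seed = 1)
#' m <- management_plan("2017-10-01",
#'   fertilization_events = data.frame(
#'     date = as.Date(c("2017-10-01", "2018-04-05")),
#'     amount = c(90, 90), type = c("basal", "topdress")))
#' out <- simulate_season(w, soil_init(), m, cultivar_params())
#' out$yield
simulate_season <- function(weather, soil, mgmt, cultivar,
                            constants = crop_constants()) {
  stopifnot(inherits(soil, "soil_init"), inherits(mgmt, "management_plan"),
            inherits(cultivar, "cultivar_params"))
  k <- constants
  weather <- validate_weather(weather, latitude = mgmt$latitude)
  i0 <- match(mgmt$sowing_date, weather$date)
  if (is.na(i0)) stop("weather does not cover the sowing date")
  w <- weather[i0:nrow(weather), , drop = FALSE]
  n <- nrow(w)

  doy <- as.POSIXlt(w$date)$yday + 1L
  dl <- daylength_hours(doy, mgmt$latitude)
  ra <- extraterrestrial_radiation(doy, mgmt$latitude)
  gdd_day <- growing_degree_days(w$tmax, w$tmin, k$tbase)
  et0 <- et_hargreaves(w$tmax, w$tmin, ra)

  # event amounts mapped onto season days
  irr <- numeric(n)
  ii <- match(mgmt$irrigation_events$date, w$date)
  ok <- !is.na(ii)
  irr[ii[ok]] <- irr[ii[ok]] + mgmt$irrigation_events$amount[ok]
  fert <- numeric(n)
  fi <- match(mgmt$fertilization_events$date, w$date)
  ok <- !is.na(fi)
  fert[fi[ok]] <- fert[fi[ok]] + mgmt$fertilization_events$amount[ok]

  thr <- k$phen_gdd * cultivar$phint / 100
  p1d_sens <- cultivar$p1d * k$p1d_scale

  # hoisted locals: the daily loop must not pay list-access costs
  tbase <- k$tbase; k_ext <- k$k_extinction; rue <- k$rue
  par_frac <- k$par_fraction; nc_a <- k$nc_a; nc_b <- k$nc_b
  nc_w_min <- k$nc_w_min; lai_per_kg <- k$lai_per_kg; lai_max <- k$lai_max
  popt <- k$photoperiod_opt; rd_max <- k$root_depth_max
  rd_gain <- k$root_gdd_gain; wx_frac <- k$water_extract_frac
  nu_frac <- k$n_uptake_frac; sen_min <- k$senescence_min
  nl_frac <- k$n_loss_frac
  t_lo <- k$temp_opt_lo; t_hi <- k$temp_opt_hi; t_max <- k$temp_max
  whc <- soil$water_holding_capacity
  rdgs_v <- cultivar$rdgs; slpf_v <- cultivar$slpf
  precip_v <- w$precip; srad_v <- w$srad
  tmean_v <- (w$tmax + w$tmin) / 2
  thr2 <- thr[2]; thr3 <- thr[3]; thr4 <- thr[4]
  agb0 <- k$agb0_per_plant * mgmt$plant_density * 10 # g m-2 -> kg ha-1

  # state
  agb <- 0                      # kg ha-1
  cum_gdd <- 0; dev <- 0
  water <- soil$initial_water
  soil_n <- (soil$no3_n + soil$nh4_n) * k$bulk_density * k$soil_depth_m * 10
  n_applied <- 0; n_mineralized <- 0; n_uptake <- 0
  root <- k$root_depth0
  stage <- 0L                   # 0 pre-emergence .. 4 mature
  mineral_rate <- soil$organic_matter * k$mineralization_per_om

  out_gdd <- numeric(n); out_agb <- numeric(n); out_stage <- integer(n)
  out_fw <- rep(1, n); out_fn <- rep(1, n)
  out_water <- numeric(n); out_soiln <- numeric(n)
  stage_dates <- rep(as.Date(NA), 4)

  gf_sum <- 0; gf_n <- 0L
  for (i in seq_len(n)) {
    g_i <- gdd_day[i]
    cum_gdd <- cum_gdd + g_i
    # photoperiod slows development between sowing and anthesis
    fp <- if (stage < 3L) {
      max(0.2, 1 - p1d_sens * max(0, popt - dl[i]))
    } else 1
    dev <- dev + g_i * fp
    new_stage <- (dev >= thr[1]) + (dev >= thr2) + (dev >= thr3) +
      (dev >= thr4)
    if (new_stage > stage) {
      for (s in (stage + 1L):new_stage) {
        if (is.na(stage_dates[s])) stage_dates[s] <- w$date[i]
      }
      if (new_stage >= 1L && agb == 0) agb <- agb0
      stage <- new_stage
    }

    soil_n <- (soil_n + fert[i] + mineral_rate) * (1 - nl_frac)
    n_applied <- n_applied + fert[i]
    n_mineralized <- n_mineralized + mineral_rate
    water <- min(water + precip_v[i] + irr[i], whc)

    fw <- 1; fn <- 1
    if (stage >= 1L && stage < 4L) {
      root <- min(rd_max, root + rdgs_v * rd_gain * g_i)
      root_frac <- root / rd_max
      # senescing canopy during grain fill
      green <- if (stage == 3L) {
        max(sen_min, 1 - (1 - sen_min) * (dev - thr3) / (thr4 - thr3))
      } else 1
      lai <- min(lai_max, lai_per_kg * agb) * green
      fint <- 1 - exp(-k_ext * lai)
      # trapezoidal temperature response of RUE
      tmean <- tmean_v[i]
      ft <- if (tmean <= tbase || tmean >= t_max) 0
        else if (tmean < t_lo) (tmean - tbase) / (t_lo - tbase)
        else if (tmean <= t_hi) 1
        else (t_max - tmean) / (t_max - t_hi)
      pot <- rue * par_frac * srad_v[i] * fint * ft * slpf_v * 10
      # 10: g m-2 -> kg ha-1

      # water supply vs transpiration demand
      demand_w <- et0[i] * fint
      supply_w <- wx_frac * water * root_frac
      fw <- if (demand_w > 0) min(1, supply_w / demand_w) else 1

      # N demand from the critical dilution curve, evaluated at the biomass
      # the crop would reach with potential growth
      w_t <- max((agb + pot) / 1000, nc_w_min)
      nc <- nc_a * w_t^(-nc_b) / 100            # kg N per kg biomass
      demand_n <- max(0, nc * (agb + pot) - n_uptake)
      supply_n <- nu_frac * soil_n * root_frac
      # smooth saturating N response: soft shoulder above the demand point
      # (tanh reaches 1.0 exactly in double precision for supply >> demand,
      # preserving the stress-free limit)
      fn <- if (demand_n > 0) tanh(supply_n / demand_n) else 1

      agb <- agb + pot * min(fw, fn)
      water <- max(0, water - min(demand_w, supply_w))
      upt <- min(demand_n, supply_n)
      soil_n <- max(0, soil_n - upt)
      n_uptake <- n_uptake + upt
      if (stage == 3L) { gf_sum <- gf_sum + min(fw, fn); gf_n <- gf_n + 1L }
    }

    out_gdd[i] <- cum_gdd; out_agb[i] <- agb
    out_stage[i] <- stage; out_fw[i] <- fw; out_fn[i] <- fn
    out_water[i] <- water; out_soiln[i] <- soil_n
    if (stage == 4L && i < n) {
      # crop mature; freeze remaining days
      idx <- (i + 1):n
      out_gdd[idx] <- cum_gdd + cumsum(gdd_day[idx])
      out_agb[idx] <- agb; out_stage[idx] <- 4L
      out_water[idx] <- water; out_soiln[idx] <- soil_n
      break
    }
  }
  out_agb <- out_agb / 1000

  gf_mean <- if (gf_n > 0) gf_sum / gf_n else 1
  hi <- k$harvest_index * (k$hi_stress_floor + (1 - k$hi_stress_floor) * gf_mean)
  names(stage_dates) <- c("emergence", "jointing", "anthesis", "maturity")
  structure(list(
    days = data.frame(date = w$date, gdd = out_gdd, agb = out_agb,
                      stage = out_stage, water_stress = out_fw,
                      n_stress = out_fn, soil_water = out_water,
                      soil_n = out_soiln),
    yield = hi * agb / 1000,
    stage_dates = stage_dates,
    n_uptake = n_uptake, n_applied = n_applied,
    n_mineralized = n_mineralized
  ), class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  cat("winter-wheat season simulation\n")
  cat(sprintf("  days: %d, final AGB %.2f t/ha, yield %.2f t/ha\n",
              nrow(x$days), max(x$days$agb), x$yield))
  sd <- x$stage_dates
  cat("  stages:", paste(names(sd), format(sd), collapse = ", "), "\n")
  invisible(x)
}

# --- crop-model registry: alternate implementations can register under a
#     name and be selected from configs/CLI -----------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Register or retrieve a crop-model implementation
#'
#' A crop model is any function with the signature
#' `(weather, soil, mgmt, cultivar)` returning a `simulation_output`. The
#' surrogate is pre-registered as `"surrogate"`.
#'
#' @param name Registry key.
#' @param fn Model function (for `register_crop_model`).
#' @return `get_crop_model` returns the function; `register_crop_model` is
#'   called for its side effect.
#' @export
register_crop_model <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .model_registry)
  invisible(name)
}

#' @rdname register_crop_model
#' @export
get_crop_model <- function(name = "surrogate") {
  if (!exists(name, envir = .model_registry)) {
    if (name == "surrogate") {
      register_crop_model("surrogate", function(weather, soil, mgmt, cultivar)
        simulate_season(weather, soil, mgmt, cultivar))
    } else {
      stop("unknown crop model: ", name)
    }
  }
  get(name, envir = .model_registry)
}
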