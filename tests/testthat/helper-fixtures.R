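# Shared fixtures, memoized so expensive objects are built once per test run.
.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, build) {
  if (!exists(key, envir = .fx)) assign(key, build(), envir = .fx)
  get(key, envir = .fx)
}

# standard season weather (seed fixed: part of the stated world, not a dial)
fx_weather <- function() {
  fx_memo("weather", function() generate_weather("2017-10-01", 300, seed = 11))
}

fx_soil <- function() soil_init()

# management with an explicit basal + jointing topdressing split
fx_mgmt <- function(basal = 90, topdress = 90, sowing = "2017-10-01") {
  management_plan(
    sowing,
    fertilization_events = data.frame(
      date = as.Date(c(sowing, "2018-04-20")),
      amount = c(basal, topdress),
      type = c("basal", "topdress")),
    irrigation_events = data.frame(
      date = as.Date(c("2017-11-15", "2018-03-20", "2018-04-20")),
      amount = c(50, 50, 50)))
}

# truth run used by several twin experiments: total 200 kg N, equal split
fx_truth <- function() {
  fx_memo("truth", function()
    simulate_season(fx_weather(), fx_soil(), fx_mgmt(100, 100),
                    cultivar_params()))
}

# the four observation dates of a twin (jointing, +20 d, anthesis, +12 d)
fx_obs_dates <- function() {
  tr <- fx_truth()
  sort(c(tr$stage_dates[["jointing"]], tr$stage_dates[["jointing"]] + 20,
         tr$stage_dates[["anthesis"]], tr$stage_dates[["anthesis"]] + 12))
}

fx_truth_agb <- function() {
  tr <- fx_truth()
  tr$days$agb[match(fx_obs_dates(), tr$days$date)]
}

# noiseless standard experiment (the fixture of the pipeline-level tests)
fx_experiment_noiseless <- function() {
  fx_memo("exp_noiseless", function()
    generate_experiment(noise = noise_model_none(), seed = 1))
}
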