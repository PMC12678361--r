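test_that("weather generator obeys its construction invariants", {
  w <- generate_weather("2017-10-01", 300, seed = 5)
  expect_equal(nrow(w), 300)
  expect_true(all(w$tmax >= w$tmin))
  expect_true(all(w$precip >= 0))
  doy <- as.integer(format(w$date, "%j"))
  dl <- daylength_hours(doy, 40.17)
  expect_true(all(w$sunshine_hours >= 0 & w$sunshine_hours <= dl + 0.01))
  expect_identical(w, generate_weather("2017-10-01", 300, seed = 5))
  expect_false(identical(w$precip,
                         generate_weather("2017-10-01", 300, seed = 6)$precip))
})

test_that("full-year precipitation lands in the site's annual range", {
  ok <- vapply(1:20, function(s) {
    total <- sum(generate_weather("2017-01-01", 365, seed = s)$precip)
    total >= 400 - 5 && total <= 620 + 5 # rounding slack on daily amounts
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("experiment design arithmetic matches the trial layout", {
  d <- experiment_design()
  expect_equal(d$n_plots, 32)
  expect_equal(d$n_samples, 128)
  expect_equal(d$topdressing_fractions, c(0, 0.25, 0.5, 0.75, 1, 1.25))
  d2 <- experiment_design(varieties = 1, replicates = 2)
  expect_equal(d2$n_plots, 8)
})

test_that("generated experiment emits 32 plots and 128 samples of each kind", {
  ex <- fx_experiment_noiseless()
  expect_equal(nrow(ex$plots), 32)
  expect_equal(nrow(ex$agb_obs), 128)
  expect_equal(nrow(ex$spectra), 128)
  expect_equal(length(unique(ex$agb_obs$plot_id)), 32)
  expect_equal(length(unique(ex$agb_obs$date)), 4)
})

test_that("noiseless reflectance inverts the HLM exactly", {
  ex <- fx_experiment_noiseless()
  pred <- hlm_predict(evi2(ex$spectra$nir, ex$spectra$red), ex$spectra$gdd)
  expect_equal(pred, ex$spectra$agb_truth, tolerance = 1e-6)
  # noisy mode perturbs the round trip but stays in the right ballpark
  exn <- generate_experiment(noise = noise_model(), seed = 1)
  predn <- hlm_predict(evi2(exn$spectra$nir, exn$spectra$red),
                       exn$spectra$gdd)
  expect_gt(cor(predn, exn$spectra$agb_truth), 0.95)
})

test_that("plot yields are non-decreasing across N rates without soil
           heterogeneity", {
  ex <- fx_experiment_noiseless()
  for (v in 1:2) {
    m <- aggregate(yield ~ n_rate, ex$plots[ex$plots$variety == v, ], mean)
    m <- m[order(m$n_rate), ]
    expect_true(all(diff(m$yield) >= -1e-9))
  }
})

test_that("generator is reproducible per seed", {
  a <- generate_experiment(noise = noise_model(), seed = 42)
  b <- generate_experiment(noise = noise_model(), seed = 42)
  expect_identical(a$plots, b$plots)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$agb_obs, b$agb_obs)
})

test_that("topdressing trial applies each fraction of the recommended rate", {
  ex <- fx_experiment_noiseless()
  ids <- ex$plots$plot_id[1:2]
  rec <- stats::setNames(c(120, 80), ids)
  trial <- generate_topdressing_trial(ex, rec)
  expect_equal(nrow(trial), 2 * 6)
  expect_equal(sort(unique(trial$treatment)),
               paste0("T", 0:5))
  expect_equal(trial$n_topdress[trial$plot_id == ids[1]],
               c(0, 0.25, 0.5, 0.75, 1, 1.25) * 120)

  # fraction 0 equals the explicit no-topdressing control run
  ctrl_m <- ex$mgmt[[ids[1]]]
  ctrl_m$fertilization_events <- data.frame(
    date = c(ctrl_m$sowing_date, ex$jointing_date),
    amount = c(90, 0), type = c("basal", "topdress"))
  ctrl <- simulate_season(ex$weather, ex$soil, ctrl_m, cultivar_params())
  expect_equal(trial$yield[trial$plot_id == ids[1] & trial$fraction == 0],
               ctrl$yield)

  # yields non-decreasing in the fraction; full rate at least as profitable
  # as 125% (the rate is near the economic optimum by construction)
  y1 <- trial[trial$plot_id == ids[1], ]
  expect_true(all(diff(y1$yield[order(y1$fraction)]) >= -1e-9))
})
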