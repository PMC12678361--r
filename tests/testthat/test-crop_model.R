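test_that("growing_degree_days matches direct arithmetic and clamps", {
  expect_equal(growing_degree_days(20, 10, 0), 15)
  expect_equal(growing_degree_days(5, 5, 5), 0)
  expect_equal(growing_degree_days(2, -6, 0), 0)
  expect_error(growing_degree_days(5, 10), "tmax < tmin")
})

test_that("Angstrom-Prescott limits and errors", {
  ra <- 30
  expect_equal(solar_radiation_angstrom(12, 12, ra), 0.75 * ra)
  expect_equal(solar_radiation_angstrom(0, 12, ra), 0.25 * ra)
  expect_equal(solar_radiation_angstrom(5, 12, 0), 0)
  expect_error(solar_radiation_angstrom(13, 12, ra), "sunshine")
  expect_error(solar_radiation_angstrom(5, 0, ra), "daylength")
})

test_that("cumulative GDD over constant weather is direct arithmetic", {
  w <- data.frame(date = as.Date("2018-03-01") + 0:99,
                  tmax = 20, tmin = 10, precip = 0, srad = 15)
  m <- management_plan("2018-03-01")
  out <- simulate_season(w, soil_init(), m, cultivar_params())
  expect_equal(out$days$gdd[100], 1500)
  expect_equal(out$days$gdd, cumsum(rep(15, 100)))
})

test_that("simulator is deterministic and monotone in N", {
  w <- fx_weather()
  a <- simulate_season(w, fx_soil(), fx_mgmt(90, 90), cultivar_params())
  b <- simulate_season(w, fx_soil(), fx_mgmt(90, 90), cultivar_params())
  expect_identical(a, b)

  y0 <- simulate_season(w, fx_soil(), fx_mgmt(0, 0), cultivar_params())$yield
  y270 <- simulate_season(w, fx_soil(), fx_mgmt(135, 135),
                          cultivar_params())$yield
  expect_lte(y0, y270)
})

test_that("N response over the 0-360 grid is monotone and saturating", {
  w <- fx_weather()
  grid <- n_search_grid()
  ys <- vapply(grid, function(td)
    simulate_season(w, fx_soil(), fx_mgmt(90, td), cultivar_params())$yield,
    numeric(1))
  dy <- diff(ys)
  expect_true(all(dy >= -1e-12))
  infl <- which.max(dy)
  expect_true(all(diff(dy[infl:length(dy)]) <= 1e-9))
})

test_that("trajectory invariants: AGB and GDD non-decreasing, stresses in [0,1],
           yield within final AGB", {
  out <- fx_truth()
  expect_true(all(diff(out$days$agb) >= -1e-12))
  expect_true(all(diff(out$days$gdd) >= 0))
  expect_true(all(out$days$water_stress >= 0 & out$days$water_stress <= 1))
  expect_true(all(out$days$n_stress >= 0 & out$days$n_stress <= 1))
  expect_gte(out$yield, 0)
  expect_lte(out$yield, max(out$days$agb))
})

test_that("conservation: N uptake bounded by sources, water within bucket", {
  out <- fx_truth()
  expect_lte(out$n_uptake,
             (fx_soil()$no3_n + fx_soil()$nh4_n) * 3.9 + out$n_applied +
               out$n_mineralized + 1e-9)
  expect_true(all(out$days$soil_water >= 0))
  expect_true(all(out$days$soil_water <=
                    fx_soil()$water_holding_capacity + 1e-9))

  # with mineralization off, the spec's exact inequality holds
  k <- crop_constants(); k$mineralization_per_om <- 0
  out2 <- simulate_season(fx_weather(), fx_soil(), fx_mgmt(100, 100),
                          cultivar_params(), constants = k)
  expect_lte(out2$n_uptake,
             (fx_soil()$no3_n + fx_soil()$nh4_n) * 3.9 + out2$n_applied + 1e-9)
})

test_that("stress-free limit: unlimited N and water give potential growth", {
  w <- fx_weather()
  rich_soil <- soil_init(no3_n = 1e5, nh4_n = 1e5,
                         water_holding_capacity = 1e6, initial_water = 1e6)
  m <- fx_mgmt(90, 90)
  m$irrigation_events$amount <- rep(1e5, 3)
  out <- simulate_season(w, rich_soil, m, cultivar_params())
  grow <- out$days$stage >= 1 & out$days$stage < 4
  expect_true(all(out$days$water_stress[grow] == 1))
  expect_true(all(out$days$n_stress[grow] == 1))
})

test_that("weather gaps and out-of-range parameters are rejected", {
  w <- fx_weather()
  expect_error(simulate_season(w[-5, ], fx_soil(), fx_mgmt(),
                               cultivar_params()), "gap")
  expect_error(cultivar_params(p1d = 80), "outside")
  clamped <- cultivar_params(p1d = 80, check = "clamp")
  expect_equal(clamped$p1d, 70)
  w2 <- w; w2$date <- w2$date + 400
  expect_error(simulate_season(w2, fx_soil(), fx_mgmt(), cultivar_params()),
               "sowing date")
})

test_that("soil and management constructors validate their invariants", {
  expect_error(soil_init(initial_water = 200, water_holding_capacity = 100),
               "exceeds")
  expect_error(soil_init(no3_n = -1), "non-negative")
  expect_error(management_plan("2017-10-01", plant_density = 0), "> 0")
  expect_error(
    management_plan("2017-10-01",
                    irrigation_events = data.frame(date = "2017-11-01",
                                                   amount = -5)),
    "non-negative")
})

test_that("crop-model registry returns the surrogate and rejects unknowns", {
  fn <- get_crop_model("surrogate")
  out <- fn(fx_weather(), fx_soil(), fx_mgmt(90, 90), cultivar_params())
  expect_s3_class(out, "simulation_output")
  expect_error(get_crop_model("no-such-model"), "unknown crop model")
})
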