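test_that("fitness_j is the mean relative squared error", {
  expect_equal(fitness_j(c(5, 6), c(5, 6)), 0)
  expect_equal(fitness_j(c(5, 6), c(4, 6)), 0.03125)
  expect_equal(fitness_j(2, 4), 0.25)
  expect_error(fitness_j(1:3, 1:2), "length mismatch")
  expect_error(fitness_j(c(1, 2), c(0, 2)), "positive")
})

test_that("swarm initialization respects the published defaults", {
  specs <- default_parameter_specs()
  cfg <- swarm_config()
  expect_equal(cfg$n_particles, 25L)
  expect_equal(cfg$c1, 2.0)
  expect_equal(cfg$c2, 2.0)
  expect_equal(cfg$max_iterations, 100L)
  expect_equal(cfg$initial_velocity_fraction, 0.10)

  set.seed(1)
  sw <- initialize_swarm(specs, cfg)
  expect_equal(nrow(sw$position), 25)
  expect_equal(unname(sw$position[1, ]), specs$initial)
  for (j in seq_len(nrow(specs))) {
    expect_true(all(sw$position[, j] >= specs$lower[j]))
    expect_true(all(sw$position[, j] <= specs$upper[j]))
    rng <- specs$upper[j] - specs$lower[j]
    expect_true(all(abs(sw$velocity[, j]) <= 0.1 * rng + 1e-12))
  }
  set.seed(1)
  sw2 <- initialize_swarm(specs, cfg)
  expect_identical(sw, sw2)
  expect_error(initialize_swarm(specs[0, ], cfg), "empty")
})

test_that("particle update follows the velocity/position equations", {
  specs1 <- data.frame(name = "x", initial = 0, lower = -100, upper = 100)
  cfg <- swarm_config(initial_velocity_fraction = 1)
  # fixed point: at both bests with zero velocity
  up <- update_particle(0, 0, 0, 0, specs1, cfg, xi = 0.7, eta = 0.3)
  expect_equal(up$position, 0)
  expect_equal(up$velocity, 0)
  # x=0, v=1, pbest=gbest=0, xi=eta=0.5 -> v'=1, x'=1
  up <- update_particle(0, 1, 0, 0, specs1, cfg, xi = 0.5, eta = 0.5)
  expect_equal(up$velocity, 1)
  expect_equal(up$position, 1)
  # x=0, v=0, pbest=0, gbest=4, eta=0.5 -> v'=4, x'=4
  up <- update_particle(0, 0, 0, 4, specs1, cfg, xi = 0.5, eta = 0.5)
  expect_equal(up$velocity, 4)
  expect_equal(up$position, 4)
  # bound clamp zeroes velocity in the clamped dimension
  up <- update_particle(95, 20, 95, 95, specs1, cfg, xi = 0, eta = 0)
  expect_equal(up$position, 100)
  expect_equal(up$velocity, 0)
  expect_error(update_particle(0, 0, 0, 0, specs1, cfg, xi = 1.5, eta = 0.5),
               "xi, eta")
})

test_that("truth seeded in the swarm yields zero cost immediately", {
  obs <- data.frame(date = fx_obs_dates(), agb = fx_truth_agb())
  res <- assimilate(obs, fx_weather(), fx_soil(), fx_mgmt(100, 100),
                    cultivar_params(),
                    specs = default_parameter_specs(free = "fertilization"),
                    config = swarm_config(n_particles = 5,
                                          max_iterations = 5, seed = 2))
  # initial value 200 equals the truth total; particle 1 sits on it
  expect_equal(res$best_cost, 0, tolerance = 1e-25)
  expect_equal(res$best_position[["fertilization"]], 200)
})

test_that("gbest trajectory is non-increasing for several seeds", {
  obs <- data.frame(date = fx_obs_dates(), agb = fx_truth_agb() * 1.05)
  for (s in 1:3) {
    res <- assimilate(obs, fx_weather(), fx_soil(), fx_mgmt(100, 100),
                      cultivar_params(),
                      specs = default_parameter_specs(free = "fertilization"),
                      config = swarm_config(n_particles = 6,
                                            max_iterations = 15, seed = s))
    expect_true(all(diff(res$cost_trajectory) <= 1e-15))
    expect_equal(res$best_cost, min(res$cost_trajectory))
  }
})

test_that("same seed gives identical assimilation results", {
  obs <- data.frame(date = fx_obs_dates(), agb = fx_truth_agb() * 0.97)
  cfg <- swarm_config(n_particles = 6, max_iterations = 8, seed = 99)
  r1 <- assimilate(obs, fx_weather(), fx_soil(), fx_mgmt(100, 100),
                   cultivar_params(),
                   specs = default_parameter_specs(free = "fertilization"),
                   config = cfg)
  r2 <- assimilate(obs, fx_weather(), fx_soil(), fx_mgmt(100, 100),
                   cultivar_params(),
                   specs = default_parameter_specs(free = "fertilization"),
                   config = cfg)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$cost_trajectory, r2$cost_trajectory)
})

test_that("observation dates outside the season are reported", {
  obs <- data.frame(date = as.Date("2030-01-01"), agb = 5)
  expect_error(
    assimilate(obs, fx_weather(), fx_soil(), fx_mgmt(100, 100),
               cultivar_params(),
               specs = default_parameter_specs(free = "fertilization")),
    "2030-01-01")
})

test_that("1-D twin recovery matches an exhaustive grid-search oracle", {
  # truth fertilization 260 (away from the spec initial value); noiseless
  truth <- simulate_season(fx_weather(), fx_soil(), fx_mgmt(130, 130),
                           cultivar_params())
  dates <- fx_obs_dates()
  idx <- match(dates, truth$days$date)
  obs <- data.frame(date = dates, agb = truth$days$agb[idx])

  # oracle: 1 kg-step exhaustive search
  grid <- seq(0, 400, 1)
  jgrid <- vapply(grid, function(f) {
    sim <- simulate_season(fx_weather(), fx_soil(), fx_mgmt(f / 2, f / 2),
                           cultivar_params())
    fitness_j(sim$days$agb[idx], obs$agb)
  }, numeric(1))
  oracle_argmin <- grid[which.min(jgrid)]
  expect_equal(oracle_argmin, 260)

  res <- assimilate(obs, fx_weather(), fx_soil(), fx_mgmt(100, 100),
                    cultivar_params(),
                    specs = default_parameter_specs(free = "fertilization"),
                    config = swarm_config(n_particles = 10,
                                          max_iterations = 40, seed = 4))
  expect_lt(abs(res$best_position[["fertilization"]] - oracle_argmin), 1 + 1)
  expect_lte(res$best_cost, min(jgrid) + 1e-8)
})

test_that("parameter mapping reaches management and cultivar objects", {
  pos <- c(plant_density = 320, irrigation = 180, fertilization = 240,
           p1d = 60, phint = 110, rdgs = 3.2, slpf = 0.9)
  ap <- apply_parameters(pos, fx_mgmt(90, 90), cultivar_params())
  expect_equal(ap$mgmt$plant_density, 320)
  expect_equal(sum(ap$mgmt$irrigation_events$amount), 180)
  fe <- ap$mgmt$fertilization_events
  expect_equal(sum(fe$amount[fe$type == "basal"]), 120)
  expect_equal(sum(fe$amount[fe$type == "topdress"]), 120)
  expect_equal(ap$cultivar$p1d, 60)
  expect_equal(ap$cultivar$slpf, 0.9)
})
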