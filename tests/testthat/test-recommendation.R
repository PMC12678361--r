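test_that("economic benefit follows E = Y*Py - N*Pn with default prices", {
  expect_equal(economic_benefit(1, 0), 2.4)
  expect_equal(economic_benefit(6000, 180), 13905)
  expect_equal(economic_benefit(0, 0), 0)
  expect_error(economic_benefit(-1, 0), "non-negative")
  expect_error(economic_params(0, 1), "positive")
})

test_that("default N grid has 37 points", {
  g <- n_search_grid()
  expect_length(g, 37)
  expect_equal(g[1], 0)
  expect_equal(g[37], 360)
  expect_error(n_search_grid(100, 0), "invalid")
})

synthetic_curve <- function(a = 4000, b = 10, c = 0.02,
                            grid = n_search_grid(),
                            prices = economic_params()) {
  y <- a + b * grid - c * grid^2
  data.frame(n_rate = grid, yield_kg_ha = y,
             benefit = economic_benefit(y, grid, prices))
}

test_that("economic optimum matches a 1 kg-step brute-force argmax", {
  prices <- economic_params()
  cases <- list(c(4000, 10, 0.02), c(3000, 18, 0.05), c(5000, 6, 0.01))
  for (cs in cases) {
    curve <- synthetic_curve(cs[1], cs[2], cs[3])
    opt <- economic_optimum(curve)
    fine <- seq(0, 360, 1)
    yf <- cs[1] + cs[2] * fine - cs[3] * fine^2
    ef <- yf * prices$grain_price - fine * prices$n_price
    fine_opt <- fine[which.max(ef)]
    expect_lte(abs(opt$n_optimum - fine_opt), 10)
    # marginal rule: one grid step above the optimum cannot raise E
    i <- match(opt$n_optimum, curve$n_rate)
    if (i < nrow(curve)) {
      expect_lte(curve$benefit[i + 1] - curve$benefit[i], 1e-9)
    }
  }
})

test_that("flat yield curve puts the optimum at zero N", {
  curve <- data.frame(n_rate = n_search_grid(), yield_kg_ha = 5000)
  curve$benefit <- economic_benefit(curve$yield_kg_ha, curve$n_rate)
  expect_equal(economic_optimum(curve)$n_optimum, 0)
})

test_that("doubling the N price never increases the optimum", {
  for (cs in list(c(4000, 10, 0.02), c(3000, 18, 0.05))) {
    cheap <- synthetic_curve(cs[1], cs[2], cs[3])
    dear <- synthetic_curve(cs[1], cs[2], cs[3],
                            prices = economic_params(n_price = 5.5))
    expect_lte(economic_optimum(dear)$n_optimum,
               economic_optimum(cheap)$n_optimum)
  }
})

test_that("recommend_n returns the first attainment or flags infeasibility", {
  curve <- synthetic_curve()
  expect_equal(recommend_n(curve, 0)$n_recommended, 0)
  # increasing region: target at the optimum is met first at the optimum
  inc <- curve[curve$n_rate <= 250, ]
  opt <- economic_optimum(inc)
  rec <- recommend_n(inc, opt$target_yield)
  expect_equal(rec$n_recommended, opt$n_optimum)
  expect_false(rec$infeasible)
  over <- recommend_n(curve, max(curve$yield_kg_ha) + 1)
  expect_true(over$infeasible)
  expect_equal(over$n_recommended,
               curve$n_rate[which.max(curve$yield_kg_ha)])
})

test_that("recommend_n is non-increasing as the target drops", {
  curve <- synthetic_curve()
  targets <- sort(runif(10, 3500, max(curve$yield_kg_ha)), decreasing = TRUE)
  recs <- vapply(targets, function(t) recommend_n(curve, t)$n_recommended,
                 numeric(1))
  expect_true(all(diff(recs) <= 0))
})

test_that("reference curve reproduces the published fit", {
  expect_equal(reference_curve_predict(1), 92.61)
  expect_equal(reference_curve_predict(2), 92.61 * 2^-0.88)
  x <- seq(0.5, 5, by = 0.25)
  expect_true(all(diff(reference_curve_predict(x)) < 0))
  expect_error(reference_curve_predict(0), "positive")
  expect_error(power_law_curve(a = -1, b = -0.5), "a must")
  expect_error(power_law_curve(a = 1, b = 0.5), "b must")
})

test_that("fit_reference_curve identifies noiseless truth exactly and
           matches the closed-form log-linear oracle", {
  x <- c(0.8, 1.2, 1.9, 2.6, 3.3, 4.1)
  y <- 92.61 * x^-0.88
  fit <- fit_reference_curve(x, y)
  expect_equal(fit$curve$a, 92.61, tolerance = 1e-8)
  expect_equal(fit$curve$b, -0.88, tolerance = 1e-8)
  expect_equal(fit$r2_log, 1, tolerance = 1e-10)

  set.seed(17)
  yn <- y * exp(rnorm(length(y), 0, 0.1))
  fit <- fit_reference_curve(x, yn)
  # oracle: closed-form simple regression on logs
  lx <- log(x); ly <- log(yn)
  b <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  a <- exp(mean(ly) - b * mean(lx))
  expect_equal(fit$curve$b, b, tolerance = 1e-10)
  expect_equal(fit$curve$a, a, tolerance = 1e-10)
})

test_that("fitted exponent keeps its sign under small noise", {
  x <- seq(0.8, 4, length.out = 12)
  y <- 92.61 * x^-0.88
  for (s in 1:20) {
    set.seed(300 + s)
    fit <- fit_reference_curve(x, y * exp(rnorm(12, 0, 0.05)))
    expect_lt(fit$curve$b, 0)
  }
})

test_that("yield response curve varies only the topdressing and reports E", {
  grid <- seq(0, 120, 40)
  curve <- yield_response_curve(fx_weather(), fx_soil(), fx_mgmt(90, 0),
                                cultivar_params(), grid = grid)
  expect_equal(nrow(curve), 4)
  expect_true(all(diff(curve$yield_kg_ha) >= -1e-9))
  expect_equal(curve$benefit[1], curve$yield_kg_ha[1] * 2.4)
  expect_equal(curve$benefit,
               curve$yield_kg_ha * 2.4 - curve$n_rate * 2.75)
})
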