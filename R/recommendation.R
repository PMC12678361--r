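#' Economic parameters for the N recommendation
#'
#' @param grain_price Farm-gate wheat price P_Y, CNY kg-1 (default 2.4).
#' @param n_price N fertilizer cost P_N, CNY kg-1 (default 2.75).
#' @return An `economic_params` list.
#' @export
economic_params <- function(grain_price = 2.4, n_price = 2.75) {
  if (grain_price <= 0 || n_price <= 0) {
    stop("economic_params: prices must be positive")
  }
  structure(list(grain_price = grain_price, n_price = n_price),
            class = "economic_params")
}

#' Field-scale economic benefit
#'
#' E = Y x P_Y - N x P_N: grain revenue minus fertilizer cost.
#'
#' @param yield_kg_ha Grain yield, kg ha-1.
#' @param n_rate Applied N, kg ha-1.
#' @param prices An [economic_params()].
#' @return Net benefit, CNY ha-1.
#' @export
#' @examples
#' economic_benefit(6000, 180)  # 14400 - 495 = 13905
economic_benefit <- function(yield_kg_ha, n_rate, prices = economic_params()) {
  if (any(yield_kg_ha < 0) || any(n_rate < 0)) {
    stop("economic_benefit: inputs must be non-negative")
  }
  yield_kg_ha * prices$grain_price - n_rate * prices$n_price
}

#' Topdressing-N search grid
#'
#' @param n_min,n_max Grid limits, kg N ha-1 (defaults 0 and 360).
#' @param step Increment, kg N ha-1 (default 10).
#' @return Numeric vector of candidate rates.
#' @export
n_search_grid <- function(n_min = 0, n_max = 360, step = 10) {
  if (n_min > n_max || step <= 0) stop("invalid N search grid")
  seq(n_min, n_max, by = step)
}

#' Yield response to topdressing N with an assimilated model
#'
#' Runs the crop model once per candidate N rate, varying only the
#' jointing-stage topdressing event, and evaluates the economic benefit of
#' each rate.
#'
#' @param weather,soil,mgmt,cultivar Season inputs, typically the assimilated
#'   `mgmt`/`cultivar` from an [assimilate()] result.
#' @param grid Candidate topdressing rates, kg N ha-1 (see [n_search_grid()]).
#' @param prices An [economic_params()].
#' @param model Crop-model function; default the registered surrogate.
#' @return Data frame with columns `n_rate` (kg ha-1), `yield_kg_ha`, and
#'   `benefit` (CNY ha-1).
#' @export
yield_response_curve <- function(weather, soil, mgmt, cultivar,
                                 grid = n_search_grid(),
                                 prices = economic_params(),
                                 model = get_crop_model("surrogate")) {
  fe <- mgmt$fertilization_events
  if (!any(fe$type == "topdress")) {
    fe <- rbind(fe, data.frame(date = mgmt$sowing_date + 170, amount = 0,
                               type = "topdress"))
  }
  rows <- lapply(grid, function(nn) {
    fe2 <- fe
    fe2$amount[fe2$type == "topdress"] <- nn / sum(fe2$type == "topdress")
    m2 <- mgmt; m2$fertilization_events <- fe2
    sim <- tryCatch(model(weather, soil, m2, cultivar), error = function(e) {
      stop("simulation failed at N = ", nn, " kg/ha: ", conditionMessage(e))
    })
    y <- sim$yield * 1000
    data.frame(n_rate = nn, yield_kg_ha = y,
               benefit = economic_benefit(y, nn, prices))
  })
  do.call(rbind, rows)
}

#' Economically optimal N rate and the target yield it defines
#'
#' The optimum is the grid rate maximizing net benefit E (lowest rate on
#' ties); its simulated yield becomes the target yield the recommendation
#' must meet.
#'
#' @param curve A response curve from [yield_response_curve()] (columns
#'   n_rate, yield_kg_ha, benefit).
#' @return List with `n_optimum` (kg ha-1), `target_yield` (kg ha-1), and
#'   `benefit` (CNY ha-1) at the optimum.
#' @export
economic_optimum <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 1,
            all(c("n_rate", "yield_kg_ha", "benefit") %in% names(curve)))
  i <- which(curve$benefit >= max(curve$benefit) - 1e-9)[1] # lowest N on ties
  list(n_optimum = curve$n_rate[i], target_yield = curve$yield_kg_ha[i],
       benefit = curve$benefit[i])
}

#' Lowest N rate attaining a target yield
#'
#' @param curve A response curve (see [economic_optimum()]).
#' @param target_yield Target, kg ha-1.
#' @return List with `n_recommended` (kg ha-1), `yield_kg_ha` at that rate,
#'   and `infeasible` (TRUE when no grid rate attains the target; the
#'   max-yield rate is then reported).
#' @export
recommend_n <- function(curve, target_yield) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 1)
  ok <- which(curve$yield_kg_ha >= target_yield - 1e-9)
  if (length(ok) == 0) {
    i <- which.max(curve$yield_kg_ha)
    return(list(n_recommended = curve$n_rate[i],
                yield_kg_ha = curve$yield_kg_ha[i], infeasible = TRUE))
  }
  i <- ok[which.min(curve$n_rate[ok])]
  list(n_recommended = curve$n_rate[i], yield_kg_ha = curve$yield_kg_ha[i],
       infeasible = FALSE)
}

#' AGB-to-N power-law reference curve
#'
#' @param a Coefficient (> 0).
#' @param b Exponent (< 0; more jointing-stage biomass means less N needed).
#' @return A `power_law_curve` list.
#' @seealso [reference_curve_published()] for the field-fitted values
#'   (92.61, -0.88).
#' @export
power_law_curve <- function(a, b) {
  if (a <= 0) stop("power_law_curve: a must be > 0")
  if (b >= 0) stop("power_law_curve: b must be < 0")
  structure(list(a = a, b = b), class = "power_law_curve")
}

#' Predict topdressing N from jointing-stage AGB via the reference curve
#'
#' A lightweight alternative to full assimilation: N = a * AGB^b.
#'
#' @param agb_jointing AGB at the jointing stage, t ha-1 (> 0). Vectorized.
#' @param curve A [power_law_curve()], default the published one.
#' @return Recommended N, kg ha-1.
#' @export
#' @examples
#' reference_curve_predict(1)  # 92.61
reference_curve_predict <- function(agb_jointing,
                                    curve = reference_curve_published()) {
  stopifnot(inherits(curve, "power_law_curve"))
  if (any(agb_jointing <= 0)) {
    stop("reference_curve_predict: AGB must be positive")
  }
  curve$a * agb_jointing^curve$b
}

#' Fit the AGB-to-N reference curve
#'
#' Least-squares fit of ln(N) = ln(a) + b ln(AGB). R-squared is reported on
#' the log scale (the fitting scale) and, separately labelled, on the
#' original scale.
#'
#' @param agb_jointing,n_recommended Positive paired vectors (>= 3 pairs).
#' @return List: `curve` ([power_law_curve()]), `r2_log`, `r2_original`, `n`.
#' @export
fit_reference_curve <- function(agb_jointing, n_recommended) {
  if (length(agb_jointing) != length(n_recommended)) {
    stop("fit_reference_curve: length mismatch")
  }
  if (length(agb_jointing) < 3) stop("fit_reference_curve: need >= 3 pairs")
  if (any(agb_jointing <= 0) || any(n_recommended <= 0)) {
    stop("fit_reference_curve: values must be positive")
  }
  lx <- log(agb_jointing); ly <- log(n_recommended)
  fit <- stats::lm(ly ~ lx)
  a <- exp(unname(stats::coef(fit)[1])); b <- unname(stats::coef(fit)[2])
  pred_log <- stats::fitted(fit)
  r2 <- function(y, f) 1 - sum((y - f)^2) / sum((y - mean(y))^2)
  list(curve = power_law_curve(a = a, b = b),
       r2_log = r2(ly, pred_log),
       r2_original = r2(n_recommended, a * agb_jointing^b),
       n = length(agb_jointing))
}
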