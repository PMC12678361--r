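#' Reference constants of the wheat growth surrogate
#'
#' Every empirical constant of the daily growth surrogate lives in this one
#' table so an alternative crop model (e.g. a DSSAT adapter) can replace the
#' whole module without touching the rest of the pipeline. Values are
#' conventional for winter wheat in temperate climates; they are not claimed
#' to match DSSAT/CERES-Wheat numerically.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{tbase}{Base temperature for growing degree days (0 degC).}
#'   \item{k_extinction}{Beer's-law canopy light extinction coefficient (0.5).}
#'   \item{rue}{Radiation use efficiency, g dry matter per MJ intercepted
#'     PAR (3.0 g MJ-1).}
#'   \item{par_fraction}{Photosynthetically active fraction of global solar
#'     radiation (0.48).}
#'   \item{nc_a, nc_b}{Critical N dilution curve Nc(%) = nc_a * W^-nc_b with
#'     W shoot biomass in t ha-1 (5.35, 0.442); Nc held constant below
#'     nc_w_min = 1.55 t ha-1.}
#'   \item{nc_w_min}{Biomass floor of the dilution curve (1.55 t ha-1).}
#'   \item{harvest_index}{Potential harvest index (0.45), scaled down by mean
#'     grain-fill stress.}
#'   \item{bulk_density, soil_depth_m}{Topsoil bulk density (1.3 g cm-3) and
#'     sampled depth (0.30 m) used to convert mg kg-1 mineral N to kg ha-1;
#'     the product x 10 gives kg ha-1 per mg kg-1 (3.9).}
#'   \item{lai_per_kg}{Green leaf area index per kg ha-1 of AGB (0.0006),
#'     i.e. LAI 3 at 5 t ha-1.}
#'   \item{lai_max}{Upper cap on LAI (7).}
#'   \item{agb0_per_plant}{Initial shoot dry mass per plant at emergence
#'     (0.05 g), so initial AGB (kg ha-1) = 0.5 x plant density (m-2).}
#'   \item{phen_gdd}{Development thresholds (degC d of development time) for
#'     emergence, jointing, anthesis and maturity at phint = 100; the whole
#'     vector is scaled by phint/100.}
#'   \item{photoperiod_opt}{Optimal (non-limiting) daylength, h (20).}
#'   \item{p1d_scale}{Development-rate penalty per unit p1d per hour of
#'     daylength shortfall (1/1000).}
#'   \item{root_depth0, root_depth_max}{Initial (10 cm) and maximum (120 cm)
#'     rooting depth; depth grows by rdgs x root_gdd_gain cm per degC d.}
#'   \item{root_gdd_gain}{Root elongation per unit GDD per unit rdgs
#'     (0.02 cm per degC d).}
#'   \item{water_extract_frac}{Fraction of root-accessible soil water
#'     extractable per day (0.12).}
#'   \item{n_uptake_frac}{Fraction of root-accessible mineral N available for
#'     uptake per day (0.07); with mineralization_per_om it was calibrated
#'     once so that (a) the economic optimum topdressing declines by ~100
#'     kg ha-1 as basal N rises from 0 to 135 kg ha-1 (the pattern field
#'     response curves show) and (b) a 200 kg ha-1 twin-experiment dressing
#'     stays identifiable from stage-wise AGB under 5% observation noise.}
#'   \item{mineralization_per_om}{Daily net N mineralization per g kg-1 of
#'     soil organic matter (0.005 kg ha-1 d-1).}
#'   \item{n_loss_frac}{Daily fractional loss of mineral N
#'     (denitrification/leaching); 0 by default.}
#'   \item{senescence_min}{Minimum green-area fraction retained at maturity
#'     (0.3); green LAI declines linearly over grain fill.}
#'   \item{temp_opt_lo, temp_opt_hi, temp_max}{Trapezoidal temperature
#'     response of radiation use efficiency: zero at tbase, rising to 1 at
#'     temp_opt_lo (12 degC), flat to temp_opt_hi (22 degC), zero again at
#'     temp_max (34 degC).}
#'   \item{hi_stress_floor}{Fraction of the potential harvest index retained
#'     under total grain-fill stress (0.5): HI = harvest_index x
#'     (floor + (1 - floor) x mean grain-fill stress factor).}
#' }
#' @export
#' @examples
#' crop_constants()$rue
crop_constants <- function() {
  list(
    tbase               = 0,
    k_extinction        = 0.5,
    rue                 = 3.0,
    par_fraction        = 0.48,
    nc_a                = 5.35,
    nc_b                = 0.442,
    nc_w_min            = 1.55,
    harvest_index       = 0.45,
    bulk_density        = 1.3,
    soil_depth_m        = 0.30,
    lai_per_kg          = 0.0006,
    lai_max             = 7,
    agb0_per_plant      = 0.05,
    phen_gdd            = c(emergence = 120, jointing = 600,
                            anthesis = 1100, maturity = 1700),
    photoperiod_opt     = 20,
    p1d_scale           = 1 / 1000,
    root_depth0         = 10,
    root_depth_max      = 120,
    root_gdd_gain       = 0.02,
    water_extract_frac  = 0.12,
    n_uptake_frac       = 0.07,
    mineralization_per_om = 0.005,
    n_loss_frac         = 0,
    senescence_min      = 0.3,
    temp_opt_lo         = 12,
    temp_opt_hi         = 22,
    temp_max            = 34,
    hi_stress_floor     = 0.5
  )
}

#' Published hierarchical-linear-model coefficients
#'
#' The four level-2 coefficients mapping (EVI2, GDD covariate) to AGB
#' (t ha-1): intercept and GDD slope of the level-1 intercept beta0, and
#' intercept and GDD slope of the level-1 slope beta1.
#'
#' @return An `hlm_coefficients` object with g00 = 1.22, g01 = 0.02,
#'   g10 = -13.35, g11 = 0.38.
#' @seealso [hlm_coefficients()], [hlm_predict()]
#' @export
hlm_published <- function() {
  hlm_coefficients(g00 = 1.22, g01 = 0.02, g10 = -13.35, g11 = 0.38)
}

#' Published AGB-to-N reference power-law curve
#'
#' Field-fitted relationship between jointing-stage AGB (t ha-1) and the
#' recommended topdressing N rate (kg ha-1): N = 92.61 * AGB^-0.88.
#'
#' @return A `power_law_curve` with a = 92.61, b = -0.88.
#' @seealso [reference_curve_predict()]
#' @export
reference_curve_published <- function() {
  power_law_curve(a = 92.61, b = -0.88)
}
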