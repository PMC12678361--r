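#' Two-band enhanced vegetation index
#'
#' EVI2 = 2.5 (NIR - R) / (NIR + 2.4 R + 1), where NIR and R are surface
#' reflectances in the near-infrared (~840 nm) and red (~650 nm) bands. The
#' constants correct for soil background and atmospheric effects while
#' resisting saturation over dense canopies.
#'
#' @param nir,red Reflectance in [0, 1]. Vectorized.
#' @return The index value (dimensionless).
#' @export
#' @examples
#' evi2(0.4, 0.08)   # 0.50251...
evi2 <- function(nir, red) {
  if (any(nir < 0 | nir > 1) || any(red < 0 | red > 1)) {
    stop("evi2: reflectances must lie in [0, 1]")
  }
  2.5 * (nir - red) / (nir + 2.4 * red + 1)
}

#' Hierarchical-linear-model coefficient set
#'
#' Level 1 regresses AGB on EVI2 (intercept beta0, slope beta1); level 2 lets
#' both level-1 coefficients vary linearly with the thermal-time covariate:
#' beta_j = g_j0 + g_j1 * GDD. Equivalently AGB = g00 + g01 GDD + g10 EVI2 +
#' g11 GDD x EVI2.
#'
#' @param g00,g01 Intercept and GDD slope of beta0.
#' @param g10,g11 Intercept and GDD slope of beta1.
#' @return An `hlm_coefficients` object.
#' @seealso [hlm_published()] for the field-calibrated values.
#' @export
hlm_coefficients <- function(g00, g01, g10, g11) {
  v <- c(g00 = g00, g01 = g01, g10 = g10, g11 = g11)
  if (any(!is.finite(v))) stop("hlm_coefficients: all must be finite")
  structure(as.list(v), class = "hlm_coefficients")
}

#' @export
print.hlm_coefficients <- function(x, ...) {
  cat(sprintf(
    "HLM: AGB = (%.4g + %.4g GDD) + (%.4g + %.4g GDD) x EVI2\n",
    x$g00, x$g01, x$g10, x$g11))
  invisible(x)
}

#' Predict AGB from EVI2 and the thermal-time covariate
#'
#' Raw model value beta0(GDD) + beta1(GDD) * EVI2 with no clamping, so
#' published coefficients are reproduced exactly; at low GDD/EVI2 the raw
#' value can be negative. Set `clamp = TRUE` (map production) to floor at 0.
#'
#' @param evi2 Vegetation index value(s).
#' @param gdd Thermal-time covariate on the same scale the coefficients were
#'   fitted on (see the synthetic generator's `gdd_scale`).
#' @param coeffs An [hlm_coefficients()] set, default the published one.
#' @param clamp Floor predictions at zero (default FALSE).
#' @return Predicted AGB, t ha-1.
#' @export
#' @examples
#' hlm_predict(0, 0)          # 1.22, the published beta0 intercept
#' hlm_predict(0.5, 100)      # 15.545
hlm_predict <- function(evi2, gdd, coeffs = hlm_published(), clamp = FALSE) {
  stopifnot(inherits(coeffs, "hlm_coefficients"))
  b0 <- coeffs$g00 + coeffs$g01 * gdd
  b1 <- coeffs$g10 + coeffs$g11 * gdd
  out <- b0 + b1 * evi2
  if (clamp) out <- pmax(0, out)
  out
}

#' Fit the hierarchical linear model
#'
#' Default method fits the expanded interaction form
#' AGB ~ GDD + EVI2 + GDD:EVI2 by least squares, algebraically identical to
#' the two-level formulation. A stagewise method (level-1 fits per group,
#' then level-2 regressions of the per-group coefficients on mean GDD) is
#' provided for comparison; it requires a `stage` column.
#'
#' @param samples Data frame with columns `evi2` (or `nir` + `red`), `gdd`
#'   and `agb_measured`; the stagewise method also needs `stage`.
#' @param method "interaction" (default) or "stagewise".
#' @return List with `coefficients` ([hlm_coefficients()]), `r2` (adjusted,
#'   p = 3), `rmse`, `nrmse` (%), `n`, `fitted`.
#' @export
hlm_fit <- function(samples, method = c("interaction", "stagewise")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(samples))
  if (is.null(samples$evi2)) {
    if (is.null(samples$nir) || is.null(samples$red)) {
      stop("hlm_fit: need an 'evi2' column or 'nir' and 'red'")
    }
    samples$evi2 <- evi2(samples$nir, samples$red)
  }
  if (is.null(samples$agb_measured) || is.null(samples$gdd)) {
    stop("hlm_fit: need 'gdd' and 'agb_measured' columns")
  }
  if (nrow(samples) < 4) stop("hlm_fit: need at least 4 samples")
  if (length(unique(samples$gdd)) < 2) {
    stop("singular fit: all samples share one GDD value; ",
         "columns gdd and gdd:evi2 are collinear with the intercept terms")
  }

  if (method == "interaction") {
    fit <- stats::lm(agb_measured ~ gdd * evi2, data = samples)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("singular fit: collinear column(s) ", paste(bad, collapse = ", "))
    }
    cf <- stats::coef(fit)
    co <- hlm_coefficients(g00 = unname(cf["(Intercept)"]),
                           g01 = unname(cf["gdd"]),
                           g10 = unname(cf["evi2"]),
                           g11 = unname(cf["gdd:evi2"]))
  } else {
    if (is.null(samples$stage)) stop("stagewise method needs a 'stage' column")
    grp <- split(samples, samples$stage)
    if (length(grp) < 2) stop("stagewise method needs >= 2 stages")
    lev1 <- do.call(rbind, lapply(grp, function(g) {
      f <- stats::lm(agb_measured ~ evi2, data = g)
      data.frame(gdd = mean(g$gdd), b0 = stats::coef(f)[1],
                 b1 = stats::coef(f)[2])
    }))
    f0 <- stats::lm(b0 ~ gdd, data = lev1)
    f1 <- stats::lm(b1 ~ gdd, data = lev1)
    co <- hlm_coefficients(g00 = unname(stats::coef(f0)[1]),
                           g01 = unname(stats::coef(f0)[2]),
                           g10 = unname(stats::coef(f1)[1]),
                           g11 = unname(stats::coef(f1)[2]))
  }
  pred <- hlm_predict(samples$evi2, samples$gdd, co)
  list(coefficients = co,
       r2 = r2_adjusted(samples$agb_measured, pred, p = 3),
       rmse = rmse(samples$agb_measured, pred),
       nrmse = nrmse(samples$agb_measured, pred),
       n = nrow(samples), fitted = pred)
}

#' Convert a destructive 20-stem sample to per-hectare AGB
#'
#' Field protocol: 20 stems are cut, oven-dried and weighed together; the
#' per-area biomass follows from the stand's stem density. The raw conversion
#' is (D x n x 15) / 20; its constants do not by themselves produce t ha-1
#' from grams and stems ha-1, so the unit normalization is an explicit
#' argument rather than silently absorbed (default 1e-6, g ha-1 to t ha-1).
#'
#' @param total_dry_mass_20stems Combined dry mass of the 20-stem sample, g.
#' @param stems_per_hectare Stem count per hectare at the sampling stage.
#' @param scale Unit normalization applied to the raw formula value
#'   (default 1e-6).
#' @return AGB in t ha-1 (under the default scale).
#' @export
#' @examples
#' plot_agb_from_sampling(20, 20, scale = 1)  # raw formula value: 300
plot_agb_from_sampling <- function(total_dry_mass_20stems, stems_per_hectare,
                                   scale = 1e-6) {
  if (any(total_dry_mass_20stems < 0) || any(stems_per_hectare < 0) ||
      any(scale < 0)) {
    stop("plot_agb_from_sampling: inputs must be non-negative")
  }
  (total_dry_mass_20stems * stems_per_hectare * 15) / 20 * scale
}
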