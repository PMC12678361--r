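#' Daily growing degree days
#'
#' GDD for one day: mean of the daily temperature extremes above a base
#' temperature, floored at zero. Cumulative GDD is the caller's running sum.
#'
#' @param tmax,tmin Daily maximum and minimum air temperature, degC.
#'   Vectorized; recycled to common length.
#' @param tbase Base temperature, degC (default 0 for winter wheat).
#' @return Daily thermal time, degC d (non-negative).
#' @export
#' @examples
#' growing_degree_days(20, 10)      # 15
#' growing_degree_days(2, -6)       # 0
growing_degree_days <- function(tmax, tmin, tbase = crop_constants()$tbase) {
  stopifnot(is.numeric(tmax), is.numeric(tmin), is.numeric(tbase))
  if (any(tmax < tmin)) {
    stop("invalid weather: tmax < tmin on ", sum(tmax < tmin), " day(s)")
  }
  pmax(0, (tmax + tmin) / 2 - tbase)
}

#' Angstrom-Prescott solar radiation from sunshine duration
#'
#' Global solar radiation as a linear function of relative sunshine duration:
#' Rs = (a + b * s/S) * Ra, with the usual default coefficients a = 0.25,
#' b = 0.50.
#'
#' @param sunshine_hours Measured bright-sunshine duration s, h.
#' @param daylength Astronomical daylength S, h (> 0).
#' @param extraterrestrial_radiation Ra, MJ m-2 d-1.
#' @param a,b Angstrom coefficients.
#' @return Global solar radiation, MJ m-2 d-1.
#' @export
#' @examples
#' solar_radiation_angstrom(12, 12, 30)  # clear day: 0.75 * 30
#' solar_radiation_angstrom(0, 12, 30)   # overcast: 0.25 * 30
solar_radiation_angstrom <- function(sunshine_hours, daylength,
                                     extraterrestrial_radiation,
                                     a = 0.25, b = 0.50) {
  if (any(daylength <= 0)) stop("daylength must be positive")
  if (any(sunshine_hours < 0) || any(sunshine_hours > daylength + 1e-9)) {
    stop("sunshine_hours must lie in [0, daylength]")
  }
  (a + b * sunshine_hours / daylength) * extraterrestrial_radiation
}

# Solar declination (rad) for day-of-year, FAO-56 convention.
solar_declination <- function(doy) {
  0.409 * sin(2 * pi * doy / 365 - 1.39)
}

#' Astronomical daylength
#'
#' @param doy Day of year (1-366).
#' @param latitude Degrees north.
#' @return Daylength in hours.
#' @export
daylength_hours <- function(doy, latitude) {
  phi <- latitude * pi / 180
  delta <- solar_declination(doy)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  ws <- acos(x)
  24 / pi * ws
}

#' Extraterrestrial radiation
#'
#' Daily extraterrestrial (top-of-atmosphere) solar radiation after FAO-56.
#'
#' @inheritParams daylength_hours
#' @return Ra in MJ m-2 d-1.
#' @export
extraterrestrial_radiation <- function(doy, latitude) {
  gsc <- 0.0820 # MJ m-2 min-1
  phi <- latitude * pi / 180
  delta <- solar_declination(doy)
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  ws <- acos(x)
  24 * 60 / pi * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

# Hargreaves reference evapotranspiration, mm d-1.
et_hargreaves <- function(tmax, tmin, ra) {
  tmean <- (tmax + tmin) / 2
  pmax(0, 0.0023 * (ra / 2.45) * (tmean + 17.8) * sqrt(pmax(0, tmax - tmin)))
}

#' Validate and complete a daily weather table
#'
#' Checks the weather frame contract (one row per consecutive calendar day,
#' tmax >= tmin, precip >= 0) and fills the `srad` column from sunshine hours
#' via the Angstrom-Prescott formula when it is absent.
#'
#' @param weather Data frame with columns `date` (Date or ISO-8601 character),
#'   `tmax`, `tmin`, `precip`, and `srad` (MJ m-2 d-1) or `sunshine_hours`.
#' @param latitude Degrees north; needed only when radiation is derived from
#'   sunshine duration.
#' @return The weather frame with `date` as Date and a guaranteed `srad`
#'   column, ordered by date.
#' @export
validate_weather <- function(weather, latitude = 40.17) {
  stopifnot(is.data.frame(weather))
  need <- c("date", "tmax", "tmin", "precip")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather is missing column(s): ",
                         paste(miss, collapse = ", "))
  weather$date <- as.Date(weather$date)
  if (anyNA(weather$date)) stop("weather: unparseable date(s)")
  weather <- weather[order(weather$date), , drop = FALSE]
  d <- diff(as.integer(weather$date))
  if (any(d != 1)) {
    gaps <- weather$date[which(d != 1)]
    stop("weather has gaps or duplicate days after: ",
         paste(gaps, collapse = ", "))
  }
  if (any(weather$tmax < weather$tmin)) {
    stop("invalid weather: tmax < tmin on ",
         paste(weather$date[weather$tmax < weather$tmin], collapse = ", "))
  }
  if (any(weather$precip < 0)) stop("weather: negative precipitation")
  if (is.null(weather$srad)) {
    if (is.null(weather$sunshine_hours)) {
      stop("weather needs either 'srad' or 'sunshine_hours'")
    }
    doy <- as.integer(format(weather$date, "%j"))
    dl <- daylength_hours(doy, latitude)
    ra <- extraterrestrial_radiation(doy, latitude)
    s <- pmin(weather$sunshine_hours, dl)
    weather$srad <- solar_radiation_angstrom(s, dl, ra)
  }
  rownames(weather) <- NULL
  weather
}
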