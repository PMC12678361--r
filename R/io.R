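#' Read a daily weather CSV
#'
#' Expected columns: date (ISO-8601), tmax, tmin, precip, and sunshine_hours
#' or srad; one row per day with no gaps. Malformed rows are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @param latitude Site latitude for sunshine-to-radiation conversion.
#' @return Validated weather data frame (see [validate_weather()]).
#' @export
read_weather_csv <- function(path, latitude = 40.17) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax", "tmin", "precip")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop(path, ": missing column(s) ",
                         paste(miss, collapse = ", "))
  parsed <- as.Date(w$date, format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed)) + 1L # header line offset
    stop(path, ": unparseable ISO-8601 date at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  w$date <- parsed
  for (col in intersect(c("tmax", "tmin", "precip", "sunshine_hours", "srad"),
                        names(w))) {
    v <- suppressWarnings(as.numeric(w[[col]]))
    if (anyNA(v) && !anyNA(w[[col]])) {
      bad <- which(is.na(v) & !is.na(w[[col]])) + 1L
      stop(path, ": non-numeric '", col, "' at line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    w[[col]] <- v
  }
  validate_weather(w, latitude = latitude)
}

#' Write a weather frame to CSV (lossless round trip with
#' [read_weather_csv()])
#' @param weather Weather data frame.
#' @param path Output path.
#' @export
write_weather_csv <- function(weather, path) {
  w <- weather
  w$date <- format(as.Date(w$date), "%Y-%m-%d")
  utils::write.csv(w, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-plot spectral/AGB observations
#'
#' Columns: plot_id, date, nir, red, gdd, and optionally agb_measured.
#'
#' @param path CSV file path.
#' @return Data frame with parsed dates.
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "date", "nir", "red", "gdd")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(path, ": missing column(s) ",
                         paste(miss, collapse = ", "))
  parsed <- as.Date(x$date, format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed)) + 1L
    stop(path, ": unparseable ISO-8601 date at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  x$date <- parsed
  x
}

#' Read a management/soil configuration from JSON
#'
#' The JSON object may carry `soil` (fields of [soil_init()]), `management`
#' (sowing_date, plant_density, latitude, irrigation_events,
#' fertilization_events) and optional `cultivar` (fields of
#' [cultivar_params()]).
#'
#' @param path JSON file path.
#' @return List with `soil`, `mgmt`, `cultivar` objects.
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  soil <- if (!is.null(cfg$soil)) do.call(soil_init, as.list(cfg$soil))
          else soil_init()
  cultivar <- if (!is.null(cfg$cultivar)) {
    do.call(cultivar_params, as.list(cfg$cultivar))
  } else cultivar_params()
  m <- cfg$management
  if (is.null(m) || is.null(m$sowing_date)) {
    stop(path, ": config needs management.sowing_date")
  }
  mk_events <- function(e) {
    if (is.null(e) || NROW(e) == 0) return(NULL)
    as.data.frame(e, stringsAsFactors = FALSE)
  }
  mgmt <- management_plan(
    sowing_date = m$sowing_date,
    plant_density = if (!is.null(m$plant_density)) m$plant_density else 350,
    irrigation_events = mk_events(m$irrigation_events),
    fertilization_events = mk_events(m$fertilization_events),
    latitude = if (!is.null(m$latitude)) m$latitude else 40.17)
  list(soil = soil, mgmt = mgmt, cultivar = cultivar)
}

#' Read parameter specs from JSON
#'
#' Expects an array of objects with fields name, initial, lower, upper
#' (defaulting to [default_parameter_specs()] rows for omitted bounds).
#'
#' @param path JSON file path.
#' @return Parameter spec data frame.
#' @export
read_parameter_specs_json <- function(path) {
  if (!file.exists(path)) stop("parameter spec file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.character(x)) return(default_parameter_specs(free = x))
  defaults <- default_parameter_specs()
  sp <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(sp$name)) stop(path, ": specs need a 'name' field")
  for (col in c("initial", "lower", "upper")) {
    if (is.null(sp[[col]])) {
      sp[[col]] <- defaults[[col]][match(sp$name, defaults$name)]
    }
  }
  validate_specs(sp)
}

#' Read/write a numeric raster matrix as plain CSV
#'
#' Gridded mode without a geospatial dependency: a headerless CSV of numbers,
#' row-major with origin at the top-left; empty cells or "NA" are masked.
#'
#' @param path CSV path.
#' @param x Numeric matrix (for the writer).
#' @return `read_raster_csv` returns a numeric matrix (NA = masked).
#' @export
read_raster_csv <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' @rdname read_raster_csv
#' @export
write_raster_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Gridded AGB and N-rate maps
#'
#' Maps aligned NIR/red rasters to an AGB raster through EVI2 and the HLM,
#' and an AGB raster to an N-rate raster through the reference curve. Masked
#' (NA) cells propagate.
#'
#' @param nir,red Aligned numeric matrices of reflectance.
#' @param gdd Thermal-time covariate (scalar or matrix) on the HLM scale.
#' @param coeffs [hlm_coefficients()]; predictions are clamped at zero for
#'   map production.
#' @param agb AGB raster, t ha-1 (for `n_rate_raster`).
#' @param curve A [power_law_curve()].
#' @return A numeric matrix the shape of the inputs.
#' @export
agb_raster <- function(nir, red, gdd, coeffs = hlm_published()) {
  stopifnot(is.matrix(nir), is.matrix(red), all(dim(nir) == dim(red)))
  mask <- is.na(nir) | is.na(red)
  v <- matrix(NA_real_, nrow(nir), ncol(nir))
  v[!mask] <- evi2(nir[!mask], red[!mask])
  g <- if (length(gdd) == 1) gdd else {
    stopifnot(all(dim(gdd) == dim(nir))); gdd[!mask]
  }
  out <- matrix(NA_real_, nrow(nir), ncol(nir))
  out[!mask] <- hlm_predict(v[!mask], g, coeffs, clamp = TRUE)
  out
}

#' @rdname agb_raster
#' @export
n_rate_raster <- function(agb, curve = reference_curve_published()) {
  stopifnot(is.matrix(agb))
  ok <- !is.na(agb) & agb > 0
  out <- matrix(NA_real_, nrow(agb), ncol(agb))
  out[ok] <- reference_curve_predict(agb[ok], curve)
  out
}

# Polynomial rolling hash of a deparsed object, for provenance stamps in
# reports (stability across runs matters; cryptographic strength does not).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
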