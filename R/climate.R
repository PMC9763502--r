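#' Daylength at a latitude and day of year
#'
#' Hours between geometric sunrise and sunset from standard
#' solar-declination / hour-angle astronomy: the solar declination is
#' `delta = 23.44 deg * sin(orbital angle)` and the half-day hour angle
#' satisfies `cos(H) = -tan(lat) * tan(delta)`, clamped so that polar day
#' and polar night return exactly 24 and 0 h. No atmospheric refraction is
#' applied (sun-centre definition). DOY 366 is treated as DOY 365.
#'
#' @param latitude latitude in decimal degrees, in `[-90, 90]`.
#' @param doy integer day of year (1-based); vectorized.
#' @return Daylength in hours, same length as `doy`.
#' @examples
#' daylength_hours(68.26, 172)  # polar day
#' daylength_hours(64.35, 80)   # ~equinox
#' @export
daylength_hours <- function(latitude, doy) {
  if (any(latitude < -90 | latitude > 90)) {
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  }
  doy <- pmin(as.numeric(doy), 365)
  decl <- 23.44 * pi / 180 * sin(2 * pi * (doy + 284) / 365)
  cosH <- -tan(latitude * pi / 180) * tan(decl)
  cosH <- pmin(pmax(cosH, -1), 1)
  24 * acos(cosH) / pi
}

new_climate <- function(year, doy, t_mean, daylength) {
  structure(
    data.frame(year = as.integer(year), doy = as.integer(doy),
               t_mean = as.numeric(t_mean), daylength = as.numeric(daylength)),
    class = c("xylo_climate", "data.frame")
  )
}

#' Read a daily temperature forcing file
#'
#' Reads a CSV with columns `date` (ISO-8601) and `t_mean_C` (daily mean air
#' temperature, degC), checks that the dates form a contiguous daily series,
#' and attaches the daylength computed from `latitude`.
#'
#' @param path path to the CSV file.
#' @param latitude site latitude in decimal degrees.
#' @return A `xylo_climate` data frame with columns
#'   `year`, `doy`, `t_mean`, `daylength`.
#' @export
read_forcing <- function(path, latitude) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "t_mean_C")
  if (!all(need %in% names(df))) {
    stop("forcing CSV must have columns 'date' and 't_mean_C'", call. = FALSE)
  }
  dates <- as.Date(df$date)
  if (anyNA(dates)) {
    stop("unparseable date(s) in forcing file, first: ",
         df$date[which(is.na(dates))[1]], call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(df$t_mean_C))
  if (anyNA(tm)) {
    stop("non-numeric temperature at date ",
         format(dates[which(is.na(tm))[1]]), call. = FALSE)
  }
  o <- order(dates)
  dates <- dates[o]
  tm <- tm[o]
  gaps <- which(diff(as.integer(dates)) != 1L)
  if (length(gaps)) {
    stop("forcing series has gap(s) after: ",
         paste(format(dates[gaps]), collapse = ", "), call. = FALSE)
  }
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  new_climate(yr, doy, tm, daylength_hours(latitude, doy))
}

#' Synthetic boreal daily temperature series
#'
#' Generates a reproducible daily mean temperature series emulating boreal
#' seasonality: a seasonal cosine plus AR(1) daily noise,
#' `t(d) = mean_C + amplitude_K * cos(2*pi*(doy - peak_doy)/365.25) + AR(1)`.
#' Defaults emulate the boreal Sweden study region (annual mean ~1 degC,
#' seasonal amplitude 14 K, warmest around DOY 200). Years have 365 days.
#' The generator uses its own RNG stream derived from `seed` and leaves the
#' global RNG state untouched.
#'
#' @param latitude site latitude in decimal degrees (used for daylength).
#' @param years integer vector of calendar years to generate.
#' @param seed integer seed; identical seeds give bit-identical series.
#' @param mean_C annual mean temperature, degC.
#' @param amplitude_K seasonal half-amplitude, K (>= 0).
#' @param ar1_phi AR(1) coefficient of the daily noise, in `[0, 1)`.
#' @param noise_sd_K SD of the AR(1) innovations, K.
#' @param peak_doy DOY of the seasonal maximum.
#' @return A `xylo_climate` data frame (see [read_forcing()]).
#' @examples
#' cl <- synthesize_climate(64.35, 1995, seed = 1)
#' range(cl$t_mean)
#' @export
synthesize_climate <- function(latitude = 64.35, years = 1995, seed = 1,
                               mean_C = 1, amplitude_K = 14, ar1_phi = 0.7,
                               noise_sd_K = 3, peak_doy = 200) {
  if (amplitude_K < 0) stop("amplitude_K must be >= 0", call. = FALSE)
  if (ar1_phi < 0 || ar1_phi >= 1) {
    stop("ar1_phi must lie in [0, 1)", call. = FALSE)
  }
  years <- sort(as.integer(years))
  n_days <- 365L * length(years)
  doy <- rep(1:365, times = length(years))
  yr <- rep(years, each = 365L)

  noise <- local_rng(seed, {
    eps <- stats::rnorm(n_days, 0, noise_sd_K)
    x <- numeric(n_days)
    # start from the stationary distribution so series do not warm up
    x[1] <- if (noise_sd_K > 0) {
      stats::rnorm(1, 0, noise_sd_K / sqrt(1 - ar1_phi^2))
    } else 0
    if (n_days > 1) {
      for (d in 2:n_days) x[d] <- ar1_phi * x[d - 1] + eps[d]
    }
    x
  })
  seasonal <- mean_C + amplitude_K * cos(2 * pi * (doy - peak_doy) / 365.25)
  new_climate(yr, doy, seasonal + noise, daylength_hours(latitude, doy))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Write a climate series to CSV
#'
#' Writes the `date,t_mean_C` dialect read by [read_forcing()]. Synthetic
#' 365-day years are written against a non-leap calendar template.
#'
#' @param climate a `xylo_climate` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forcing <- function(climate, path) {
  dates <- as.Date(paste0(climate$year, "-01-01")) + (climate$doy - 1L)
  utils::write.csv(
    data.frame(date = format(dates, "%Y-%m-%d"), t_mean_C = climate$t_mean),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
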