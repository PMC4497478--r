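## Meteorological forcing: synthetic daily weather in the style of an
## interpolated station product (daily rain, global solar exposure, Tmax/Tmin,
## vapour pressure) and disaggregation of daily values to the hourly
## resolution the simulator consumes.

PPFD_PER_J <- 4.57e-6   # mol quanta per J of global irradiance
P_ATM_KPA <- 101.325
DAYS_PER_YEAR <- 365L   # no leap days anywhere in this package

#' Synthetic climate specification
#'
#' Describes the statistical climate of a synthetic site: a seasonal
#' first-order (wet/dry) rainfall occurrence chain with exponential wet-day
#' depths, clear-sky-scaled irradiance, a seasonal temperature cycle and a
#' constant mean relative humidity.
#'
#' @param mean_annual_rain_mm target long-run mean annual rainfall (mm).
#' @param wet_season_center day-of-year at which wet-day probability peaks.
#' @param rain_seasonality concentration of rainfall seasonality in `[0, 1]`;
#'   0 gives uniform wet-day probability over the year.
#' @param wet_day_prob mean (deseasonalised) probability that a day is wet.
#' @param mean_wet_day_depth_mm mean depth of a wet day (mm). If `NULL`
#'   (default) it is derived so the expected annual total equals
#'   `mean_annual_rain_mm`.
#' @param latitude_deg site latitude (degrees, negative south).
#' @param temperature_mean,temperature_amplitude annual mean and seasonal
#'   half-amplitude of daily mean air temperature (degC).
#' @param diurnal_range_mean mean diurnal temperature range Tmax - Tmin (degC).
#' @param irradiance_clear_sky_fraction_range length-2 range of the clear-sky
#'   fraction used to scale extraterrestrial irradiance.
#' @param relative_humidity_mean mean relative humidity in `[0, 1]` used to
#'   set daily vapour pressure.
#' @param rain_persistence lag-1 persistence of the wet/dry occurrence chain.
#' @param rng_seed integer seed; identical spec + seed gives identical series.
#' @return an object of class `climate_spec`.
#' @export
climate_spec <- function(mean_annual_rain_mm = 800,
                         wet_season_center = 15,
                         rain_seasonality = 0.8,
                         wet_day_prob = 0.25,
                         mean_wet_day_depth_mm = NULL,
                         latitude_deg = -20,
                         temperature_mean = 25,
                         temperature_amplitude = 5,
                         diurnal_range_mean = 10,
                         irradiance_clear_sky_fraction_range = c(0.35, 0.95),
                         relative_humidity_mean = 0.6,
                         rain_persistence = 0.5,
                         rng_seed = 1L) {
  spec <- list(mean_annual_rain_mm = mean_annual_rain_mm,
               wet_season_center = wet_season_center,
               rain_seasonality = rain_seasonality,
               wet_day_prob = wet_day_prob,
               mean_wet_day_depth_mm = mean_wet_day_depth_mm,
               latitude_deg = latitude_deg,
               temperature_mean = temperature_mean,
               temperature_amplitude = temperature_amplitude,
               diurnal_range_mean = diurnal_range_mean,
               irradiance_clear_sky_fraction_range = irradiance_clear_sky_fraction_range,
               relative_humidity_mean = relative_humidity_mean,
               rain_persistence = rain_persistence,
               rng_seed = rng_seed)
  if (!is.numeric(mean_annual_rain_mm) || mean_annual_rain_mm <= 0)
    stop("configuration error: mean_annual_rain_mm must be > 0")
  for (p in c("wet_day_prob", "rain_seasonality", "relative_humidity_mean",
              "rain_persistence")) {
    v <- spec[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("configuration error: ", p, " must lie in [0, 1]")
  }
  r <- spec$irradiance_clear_sky_fraction_range
  if (length(r) != 2 || any(r <= 0) || any(r > 1) || r[1] > r[2])
    stop("configuration error: irradiance_clear_sky_fraction_range invalid")
  if (abs(latitude_deg) > 66)
    stop("configuration error: polar latitudes are not supported")
  structure(spec, class = "climate_spec")
}

#' Saturation vapour pressure (Magnus form)
#'
#' @param temp_c air temperature (degC)
#' @return saturation vapour pressure (kPa)
#' @export
esat_kpa <- function(temp_c) 0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))

# daily extraterrestrial solar exposure (MJ m-2 d-1), 365-day year
extraterrestrial_mj <- function(doy, latitude_deg) {
  lat <- latitude_deg * pi / 180
  dec <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  x <- pmin(1, pmax(-1, -tan(lat) * tan(dec)))
  ws <- acos(x)
  37.586 * dr * (ws * sin(lat) * sin(dec) + cos(lat) * cos(dec) * sin(ws))
}

#' Generate synthetic daily weather
#'
#' Draws `n_years` of daily weather (365-day years) from a [climate_spec()].
#' Rainfall occurrence follows a two-state first-order chain whose wet
#' probability varies seasonally; wet-day depths are exponential. Irradiance
#' is extraterrestrial radiation scaled by a stochastic clear-sky fraction
#' (lower on wet days); temperature follows a seasonal cycle with AR(1)
#' day-to-day noise; vapour pressure is relative humidity times saturation
#' vapour pressure at the daily mean temperature.
#'
#' @param spec a [climate_spec()].
#' @param n_years number of years (>= 1).
#' @return data.frame with columns `date`, `doy`, `rain_mm`, `I_g_daily`
#'   (MJ m-2 d-1), `T_max`, `T_min` (degC) and `e_a` (kPa).
#' @export
generate_synthetic_daily <- function(spec, n_years) {
  if (!inherits(spec, "climate_spec")) spec <- do.call(climate_spec, spec)
  if (!is.numeric(n_years) || n_years < 1)
    stop("configuration error: n_years must be >= 1")
  n_years <- as.integer(n_years)
  nd <- n_years * DAYS_PER_YEAR
  doy <- rep(seq_len(DAYS_PER_YEAR), n_years)

  with_seed(spec$rng_seed, {
    seas <- 1 + spec$rain_seasonality *
      cos(2 * pi * (doy - spec$wet_season_center) / 365)
    p_wet <- pmin(1, pmax(0, spec$wet_day_prob * seas))
    rho <- spec$rain_persistence
    # transition probabilities preserving the marginal wet probability
    p01 <- (1 - rho) * p_wet          # dry -> wet
    p11 <- rho + (1 - rho) * p_wet    # wet -> wet
    uu <- runif(nd)
    wet <- logical(nd)
    state <- FALSE
    for (d in seq_len(nd)) {
      state <- if (state) uu[d] < p11[d] else uu[d] < p01[d]
      wet[d] <- state
    }
    depth_mean <- spec$mean_wet_day_depth_mm
    if (is.null(depth_mean)) {
      if (spec$wet_day_prob > 0)
        depth_mean <- spec$mean_annual_rain_mm / (DAYS_PER_YEAR * spec$wet_day_prob)
      else depth_mean <- 0
    }
    rain <- numeric(nd)
    if (any(wet) && depth_mean > 0)
      rain[wet] <- rexp(sum(wet), rate = 1 / depth_mean)

    ra <- extraterrestrial_mj(doy, spec$latitude_deg)
    rng <- spec$irradiance_clear_sky_fraction_range
    csf <- runif(nd, rng[1], rng[2])
    csf[wet] <- pmax(0.05, csf[wet] - 0.3 * (rng[2] - rng[1]))
    ig <- ra * 0.75 * csf

    peak_doy <- if (spec$latitude_deg < 0) 15 else 196
    tm_seas <- spec$temperature_mean + spec$temperature_amplitude *
      cos(2 * pi * (doy - peak_doy) / 365)
    eps <- numeric(nd)
    innov <- rnorm(nd, sd = 1.2)
    for (d in seq_len(nd)) eps[d] <- 0.6 * (if (d > 1) eps[d - 1] else 0) + innov[d]
    tmean <- tm_seas + eps
    drange <- pmax(2, spec$diurnal_range_mean - 4 * wet +
                     rnorm(nd, sd = 1))
    tmax <- tmean + drange / 2
    tmin <- tmean - drange / 2
    ea <- pmin(spec$relative_humidity_mean *
                 exp(rnorm(nd, sd = 0.08)) * esat_kpa(tmean),
               esat_kpa(tmean))
    ea <- pmax(ea, 0.05)

    data.frame(date = as.Date("2000-01-01") + seq_len(nd) - 1,
               doy = doy, rain_mm = rain, I_g_daily = ig,
               T_max = tmax, T_min = tmin, e_a = ea)
  })
}

#' Convert global irradiance to photosynthetically active photon flux
#'
#' Uses the fixed conversion coefficient 4.57e-6 mol quanta per joule of
#' global irradiance.
#'
#' @param i_g global irradiance (W m-2), non-negative.
#' @return PPFD (mol quanta m-2 s-1)
#' @export
ppfd_from_irradiance <- function(i_g) {
  if (any(i_g < 0)) stop("domain error: irradiance must be non-negative")
  PPFD_PER_J * i_g
}

# normalized intra-day irradiance weights (half-sine via solar elevation)
# at hour centres; returns list(w = weights summing to 1, sunrise = hour)
solar_weights <- function(doy, latitude_deg) {
  lat <- latitude_deg * pi / 180
  dec <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  tc <- seq(0.5, 23.5, by = 1)
  hang <- pi * (tc - 12) / 12
  sinb <- sin(lat) * sin(dec) + cos(lat) * cos(dec) * cos(hang)
  w <- pmax(0, sinb)
  if (sum(w) <= 0) w <- rep(1, 24)  # degenerate (polar); spread uniformly
  x <- pmin(1, pmax(-1, -tan(lat) * tan(dec)))
  sunrise <- 12 - acos(x) * 12 / pi
  list(w = w / sum(w), sunrise = sunrise)
}

# diurnal temperature shape: minimum at dawn, maximum ~2 h after solar noon;
# anchors are snapped to the hour-centre grid so the series attains T_min and
# T_max exactly
diurnal_temperature <- function(t_max_c, t_min_c, sunrise) {
  tc <- seq(0.5, 23.5, by = 1)
  t_pk <- 13.5
  sunrise <- pmin(floor(sunrise) + 0.5, t_pk - 1)
  rise <- tc >= sunrise & tc <= t_pk
  out <- numeric(24)
  out[rise] <- t_min_c + (t_max_c - t_min_c) *
    (1 - cos(pi * (tc[rise] - sunrise) / (t_pk - sunrise))) / 2
  fall_len <- 24 - (t_pk - sunrise)
  u <- (tc[!rise] - t_pk) %% 24
  out[!rise] <- t_max_c - (t_max_c - t_min_c) * (1 - cos(pi * u / fall_len)) / 2
  out
}

#' Disaggregate one day of weather to 24 hourly forcing records
#'
#' Rain is spread evenly over 24 h; irradiance follows a half-sine over the
#' daylight period (energy conserving); temperature runs from `T_min` at dawn
#' to `T_max` two hours after solar noon; vapour pressure is held constant
#' over the day and the vapour mole fraction deficit is computed hourly.
#'
#' @param day one-row data.frame as produced by [generate_synthetic_daily()]
#'   (fields `doy`, `rain_mm`, `I_g_daily`, `T_max`, `T_min`, `e_a`).
#' @param latitude_deg site latitude (degrees).
#' @param c_a atmospheric CO2 mole fraction (ppm).
#' @return 24-row data.frame with columns `hour`, `I_a` (mol quanta m-2 s-1),
#'   `I_g` (W m-2), `T_a` (degC), `D_v` (mol mol-1), `rain` (mm h-1), `C_a`.
#' @export
disaggregate_to_hourly <- function(day, latitude_deg, c_a = 380) {
  stopifnot(nrow(day) == 1)
  if (day$T_max < day$T_min) stop("invalid day: T_max < T_min")
  if (day$rain_mm < 0 || day$I_g_daily < 0 || day$e_a < 0)
    stop("invalid day: negative rain, irradiance or vapour pressure")
  sw <- solar_weights(day$doy, latitude_deg)
  ig_wm2 <- day$I_g_daily * 1e6 * sw$w / 3600   # W m-2 at hour centres
  ta <- diurnal_temperature(day$T_max, day$T_min, sw$sunrise)
  dv <- pmax(0, esat_kpa(ta) - day$e_a) / P_ATM_KPA
  data.frame(hour = 0:23,
             I_a = ppfd_from_irradiance(ig_wm2),
             I_g = ig_wm2,
             T_a = ta,
             D_v = dv,
             rain = day$rain_mm / 24,
             C_a = c_a)
}

#' Build an hourly forcing table for a daily series
#'
#' Vectorised application of [disaggregate_to_hourly()] over a daily weather
#' data.frame.
#'
#' @param daily data.frame from [generate_synthetic_daily()] or
#'   [read_daily_weather()].
#' @inheritParams disaggregate_to_hourly
#' @return data.frame with `24 * nrow(daily)` rows and the hourly columns.
#' @export
make_hourly_forcing <- function(daily, latitude_deg, c_a = 380) {
  nd <- nrow(daily)
  lat <- latitude_deg * pi / 180
  doy <- daily$doy
  dec <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  tc <- seq(0.5, 23.5, by = 1)
  # 24 x nd matrices
  hang <- matrix(pi * (tc - 12) / 12, 24, nd)
  sinb <- sin(lat) * matrix(sin(dec), 24, nd, byrow = TRUE) +
    cos(lat) * matrix(cos(dec), 24, nd, byrow = TRUE) * cos(hang)
  w <- sinb; w[w < 0] <- 0
  cs <- colSums(w)
  bad <- cs <= 0
  if (any(bad)) { w[, bad] <- 1; cs[bad] <- 24 }
  w <- sweep(w, 2, cs, "/")
  ig <- sweep(w, 2, daily$I_g_daily * 1e6 / 3600, "*")

  x <- pmin(1, pmax(-1, -tan(lat) * tan(dec)))
  sunrise <- 12 - acos(x) * 12 / pi
  t_pk <- 13.5
  sunrise <- pmin(floor(sunrise) + 0.5, t_pk - 1)
  tcm <- matrix(tc, 24, nd)
  srm <- matrix(sunrise, 24, nd, byrow = TRUE)
  tmaxm <- matrix(daily$T_max, 24, nd, byrow = TRUE)
  tminm <- matrix(daily$T_min, 24, nd, byrow = TRUE)
  rise <- tcm >= srm & tcm <= t_pk
  ta <- matrix(0, 24, nd)
  ta[rise] <- tminm[rise] + (tmaxm[rise] - tminm[rise]) *
    (1 - cos(pi * (tcm[rise] - srm[rise]) / (t_pk - srm[rise]))) / 2
  fall_len <- 24 - (t_pk - srm)
  u <- (tcm - t_pk) %% 24
  ta[!rise] <- tmaxm[!rise] - (tmaxm[!rise] - tminm[!rise]) *
    (1 - cos(pi * u[!rise] / fall_len[!rise])) / 2

  eam <- matrix(daily$e_a, 24, nd, byrow = TRUE)
  dv <- pmax(0, esat_kpa(ta) - eam) / P_ATM_KPA
  data.frame(day = rep(seq_len(nd), each = 24),
             hour = rep(0:23, nd),
             I_a = PPFD_PER_J * as.vector(ig),
             I_g = as.vector(ig),
             T_a = as.vector(ta),
             D_v = as.vector(dv),
             rain = rep(daily$rain_mm / 24, each = 24),
             C_a = c_a)
}

#' Read a daily weather file
#'
#' Reads a headered CSV with ISO dates and the daily weather columns
#' (`date`, `rain_mm`, `I_g_daily`, `T_max`, `T_min`, `e_a`). Missing days in
#' the date sequence are reported in the `gaps` attribute.
#'
#' @param path file path.
#' @return data.frame of daily weather with a `gaps` attribute (Date vector
#'   of missing days, possibly empty).
#' @export
read_daily_weather <- function(path) {
  x <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("format error: ", conditionMessage(e)))
  if (nrow(x) == 0) stop("format error: empty weather file")
  need <- c("date", "rain_mm", "I_g_daily", "T_max", "T_min", "e_a")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("format error: missing columns: ", paste(miss, collapse = ", "))
  dates <- as.Date(x$date)
  if (anyNA(dates)) stop("format error: unparseable dates")
  x$date <- dates
  full <- seq(min(dates), max(dates), by = "day")
  gaps <- full[!full %in% dates]
  if (length(gaps))
    message("weather file has ", length(gaps), " missing day(s): ",
            paste(format(gaps), collapse = ", "))
  if (!"doy" %in% names(x))
    x$doy <- ((as.integer(format(x$date, "%j")) - 1L) %% 365L) + 1L
  ok <- x$rain_mm >= 0 & x$I_g_daily >= 0 & x$T_max >= x$T_min & x$e_a >= 0
  if (!all(ok)) stop("format error: invariant violation in rows ",
                     paste(which(!ok), collapse = ", "))
  attr(x, "gaps") <- gaps
  x
}

#' Write a daily weather file
#'
#' @param daily data.frame of daily weather.
#' @param path output CSV path.
#' @export
write_daily_weather <- function(daily, path) {
  write.csv(daily, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
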