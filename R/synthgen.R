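#' Synthetic weather configuration
#'
#' Parameters of the synthetic "truth" weather generator. The defaults
#' emulate a mid-summer arid-subtropical regime (Mesa, Arizona-like): mostly
#' clear skies with day-coherent cloudy spells, a strong diurnal temperature
#' cycle riding on slowly varying synoptic anomalies, a large and persistent
#' dew-point deficit, and light winds.
#'
#' Cloudiness is built from a latent hourly AR(1) Gaussian process mapped
#' through `pnorm(.)^cloud_shape`, giving a [0, 1] cloud fraction skewed
#' toward clear conditions; surface shortwave is clear-sky irradiance times
#' `1 - cloud_strength * cloudiness`. Air temperature is
#' `temp_mean + temp_diurnal_amplitude * sin(...)` (peaking at 15:00 local)
#' plus an AR(1) synoptic anomaly. Dew point is air temperature minus a
#' positive AR(1) deficit, so the dewpoint invariant holds by construction.
#'
#' @param latitude Degrees north, in [-90, 90].
#' @param start_date Date (or string) of the first generated day.
#' @param n_days Number of days to generate (hourly resolution).
#' @param utc_offset Fixed local-time offset from UTC in hours (solar
#'   geometry and the diurnal cycle are computed in local time; timestamps
#'   are UTC).
#' @param cloud_persistence Hourly AR(1) coefficient of the latent
#'   cloudiness process, in [0, 1).
#' @param cloud_strength Maximum fractional shortwave reduction by cloud, in
#'   [0, 1].
#' @param cloud_shape Exponent skewing cloudiness toward clear skies
#'   (larger = clearer climate).
#' @param temp_mean Daily-mean air temperature, degC.
#' @param temp_diurnal_amplitude Amplitude of the diurnal temperature
#'   sinusoid, degC.
#' @param temp_synoptic_sd Marginal sd of the AR(1) synoptic temperature
#'   anomaly, degC.
#' @param temp_persistence Hourly AR(1) coefficient of the synoptic anomaly.
#' @param dewpoint_deficit Mean dew-point depression below air temperature,
#'   degC.
#' @param dewpoint_deficit_sd Marginal sd of the AR(1) deficit anomaly, degC.
#' @param wind_mean Mean wind speed, m s-1.
#' @param wind_sd Marginal sd of the AR(1) wind anomaly, m s-1.
#' @param pressure Air pressure, kPa (constant).
#' @param transmittance Clear-sky broadband atmospheric transmittance.
#' @param seed Integer seed; the generated series is a pure function of the
#'   configuration.
#' @return A `weather_config` list.
#' @export
weather_config <- function(latitude = 33.4,
                           start_date = "2013-06-01",
                           n_days = 92,
                           utc_offset = -7,
                           cloud_persistence = 0.97,
                           cloud_strength = 0.5,
                           cloud_shape = 3,
                           temp_mean = 31,
                           temp_diurnal_amplitude = 8,
                           temp_synoptic_sd = 2,
                           temp_persistence = 0.98,
                           dewpoint_deficit = 15,
                           dewpoint_deficit_sd = 3,
                           wind_mean = 3,
                           wind_sd = 1,
                           pressure = 97,
                           transmittance = 0.75,
                           seed = 1) {
  check_number(latitude, "latitude", -90, 90)
  check_number(n_days, "n_days", 1)
  check_number(cloud_persistence, "cloud_persistence", 0, 1 - 1e-9)
  check_number(cloud_strength, "cloud_strength", 0, 1)
  check_number(temp_diurnal_amplitude, "temp_diurnal_amplitude", 0)
  check_number(temp_synoptic_sd, "temp_synoptic_sd", 0)
  check_number(wind_mean, "wind_mean", 0)
  structure(list(
    latitude = latitude, start_date = as.Date(start_date), n_days = n_days,
    utc_offset = utc_offset, cloud_persistence = cloud_persistence,
    cloud_strength = cloud_strength, cloud_shape = cloud_shape,
    temp_mean = temp_mean, temp_diurnal_amplitude = temp_diurnal_amplitude,
    temp_synoptic_sd = temp_synoptic_sd, temp_persistence = temp_persistence,
    dewpoint_deficit = dewpoint_deficit,
    dewpoint_deficit_sd = dewpoint_deficit_sd,
    wind_mean = wind_mean, wind_sd = wind_sd, pressure = pressure,
    transmittance = transmittance, seed = as.integer(seed)
  ), class = "weather_config")
}

# clear-sky broadband shortwave from solar geometry, W m-2
clearsky_shortwave <- function(day_of_year, hour, latitude, transmittance = 0.75) {
  if (any(latitude < -90 | latitude > 90)) {
    stop_pondcast("`latitude` must be within [-90, 90]", class = "domain")
  }
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- latitude * pi / 180
  hang <- pi * (hour - 12) / 12
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hang)
  cosz <- pmax(cosz, 0)
  # transmittance along the slant path; zero when the sun is down
  ifelse(cosz > 0,
         .const$solar * cosz * transmittance^(1 / pmax(cosz, 1e-3)),
         0)
}

#' Deterministic clear-sky PAR from solar geometry
#'
#' Top-of-atmosphere irradiance scaled by the solar zenith cosine and an
#' atmospheric transmittance along the slant path, converted to PAR with
#' [shortwave_to_par()]. Zero when the sun is below the horizon; symmetric
#' about solar noon (`hour` is local solar time).
#'
#' @param day_of_year Day of year, 1-366 (vectorised).
#' @param hour Local solar hour, 0-23 (fractional allowed, vectorised).
#' @param latitude Degrees north, in [-90, 90].
#' @param transmittance Broadband clear-sky transmittance.
#' @return Clear-sky PAR, umol m-2 s-1.
#' @examples
#' clearsky_par(172, 12, 33.4)  # mid-summer noon at Mesa-like latitude
#' clearsky_par(172, 0, 33.4)   # 0 at night
#' @export
clearsky_par <- function(day_of_year, hour, latitude, transmittance = 0.75) {
  if (any(day_of_year < 1 | day_of_year > 366)) {
    stop_pondcast("`day_of_year` must be in [1, 366]", class = "domain")
  }
  shortwave_to_par(clearsky_shortwave(day_of_year, hour, latitude, transmittance))
}

#' Generate a synthetic "truth" weather series
#'
#' Draws an hourly meteorological series from the stochastic weather model
#' described in [weather_config()]. The series is reproducible: the same
#' configuration (including `seed`) always yields the identical series, and
#' the caller's RNG stream is left untouched.
#'
#' @param cfg A [weather_config()].
#' @return A validated meteorological tibble of `24 * n_days` hourly rows
#'   starting at local midnight of `start_date` (timestamps in UTC).
#' @examples
#' met <- generate_truth_weather(weather_config(n_days = 3, seed = 42))
#' range(met$par)
#' @export
generate_truth_weather <- function(cfg) {
  stopifnot(inherits(cfg, "weather_config"))
  n <- as.integer(cfg$n_days * 24)
  # local wall-clock hours; timestamps stored in UTC
  t_local0 <- lubridate::as_datetime(cfg$start_date, tz = "UTC")
  time_utc <- t_local0 + (seq_len(n) - 1L) * 3600 - cfg$utc_offset * 3600
  hour_local <- (seq_len(n) - 1L) %% 24
  doy <- lubridate::yday(cfg$start_date + ((seq_len(n) - 1L) %/% 24))

  with_seed(cfg$seed, {
    z_cloud <- ar1_series(n, cfg$cloud_persistence, 1)
    cloudiness <- stats::pnorm(z_cloud)^cfg$cloud_shape
    sw_clear <- clearsky_shortwave(doy, hour_local, cfg$latitude, cfg$transmittance)
    shortwave <- sw_clear * (1 - cfg$cloud_strength * cloudiness)

    synoptic <- ar1_series(n, cfg$temp_persistence, cfg$temp_synoptic_sd)
    # cloudy days are cooler: couple the synoptic anomaly to cloudiness
    air_temp <- cfg$temp_mean +
      cfg$temp_diurnal_amplitude * sin(2 * pi * (hour_local - 9) / 24) +
      synoptic - 3 * (cloudiness - mean(cloudiness))

    deficit <- pmax(0.5, cfg$dewpoint_deficit +
                      ar1_series(n, 0.95, cfg$dewpoint_deficit_sd))
    wind <- pmax(0.2, cfg$wind_mean + ar1_series(n, 0.9, cfg$wind_sd))

    tibble(
      time = time_utc,
      shortwave = shortwave,
      par = shortwave_to_par(shortwave),
      air_temp = air_temp,
      dewpoint = air_temp - deficit,
      wind = wind,
      pressure = rep(cfg$pressure, n)
    )
  })
}

#' Forecast-error configuration for synthetic ensembles
#'
#' Describes how synthetic ensemble members are derived from truth weather:
#' member = truth + systematic bias + a member-specific AR(1) perturbation.
#' Shortwave (and hence PAR) is treated multiplicatively — bias
#' `shortwave_mult` and relative spread `shortwave_rel` — so that nights stay
#' dark; air temperature, dew point and wind are additive. Physical bounds
#' are re-imposed after perturbation (non-negative radiation and wind,
#' dewpoint <= air temperature).
#'
#' The default mild positive shortwave/temperature bias and spread are
#' invented calibration values standing in for typical short-range NWP
#' ensemble error; no quantitative error statistics are published for the
#' regime being emulated.
#'
#' @param n_members Ensemble size E (>= 1); 11 matches an operational
#'   global ensemble reforecast.
#' @param bias Named list: `shortwave_mult` (multiplicative), `air_temp`,
#'   `dewpoint`, `wind` (additive, degC / degC / m s-1).
#' @param spread_sd Named list of member-perturbation scales:
#'   `shortwave_rel` (relative), `air_temp`, `dewpoint`, `wind` (additive).
#' @param error_persistence Hourly AR(1) coefficient of member
#'   perturbations; high values make whole days coherently wrong, the
#'   signature of synoptic-scale forecast busts.
#' @param seed Integer seed; member m uses a seed derived deterministically
#'   from `(seed, m)` so single members are reproducible in isolation.
#' @return A `forecast_error_config` list.
#' @export
forecast_error_config <- function(n_members = 11,
                                  bias = list(shortwave_mult = 1.03,
                                              air_temp = 0.5,
                                              dewpoint = 0,
                                              wind = 0),
                                  spread_sd = list(shortwave_rel = 0.12,
                                                   air_temp = 1.2,
                                                   dewpoint = 1.0,
                                                   wind = 0.6),
                                  error_persistence = 0.9,
                                  seed = 1) {
  check_number(n_members, "n_members", 1)
  check_number(error_persistence, "error_persistence", 0, 1 - 1e-9)
  defaults_bias <- list(shortwave_mult = 1, air_temp = 0, dewpoint = 0, wind = 0)
  defaults_sd <- list(shortwave_rel = 0, air_temp = 0, dewpoint = 0, wind = 0)
  bias <- utils::modifyList(defaults_bias, bias)
  spread_sd <- utils::modifyList(defaults_sd, spread_sd)
  if (any(unlist(spread_sd) < 0)) {
    stop_pondcast("`spread_sd` entries must be >= 0", class = "domain")
  }
  structure(list(n_members = as.integer(n_members), bias = bias,
                 spread_sd = spread_sd, error_persistence = error_persistence,
                 seed = as.integer(seed)),
            class = "forecast_error_config")
}

#' Generate a synthetic ensemble forecast from truth weather
#'
#' Slices the truth series over `[issue_time, issue_time + horizon_hours)`
#' and perturbs it per member as described in [forecast_error_config()]. A
#' zero-bias, zero-spread configuration reproduces the truth slice exactly
#' in every member, which makes a degenerate ensemble interchangeable with a
#' perfect forecast.
#'
#' @param truth A meteorological tibble covering the requested window.
#' @param issue_time POSIXct issue instant (must be a truth timestamp).
#' @param horizon_hours Forecast horizon, hours.
#' @param err A [forecast_error_config()].
#' @return An [ensemble_forecast()] with E members.
#' @examples
#' truth <- generate_truth_weather(weather_config(n_days = 2, seed = 1))
#' fc <- generate_ensemble_forecast(truth, truth$time[1], 24,
#'                                  forecast_error_config(n_members = 11))
#' n_members(fc)  # 11
#' @export
generate_ensemble_forecast <- function(truth, issue_time, horizon_hours = 24,
                                       err = forecast_error_config()) {
  truth <- validate_meteo(truth)
  stopifnot(inherits(err, "forecast_error_config"))
  idx <- which(truth$time >= issue_time &
                 truth$time < issue_time + horizon_hours * 3600)
  step <- meteo_step_hours(truth)
  if (length(idx) < horizon_hours / step) {
    stop_pondcast(
      sprintf("truth does not cover [%s, +%g h]", format(issue_time, tz = "UTC"),
              horizon_hours),
      class = "horizon"
    )
  }
  base <- truth[idx, ]
  n <- nrow(base)
  members <- lapply(seq_len(err$n_members), function(m) {
    mseed <- (as.numeric(err$seed) * 1000003 + m * 7919) %% .Machine$integer.max
    with_seed(mseed, {
      sw <- base$shortwave * err$bias$shortwave_mult *
        pmax(0, 1 + ar1_series(n, err$error_persistence, err$spread_sd$shortwave_rel))
      at <- base$air_temp + err$bias$air_temp +
        ar1_series(n, err$error_persistence, err$spread_sd$air_temp)
      dp <- base$dewpoint + err$bias$dewpoint +
        ar1_series(n, err$error_persistence, err$spread_sd$dewpoint)
      wd <- pmax(0, base$wind + err$bias$wind +
                   ar1_series(n, err$error_persistence, err$spread_sd$wind))
      tibble(
        time = base$time, shortwave = sw, par = shortwave_to_par(sw),
        air_temp = at, dewpoint = pmin(dp, at), wind = wd,
        pressure = base$pressure
      )
    })
  })
  ensemble_forecast(members, issue_time = issue_time,
                    horizon_hours = horizon_hours)
}
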