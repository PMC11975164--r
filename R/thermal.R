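#' Pond thermal model parameters
#'
#' Parameters of the zero-dimensional (depth-averaged, well-mixed) pond
#' energy balance. Net surface flux combines absorbed shortwave, Brunt
#' clear-sky atmospheric longwave (from vapor pressure at the dew point),
#' grey-body water longwave emission, wind-function latent heat and
#' Bowen-ratio sensible heat. All coefficients are configurable; the
#' defaults are standard limnological choices for a shallow raceway.
#'
#' @param depth Pond depth, m (> 0). The 0.25 m default matches a raceway
#'   operated at 25 cm with daily make-up water.
#' @param albedo Shortwave water-surface albedo, in [0, 1].
#' @param water_emissivity Longwave emissivity of the water surface.
#' @param wind_function Numeric `c(a, b)` in the aerodynamic transfer
#'   function `f(U) = a + b * wind` (W m-2 kPa-1); multiplies the
#'   vapor-pressure deficit for latent heat and, scaled by the psychrometric
#'   constant, the air-water temperature difference for sensible heat.
#' @param initial_temp Initial water temperature, degC.
#' @param substep_seconds Internal explicit-Euler substep, s. Stepping is
#'   sub-divided for stability; the hourly interface is unchanged.
#' @return A `thermal_params` list.
#' @export
thermal_params <- function(depth = 0.25, albedo = 0.06,
                           water_emissivity = 0.97,
                           wind_function = c(a = 120, b = 20),
                           initial_temp = 25,
                           substep_seconds = 300) {
  check_number(depth, "depth", 1e-6)
  check_number(albedo, "albedo", 0, 1)
  check_number(water_emissivity, "water_emissivity", 0, 1)
  stopifnot(length(wind_function) == 2L, all(is.finite(wind_function)))
  check_number(initial_temp, "initial_temp", -50, 80)
  check_number(substep_seconds, "substep_seconds", 1, 3600)
  structure(list(depth = depth, albedo = albedo,
                 water_emissivity = water_emissivity,
                 wind_function = unname(wind_function),
                 initial_temp = initial_temp,
                 substep_seconds = substep_seconds),
            class = "thermal_params")
}

#' Net surface heat flux of the pond
#'
#' `Q_net = SW(1 - albedo) + LW_in - LW_out - latent - sensible`, W m-2,
#' positive into the water. Vectorised over all arguments.
#'
#' @param water_temp Water temperature, degC.
#' @param shortwave Shortwave irradiance, W m-2.
#' @param air_temp Air temperature, degC.
#' @param dewpoint Dew point, degC.
#' @param wind Wind speed, m s-1.
#' @param pressure Air pressure, kPa.
#' @param p A [thermal_params()].
#' @return Net heat flux, W m-2.
#' @export
net_heat_flux <- function(water_temp, shortwave, air_temp, dewpoint, wind,
                          pressure, p = thermal_params()) {
  ea <- saturation_vapor_pressure(dewpoint)        # actual vapor pressure, kPa
  esw <- saturation_vapor_pressure(water_temp)     # at water surface
  # Brunt clear-sky emissivity, vapor pressure in hPa
  eps_a <- pmin(1, 0.51 + 0.066 * sqrt(ea * 10))
  lw_in <- eps_a * .const$sigma * (air_temp + 273.15)^4
  lw_out <- p$water_emissivity * .const$sigma * (water_temp + 273.15)^4
  fU <- p$wind_function[1] + p$wind_function[2] * wind
  latent <- fU * (esw - ea)
  gamma <- 0.000665 * pressure                     # psychrometric, kPa K-1
  sensible <- fU * gamma * (water_temp - air_temp)
  shortwave * (1 - p$albedo) + lw_in - lw_out - latent - sensible
}

#' Advance pond water temperature by one explicit Euler step
#'
#' `T' = T + dt * Q_net / (rho c_p depth)`. This is the primitive the
#' simulator composes (with internal substepping); it is exposed for
#' testing and for building alternative integrators.
#'
#' @param water_temp Current water temperature, degC.
#' @param met One meteorological record (a one-row data frame or named list
#'   with `shortwave`, `air_temp`, `dewpoint`, `wind`, `pressure`).
#' @param p A [thermal_params()].
#' @param dt Time step, s (> 0).
#' @return Updated water temperature, degC.
#' @export
step_water_temperature <- function(water_temp, met, p = thermal_params(),
                                   dt = 3600) {
  check_number(dt, "dt", 1e-9)
  q <- net_heat_flux(water_temp, met$shortwave, met$air_temp, met$dewpoint,
                     met$wind, met$pressure, p)
  if (any(!is.finite(q))) {
    stop_pondcast("non-finite forcing in thermal step", class = "numeric")
  }
  water_temp + dt * q / (.const$rho_w * .const$cp_w * p$depth)
}

#' Simulate pond water temperature over a meteorological series
#'
#' Integrates the 0-D energy balance along an hourly series. The returned
#' temperature at each timestamp is the state *at* that instant: the first
#' equals `p$initial_temp`, and record i's forcing advances the state from
#' timestamp i to i+1 in substeps of `p$substep_seconds`. Deterministic and
#' independent of chunking: simulating two halves (seeding the second with
#' the first's final temperature) equals one pass.
#'
#' @param met An hourly meteorological tibble.
#' @param p A [thermal_params()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation built on [step_water_temperature()]); both produce the
#'   same trajectory.
#' @return A tibble `time`, `water_temp` (degC), `evaporation_mm` — the
#'   diagnostic evaporative water loss over the hour starting at `time`
#'   (depth itself is held constant, emulating daily make-up water).
#' @examples
#' met <- generate_truth_weather(weather_config(n_days = 2, seed = 1))
#' wt <- simulate_water_temperature(met, thermal_params())
#' range(wt$water_temp)
#' @export
simulate_water_temperature <- function(met, p = thermal_params(),
                                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  met <- validate_meteo(met)
  if (!isTRUE(all.equal(meteo_step_hours(met), 1))) {
    stop_pondcast("thermal simulation expects an hourly series", class = "step")
  }
  n <- nrow(met)
  nsub <- ceiling(3600 / p$substep_seconds)
  dt <- 3600 / nsub
  if (engine == "cpp") {
    temps <- thermal_sim_cpp(p$initial_temp, met$shortwave, met$air_temp,
                             met$dewpoint, met$wind, met$pressure,
                             dt, nsub, p$depth, p$albedo, p$water_emissivity,
                             p$wind_function[1], p$wind_function[2])
  } else {
    temps <- numeric(n)
    temps[1] <- p$initial_temp
    tw <- p$initial_temp
    for (i in seq_len(n - 1L)) {
      row <- met[i, ]
      for (s in seq_len(nsub)) {
        tw <- step_water_temperature(tw, row, p, dt)
      }
      temps[i + 1L] <- tw
    }
  }
  # diagnostic evaporation from the latent flux at the resolved state
  ea <- saturation_vapor_pressure(met$dewpoint)
  fU <- p$wind_function[1] + p$wind_function[2] * met$wind
  latent <- pmax(0, fU * (saturation_vapor_pressure(temps) - ea))
  tibble(time = met$time, water_temp = temps,
         evaporation_mm = latent * 3600 / (.const$lambda_v * .const$rho_w) * 1000)
}
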