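#' Pond optics parameters
#'
#' Light attenuation through the culture follows the Beer-Lambert law with
#' total attenuation `k_water + k_biomass * concentration` (m-1,
#' concentration in g AFDW L-1). The water column is discretised into
#' `n_layers` equal-volume layers perpendicular to the incident light,
#' each evaluated at its midpoint depth.
#'
#' @param k_water Background attenuation of the medium, m-1.
#' @param k_biomass Biomass-specific attenuation, m-1 per (g L-1); the
#'   product `k_biomass * concentration * depth` is the dimensionless
#'   culture optical depth.
#' @param n_layers Number of layers M (>= 1). 100 keeps the discretisation
#'   error of daily production well below 0.5%.
#' @return An `optics_params` list.
#' @export
optics_params <- function(k_water = 0.2, k_biomass = 120, n_layers = 100) {
  check_number(k_water, "k_water", 0)
  check_number(k_biomass, "k_biomass", 0)
  check_number(n_layers, "n_layers", 1)
  structure(list(k_water = k_water, k_biomass = k_biomass,
                 n_layers = as.integer(n_layers)),
            class = "optics_params")
}

#' Pond culture state
#'
#' An instantaneous snapshot of the culture: biomass concentration, pond
#' volume and depth, water temperature and clock.
#'
#' @param concentration Biomass concentration, g AFDW L-1 (>= 0).
#' @param volume Culture volume, L (> 0); 800 L matches an indoor
#'   fiberglass raceway.
#' @param depth Pond depth, m.
#' @param water_temp Water temperature, degC.
#' @param clock POSIXct instant of the snapshot.
#' @return A `pond_state` list.
#' @export
pond_state <- function(concentration = 0.25, volume = 800, depth = 0.25,
                       water_temp = 25,
                       clock = as.POSIXct("2013-06-01", tz = "UTC")) {
  check_number(concentration, "concentration", 0)
  check_number(volume, "volume", 1e-9)
  check_number(depth, "depth", 1e-9)
  check_number(water_temp, "water_temp", -50, 80)
  structure(list(concentration = concentration, volume = volume,
                 depth = depth, water_temp = water_temp, clock = clock),
            class = "pond_state")
}

#' @export
print.pond_state <- function(x, ...) {
  cat(sprintf("<pond_state> %.4f g/L in %.0f L at %.1f degC, depth %.2f m, %s\n",
              x$concentration, x$volume, x$water_temp, x$depth,
              format(x$clock, tz = "UTC", usetz = TRUE)))
  invisible(x)
}

#' Irradiance profile through the culture
#'
#' Beer-Lambert attenuation evaluated at layer midpoints:
#' `I_j = surface_par * exp(-(k_water + k_biomass c) z_j)` with
#' `z_j = depth * (j - 1/2) / M`. Strictly non-increasing with depth.
#'
#' @param surface_par Surface PAR, umol m-2 s-1 (>= 0).
#' @param concentration Biomass concentration, g L-1 (>= 0).
#' @param optics An [optics_params()].
#' @param depth Pond depth, m.
#' @return Numeric vector of M layer irradiances, surface layer first.
#' @examples
#' light_profile(2000, 0.5, optics_params(n_layers = 5), depth = 0.25)
#' @export
light_profile <- function(surface_par, concentration, optics = optics_params(),
                          depth = 0.25) {
  check_number(surface_par, "surface_par", 0)
  check_number(concentration, "concentration", 0)
  check_number(depth, "depth", 1e-9)
  m <- optics$n_layers
  z <- depth * (seq_len(m) - 0.5) / m
  k <- optics$k_water + optics$k_biomass * concentration
  surface_par * exp(-k * z)
}

#' Net specific growth rate of the mixed culture
#'
#' The layer-averaged instantaneous rate: each of the M layers contributes
#' its interpolated growth rate if its irradiance is at or above the
#' strain's compensation threshold, and minus its dark-loss rate below it
#' (respiration continues in the dark zone even during the day). Because
#' the culture is well mixed, cells sample all layers and the whole pond
#' grows at the layer mean.
#'
#' @param concentration Biomass concentration, g L-1 (vectorised).
#' @param surface_par Surface PAR, umol m-2 s-1.
#' @param water_temp Culture temperature, degC.
#' @param optics An [optics_params()].
#' @param strain A [strain_response()].
#' @param depth Pond depth, m.
#' @return Net specific rate, d-1 (same length as `concentration`).
#' @export
net_growth_rate <- function(concentration, surface_par, water_temp,
                            optics = optics_params(),
                            strain = default_strain(), depth = 0.25) {
  m <- optics$n_layers
  z <- depth * (seq_len(m) - 0.5) / m
  vapply(concentration, function(cc) {
    irr <- surface_par * exp(-(optics$k_water + optics$k_biomass * cc) * z)
    lit <- irr >= strain$compensation_light
    r <- numeric(m)
    if (any(lit)) {
      r[lit] <- interp_rate(strain, water_temp, irr[lit], "growth")
    }
    if (any(!lit)) {
      r[!lit] <- -interp_rate(strain, water_temp, irr[!lit], "dark_loss")
    }
    mean(r)
  }, numeric(1))
}

#' Advance the culture concentration by one time step
#'
#' Exponential within-step update at the current net specific rate:
#' `c' = c * exp(r * dt / 24)` with `r` in d-1 and `dt` in hours; layers
#' re-mix instantly afterwards (well-mixed assumption).
#'
#' @param state A [pond_state()] (supplies concentration, water temperature
#'   and depth).
#' @param surface_par Surface PAR over the step, umol m-2 s-1.
#' @param optics An [optics_params()].
#' @param strain A [strain_response()].
#' @param dt_hours Step length, h (> 0).
#' @return The new concentration, g L-1.
#' @examples
#' st <- pond_state(concentration = 0.3, water_temp = 30)
#' step_growth(st, surface_par = 1500)
#' @export
step_growth <- function(state, surface_par, optics = optics_params(),
                        strain = default_strain(), dt_hours = 1) {
  stopifnot(inherits(state, "pond_state"))
  check_number(dt_hours, "dt_hours", 1e-9)
  if (state$concentration < 0) {
    stop_pondcast("negative concentration in pond state", class = "state")
  }
  r <- net_growth_rate(state$concentration, surface_par, state$water_temp,
                       optics, strain, state$depth)
  state$concentration * exp(r * dt_hours / 24)
}

#' Simulate culture growth over a forced interval
#'
#' Sequentially applies the hourly growth update using each record's PAR
#' and pond water temperature. The forcing tibble must carry a
#' `water_temp` column (join the output of
#' [simulate_water_temperature()] onto the meteorological series).
#' Deterministic, and composable: simulating an interval in two chained
#' halves equals one pass.
#'
#' @param state A [pond_state()] valid at the first record's timestamp.
#' @param met Hourly tibble with at least `time`, `par`, `water_temp`.
#' @param optics An [optics_params()].
#' @param strain A [strain_response()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference path
#'   through [step_growth()]).
#' @return A tibble `time`, `concentration`, `water_temp` with
#'   `nrow(met) + 1` rows: the state at each record's start plus the final
#'   state one step after the last record.
#' @examples
#' met <- generate_truth_weather(weather_config(n_days = 1, seed = 1))
#' wt <- simulate_water_temperature(met)
#' met$water_temp <- wt$water_temp
#' traj <- simulate_growth(pond_state(0.25), met)
#' tail(traj, 1)
#' @export
simulate_growth <- function(state, met, optics = optics_params(),
                            strain = default_strain(),
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(state, "pond_state"))
  if (!all(c("time", "par", "water_temp") %in% names(met))) {
    stop_pondcast("growth forcing needs `time`, `par`, `water_temp` columns",
                  class = "schema")
  }
  n <- nrow(met)
  step_h <- if (n >= 2L) {
    as.numeric(met$time[2] - met$time[1], units = "hours")
  } else 1
  if (!isTRUE(all.equal(step_h, 1))) {
    stop_pondcast("growth simulation expects an hourly series", class = "step")
  }
  if (engine == "cpp") {
    conc <- drop(growth_sim_cpp(
      state$concentration, met$par, met$water_temp, 1,
      strain$temp_grid, strain$light_grid, strain$growth_rate,
      strain$dark_loss, strain$compensation_light,
      optics$k_water, optics$k_biomass, state$depth, optics$n_layers))
  } else {
    conc <- numeric(n + 1L)
    conc[1] <- state$concentration
    s <- state
    for (i in seq_len(n)) {
      s$water_temp <- met$water_temp[i]
      s$concentration <- step_growth(s, met$par[i], optics, strain, 1)
      conc[i + 1L] <- s$concentration
    }
  }
  tibble(
    time = c(met$time, met$time[n] + 3600),
    concentration = conc,
    water_temp = c(met$water_temp, met$water_temp[n])
  )
}
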