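# shared fixtures, all built in code

# constant meteorological forcing as a valid hourly series
constant_met <- function(n_hours, shortwave = 400, air_temp = 30,
                         dewpoint = 12, wind = 3, pressure = 97,
                         par = NULL,
                         start = as.POSIXct("2013-06-01 00:00:00", tz = "UTC")) {
  sw <- rep_len(shortwave, n_hours)
  if (is.null(par)) par <- shortwave_to_par(sw)
  tibble::tibble(
    time = start + (seq_len(n_hours) - 1L) * 3600,
    shortwave = sw, par = par,
    air_temp = air_temp, dewpoint = dewpoint, wind = wind, pressure = pressure
  )
}

# strain with spatially/thermally constant rates; useful for closed forms
constant_strain <- function(mu = 0.5, loss = 0.1, compensation_light = 10) {
  strain_response(
    temp_grid = c(0, 50), light_grid = c(0, 3000),
    growth_rate = matrix(mu, 2, 2), dark_loss = matrix(loss, 2, 2),
    compensation_light = compensation_light
  )
}

# optics with no attenuation at all
no_optics <- function(n_layers = 10) {
  optics_params(k_water = 0, k_biomass = 0, n_layers = n_layers)
}

# small Mesa-like truth series cached per test file
mesa_truth <- local({
  cache <- new.env(parent = emptyenv())
  function(n_days, seed = 1) {
    key <- paste0("d", n_days, "s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_truth_weather(
        weather_config(n_days = n_days, seed = seed))
    }
    cache[[key]]
  }
})

# independent bisection root of the net heat flux under fixed forcing
bisect_equilibrium <- function(met_row, p, lower = -10, upper = 80) {
  f <- function(tw) net_heat_flux(tw, met_row$shortwave, met_row$air_temp,
                                  met_row$dewpoint, met_row$wind,
                                  met_row$pressure, p)
  stopifnot(f(lower) > 0, f(upper) < 0)
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}
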