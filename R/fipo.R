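#' Dilution scenario grid
#'
#' The candidate dilution rates evaluated every decision day. The default
#' is the 100-value grid 0.00, 0.01, ..., 0.99: from no operation to a
#' near-complete blowdown.
#'
#' @param n Number of rates.
#' @param max_rate Largest rate (<= 0.99).
#' @return Ascending numeric vector of unique rates in [0, 0.99].
#' @export
scenario_grid <- function(n = 100, max_rate = 0.99) {
  check_number(n, "n", 1)
  check_number(max_rate, "max_rate", 0, 0.99)
  rates <- if (n == 1) 0 else seq(0, max_rate, length.out = n)
  validate_grid(rates)
}

validate_grid <- function(rates) {
  if (length(rates) < 1L || any(!is.finite(rates)) ||
      any(rates < 0 | rates > 0.99) || any(diff(rates) <= 0)) {
    stop_pondcast("scenario grid must be ascending, unique, within [0, 0.99]",
                  class = "domain")
  }
  rates
}

check_member_window <- function(member, clock, horizon_hours) {
  idx <- which(member$time >= clock & member$time < clock + horizon_hours * 3600)
  if (length(idx) < horizon_hours ||
      abs(as.numeric(member$time[idx[1]] - clock, units = "hours")) > 1e-6) {
    stop_pondcast(
      sprintf("forecast member does not cover [%s, +%g h]",
              format(clock, tz = "UTC"), horizon_hours),
      class = "horizon"
    )
  }
  member[idx, ]
}

#' Predicted production of one dilution scenario under one forecast member
#'
#' The scenario objective is total biomass production over the decision
#' horizon: biomass harvested now plus the standing biomass predicted at
#' the next harvest time,
#' `J_m(d) = d c V + c_plus(d, member) V`.
#' The member's meteorology drives the pond water temperature (initialised
#' at the current pond temperature) and then the layered growth model for
#' the diluted culture.
#'
#' @param state A [pond_state()] at the decision instant.
#' @param member One meteorological tibble covering
#'   `[state$clock, state$clock + horizon_hours)`.
#' @param d Dilution rate in [0, 0.99].
#' @param strain A [strain_response()].
#' @param optics An [optics_params()].
#' @param tparams A [thermal_params()].
#' @param horizon_hours Decision horizon (24 h: next-day optimisation).
#' @return Predicted production, g.
#' @export
evaluate_scenario <- function(state, member, d, strain = default_strain(),
                              optics = optics_params(),
                              tparams = thermal_params(),
                              horizon_hours = 24) {
  stopifnot(inherits(state, "pond_state"))
  member <- check_member_window(member, state$clock, horizon_hours)
  dil <- apply_dilution(state, d)
  tp <- tparams
  tp$initial_temp <- state$water_temp
  wt <- simulate_water_temperature(member, tp)
  member$water_temp <- wt$water_temp
  traj <- simulate_growth(dil$state, member, optics, strain)
  dil$harvested_g + traj$concentration[nrow(traj)] * state$volume
}

#' Ensemble-mean objective of one dilution scenario
#'
#' The mean of [evaluate_scenario()] across all forecast members: the
#' ensemble-mean predicted production for that rate.
#'
#' @inheritParams evaluate_scenario
#' @param forecast An [ensemble_forecast()].
#' @return Ensemble-mean predicted production, g.
#' @export
ensemble_objective <- function(state, forecast, d, strain = default_strain(),
                               optics = optics_params(),
                               tparams = thermal_params(),
                               horizon_hours = 24) {
  members <- forecast_members(forecast)
  if (length(members) == 0L) {
    stop_pondcast("ensemble has no members", class = "domain")
  }
  mean(vapply(members, function(m) {
    evaluate_scenario(state, m, d, strain, optics, tparams, horizon_hours)
  }, numeric(1)))
}

#' Choose the day's dilution rate from an ensemble forecast
#'
#' Evaluates every rate of the scenario grid under every forecast member
#' (`E * |grid|` one-day growth simulations), averages production across
#' members per rate, and picks the rate maximising the ensemble mean. Ties
#' resolve to the smallest rate (least intervention). The full member-by-
#' rate objective table is retained as an audit trail.
#'
#' @inheritParams ensemble_objective
#' @param grid Ascending rate grid, default [scenario_grid()].
#' @return A `fipo_decision`: list with `time`, `chosen_rate`, `objective`
#'   (tibble `rate`, `objective_g`), `member_objectives` (E x |grid|
#'   matrix, g), `n_members`, `n_simulations`.
#' @examples
#' truth <- generate_truth_weather(weather_config(n_days = 2, seed = 1))
#' st <- pond_state(0.4, clock = truth$time[13], water_temp = 28)
#' fc <- generate_ensemble_forecast(truth, st$clock, 24,
#'                                  forecast_error_config(n_members = 3))
#' dec <- choose_dilution(st, fc, grid = seq(0, 0.9, by = 0.1))
#' dec$chosen_rate
#' @export
choose_dilution <- function(state, forecast, grid = scenario_grid(),
                            strain = default_strain(),
                            optics = optics_params(),
                            tparams = thermal_params(),
                            horizon_hours = 24) {
  stopifnot(inherits(state, "pond_state"))
  grid <- validate_grid(grid)
  members <- forecast_members(forecast)
  e <- length(members)
  if (e == 0L) stop_pondcast("ensemble has no members", class = "domain")
  c0 <- state$concentration * (1 - grid)
  standing <- matrix(NA_real_, nrow = e, ncol = length(grid))
  nsub <- ceiling(3600 / tparams$substep_seconds)
  for (m in seq_len(e)) {
    mem <- check_member_window(members[[m]], state$clock, horizon_hours)
    wtemp <- thermal_sim_cpp(state$water_temp, mem$shortwave, mem$air_temp,
                             mem$dewpoint, mem$wind, mem$pressure,
                             3600 / nsub, nsub, tparams$depth, tparams$albedo,
                             tparams$water_emissivity,
                             tparams$wind_function[1], tparams$wind_function[2])
    fin <- growth_sim_cpp(c0, mem$par, wtemp, 1,
                          strain$temp_grid, strain$light_grid,
                          strain$growth_rate, strain$dark_loss,
                          strain$compensation_light,
                          optics$k_water, optics$k_biomass,
                          state$depth, optics$n_layers)
    standing[m, ] <- fin[nrow(fin), ]
  }
  member_objectives <- state$concentration * state$volume *
    matrix(grid, nrow = e, ncol = length(grid), byrow = TRUE) +
    standing * state$volume
  objective <- colMeans(member_objectives)
  chosen <- grid[which.max(objective)]  # first max = smallest rate on ties
  structure(list(
    time = state$clock,
    chosen_rate = chosen,
    objective = tibble(rate = grid, objective_g = objective),
    member_objectives = member_objectives,
    n_members = e,
    n_simulations = e * length(grid)
  ), class = "fipo_decision")
}

#' @export
print.fipo_decision <- function(x, ...) {
  cat(sprintf(
    "<fipo_decision> %s: chose d = %.2f (%d members x %d rates = %d simulations)\n",
    format(x$time, tz = "UTC", usetz = TRUE), x$chosen_rate, x$n_members,
    nrow(x$objective), x$n_simulations))
  invisible(x)
}

#' Run one cultivation treatment over truth weather
#'
#' Simulates the pond day by day under the truth weather. At each daily
#' operation instant (`start + k` days, `k = 1 .. n_days`) the policy's
#' rate is applied: a fixed schedule for batch/fixed policies, or a fresh
#' [choose_dilution()] against that day's forecast for forecast-informed
#' policies. The forecast is used only to decide; the pond always evolves
#' under the truth weather afterwards, which is what makes forecast error
#' matter. The run is closed with [finalize_experiment()].
#'
#' @param truth Hourly truth meteorological tibble covering
#'   `[start, start + n_days days]` (one extra day for forecast-informed
#'   policies).
#' @param policy A policy (see [policy_batch()]).
#' @param n_days Number of daily operation cycles.
#' @param pond Initial [pond_state()] (its clock is reset to `start`; its
#'   water temperature follows the simulated truth temperature).
#' @param strain,optics,tparams Model parameter objects.
#' @param start POSIXct first instant of the run (default: first truth
#'   timestamp). Decisions happen at `start + 1, ..., n_days` days.
#' @param forecasts Forecast source for forecast-informed policies: `NULL`
#'   uses the truth itself as a degenerate single-member (perfect)
#'   forecast; a [forecast_error_config()] generates a synthetic ensemble
#'   each day (member seeds derived from the config seed and the day
#'   index); or a pre-built list of [ensemble_forecast()]s, one per day,
#'   issued at the decision instants.
#' @param grid Scenario grid for forecast-informed policies.
#' @param horizon_hours Decision horizon, h.
#' @return A `pond_run`: list with `trajectory` (tibble `time`,
#'   `concentration`, `water_temp`; operation instants appear twice,
#'   before and after the dilution drop), `ledger` (tibble `time`, `day`,
#'   `rate`, `conc_before`, `conc_after`, `harvested_g`, `kind`),
#'   `decisions` (list of `fipo_decision`, forecast policies only),
#'   `policy`, `n_days`, `total_g`.
#' @examples
#' truth <- generate_truth_weather(weather_config(n_days = 10, seed = 1))
#' run <- run_treatment(truth, policy_fixed(0.6, 3), n_days = 9,
#'                      pond = pond_state(0.25))
#' run$ledger
#' @export
run_treatment <- function(truth, policy, n_days,
                          pond = pond_state(),
                          strain = default_strain(),
                          optics = optics_params(),
                          tparams = thermal_params(),
                          start = NULL, forecasts = NULL,
                          grid = scenario_grid(), horizon_hours = 24) {
  truth <- validate_meteo(truth)
  if (!isTRUE(all.equal(meteo_step_hours(truth), 1))) {
    stop_pondcast("treatment runs need hourly truth weather", class = "step")
  }
  stopifnot(inherits(policy, "pond_policy"))
  check_number(n_days, "n_days", 1)
  n_days <- as.integer(n_days)
  start <- start %||% truth$time[1]

  is_fipo <- policy$kind == "forecast_informed"
  needed_end <- start + n_days * 86400 + if (is_fipo) (horizon_hours - 1) * 3600 else 0
  if (truth$time[1] > start || truth$time[nrow(truth)] < needed_end) {
    stop_pondcast("truth weather does not cover the experiment window",
                  class = "horizon")
  }
  if (is.list(forecasts) && !inherits(forecasts, "forecast_error_config") &&
      length(forecasts) < n_days && is_fipo) {
    stop_pondcast("need one ensemble forecast per operation day",
                  class = "alignment")
  }

  wt <- simulate_water_temperature(truth, tparams)
  met <- truth
  met$water_temp <- wt$water_temp

  state <- pond
  state$clock <- start
  i0 <- which(met$time == start)
  if (length(i0) != 1L) {
    stop_pondcast("`start` must coincide with a truth timestamp",
                  class = "alignment")
  }
  state$water_temp <- met$water_temp[i0]

  ledger <- empty_ledger()
  decisions <- vector("list", if (is_fipo) n_days else 0L)
  traj_parts <- vector("list", n_days)

  for (k in seq_len(n_days)) {
    idx <- i0 + (k - 1L) * 24L + 0:23
    day_met <- met[idx, ]
    traj <- simulate_growth(state, day_met, optics, strain)
    traj_parts[[k]] <- traj
    t_k <- start + k * 86400
    state$concentration <- traj$concentration[25]
    state$water_temp <- met$water_temp[i0 + k * 24L]
    state$clock <- t_k

    if (is_fipo) {
      fc <- day_forecast(forecasts, met, t_k, horizon_hours, k)
      if (abs(as.numeric(attr(fc, "issue_time") - t_k, units = "hours")) > 1e-6) {
        stop_pondcast(
          sprintf("forecast for day %d issued at %s, expected %s", k,
                  format(attr(fc, "issue_time"), tz = "UTC"),
                  format(t_k, tz = "UTC")),
          class = "alignment"
        )
      }
      dec <- choose_dilution(state, fc, grid, strain, optics, tparams,
                             horizon_hours)
      decisions[[k]] <- dec
      rate <- dec$chosen_rate
      kind <- "decision"
    } else {
      rate <- scheduled_rate(policy, k)
      kind <- "scheduled"
    }

    if (rate > 0) {
      before <- state$concentration
      dil <- apply_dilution(state, rate)
      state <- dil$state
      ledger <- bind_rows(ledger, ledger_row(
        time = t_k, day = k, rate = rate, conc_before = before,
        conc_after = state$concentration, harvested_g = dil$harvested_g,
        kind = kind))
    }
  }

  ledger <- finalize_experiment(state, ledger)
  trajectory <- bind_rows(traj_parts)
  structure(list(
    trajectory = trajectory, ledger = ledger, decisions = decisions,
    policy = policy, n_days = n_days, start = start,
    total_g = ledger_total(ledger)
  ), class = "pond_run")
}

# resolve the forecast for operation day k issued at t_k
day_forecast <- function(forecasts, met, t_k, horizon_hours, k) {
  if (is.null(forecasts)) {
    # perfect forecast: degenerate single-member ensemble equal to truth
    slice <- check_member_window(met, t_k, horizon_hours)
    return(ensemble_forecast(list(slice[, setdiff(names(slice), "water_temp")]),
                             issue_time = t_k, horizon_hours = horizon_hours))
  }
  if (inherits(forecasts, "forecast_error_config")) {
    err_k <- forecasts
    err_k$seed <- as.integer((as.numeric(forecasts$seed) + k * 131) %%
                               .Machine$integer.max)
    return(generate_ensemble_forecast(
      met[, setdiff(names(met), "water_temp")], t_k, horizon_hours, err_k))
  }
  forecasts[[k]]
}

#' @export
print.pond_run <- function(x, ...) {
  n_events <- sum(x$ledger$kind != "terminal")
  cat(sprintf("<pond_run> %s: %d day(s), %d harvest event(s) + terminal, total %.2f g\n",
              x$policy$kind, x$n_days, n_events, x$total_g))
  invisible(x)
}
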