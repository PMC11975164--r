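# closed-form regimes: no attenuation, rate surfaces constant, so
# J(d) = c V (d + (1 - d) exp(r * dt / 24)) exactly

test_that("with growth beating harvest the optimizer keeps the culture (d = 0)", {
  mu <- 0.8
  st_strain <- constant_strain(mu = mu, loss = 0, compensation_light = 0)
  met <- constant_met(25, par = 500)
  state <- pond_state(0.5, volume = 800, water_temp = 30,
                      clock = met$time[1])
  fc <- ensemble_forecast(list(met), issue_time = met$time[1])
  grid <- scenario_grid()
  dec <- choose_dilution(state, fc, grid, strain = st_strain,
                         optics = no_optics())
  analytic <- 0.5 * 800 * (grid + (1 - grid) * exp(mu))
  expect_equal(dec$objective$objective_g, analytic, tolerance = 1e-9)
  expect_identical(dec$chosen_rate, 0)
})

test_that("with net biomass loss the optimizer recommends a blowdown (d = 0.99)", {
  lambda <- 0.3
  st_strain <- constant_strain(mu = 2, loss = lambda, compensation_light = 10)
  met <- constant_met(25, shortwave = 0, par = 0)  # all-dark cold member
  state <- pond_state(0.5, volume = 800, water_temp = 10,
                      clock = met$time[1])
  fc <- ensemble_forecast(list(met), issue_time = met$time[1])
  grid <- scenario_grid()
  dec <- choose_dilution(state, fc, grid, strain = st_strain,
                         optics = no_optics())
  analytic <- 0.5 * 800 * (grid + (1 - grid) * exp(-lambda))
  expect_equal(dec$objective$objective_g, analytic, tolerance = 1e-9)
  expect_identical(dec$chosen_rate, 0.99)
})

test_that("a batch day (d = 0) is the standing biomass after 24 h of growth", {
  met <- mesa_truth(2)
  st <- pond_state(0.4, clock = met$time[1], water_temp = 26)
  j0 <- evaluate_scenario(st, met, 0)
  wt <- simulate_water_temperature(met[1:24, ],
                                   thermal_params(initial_temp = 26))
  day <- met[1:24, ]
  day$water_temp <- wt$water_temp
  traj <- simulate_growth(st, day)
  expect_equal(j0, traj$concentration[25] * 800, tolerance = 1e-9)
})

test_that("a default decision performs exactly E x 100 simulations", {
  met <- mesa_truth(2)
  st <- pond_state(0.4, clock = met$time[1], water_temp = 28)
  fc <- generate_ensemble_forecast(met, st$clock, 24,
                                   forecast_error_config(n_members = 11))
  dec <- choose_dilution(st, fc)
  expect_identical(dec$n_simulations, 1100L)
  expect_identical(dim(dec$member_objectives), c(11L, 100L))
  expect_identical(length(dec$objective$rate), 100L)
  expect_equal(dec$objective$rate, seq(0, 0.99, by = 0.01), tolerance = 1e-12)
})

test_that("ensemble objective is the member mean and is permutation-invariant", {
  met <- mesa_truth(2)
  st <- pond_state(0.4, clock = met$time[1], water_temp = 28)
  fc <- generate_ensemble_forecast(met, st$clock, 24,
                                   forecast_error_config(n_members = 4))
  members <- forecast_members(fc)
  per_member <- vapply(members, function(m) evaluate_scenario(st, m, 0.3),
                       numeric(1))
  expect_equal(ensemble_objective(st, fc, 0.3), mean(per_member),
               tolerance = 1e-12)

  perm <- ensemble_forecast(members[c(3, 1, 4, 2)], issue_time = st$clock)
  expect_equal(ensemble_objective(st, perm, 0.3),
               ensemble_objective(st, fc, 0.3), tolerance = 1e-12)

  ident <- ensemble_forecast(members[c(2, 2, 2)], issue_time = st$clock)
  expect_equal(ensemble_objective(st, ident, 0.3), unname(per_member[2]),
               tolerance = 1e-12)
})

test_that("the audit table matches per-scenario evaluation and the brute-force argmax", {
  met <- mesa_truth(2)
  st <- pond_state(0.45, clock = met$time[1], water_temp = 27)
  fc <- generate_ensemble_forecast(met, st$clock, 24,
                                   forecast_error_config(n_members = 3))
  grid <- seq(0, 0.99, by = 0.11)
  dec <- choose_dilution(st, fc, grid)
  members <- forecast_members(fc)
  # dual route: scalar evaluation of every (member, rate) cell
  for (m in seq_along(members)) {
    for (i in seq_along(grid)) {
      expect_equal(dec$member_objectives[m, i],
                   evaluate_scenario(st, members[[m]], grid[i]),
                   tolerance = 1e-9)
    }
  }
  # brute-force maximisation over the audit table
  best <- 1L
  for (i in seq_along(grid)) {
    s <- 0
    for (m in seq_along(members)) s <- s + dec$member_objectives[m, i]
    if (s / length(members) > sum(dec$member_objectives[, best]) / length(members)) {
      best <- i
    }
  }
  expect_identical(dec$chosen_rate, grid[best])
})

test_that("treatment runs honour the schedule and close with a terminal event", {
  truth <- mesa_truth(10)
  run_b <- run_treatment(truth, policy_batch(), n_days = 9,
                         pond = pond_state(0.25))
  expect_identical(nrow(run_b$ledger), 1L)
  expect_identical(run_b$ledger$kind, "terminal")

  run_f <- run_treatment(truth, policy_fixed(0.6, 3), n_days = 9,
                         pond = pond_state(0.25))
  expect_identical(sum(run_f$ledger$kind == "scheduled"), 3L)
  expect_identical(nrow(run_f$ledger), 4L)
  expect_equal(run_f$ledger$day[run_f$ledger$kind == "scheduled"], c(3L, 6L, 9L))
  expect_equal(ledger_total(run_f$ledger), sum(run_f$ledger$harvested_g))

  # mass balance at every recorded event
  ev <- run_f$ledger[run_f$ledger$kind == "scheduled", ]
  expect_equal(ev$harvested_g, ev$rate * ev$conc_before * 800, tolerance = 1e-12)
  expect_equal(ev$conc_after, ev$conc_before * (1 - ev$rate), tolerance = 1e-12)
})

test_that("zero-error ensembles reproduce the perfect-forecast run exactly", {
  truth <- mesa_truth(7)
  err0 <- forecast_error_config(
    n_members = 5,
    bias = list(shortwave_mult = 1, air_temp = 0, dewpoint = 0, wind = 0),
    spread_sd = list(shortwave_rel = 0, air_temp = 0, dewpoint = 0, wind = 0)
  )
  perfect <- run_treatment(truth, policy_forecast("perfect"), n_days = 5,
                           pond = pond_state(0.3))
  degen <- run_treatment(truth, policy_forecast("ensemble"), n_days = 5,
                         pond = pond_state(0.3), forecasts = err0)
  expect_equal(degen$ledger$rate, perfect$ledger$rate, tolerance = 1e-12)
  expect_equal(degen$ledger$harvested_g, perfect$ledger$harvested_g,
               tolerance = 1e-9)
  expect_equal(degen$total_g, perfect$total_g, tolerance = 1e-9)
})

test_that("misaligned or missing forecasts are rejected", {
  truth <- mesa_truth(4)
  fc_wrong <- generate_ensemble_forecast(
    truth, truth$time[1], 24, forecast_error_config(n_members = 2))
  expect_error(
    run_treatment(truth, policy_forecast("ensemble"), n_days = 2,
                  pond = pond_state(0.3),
                  forecasts = list(fc_wrong, fc_wrong)),
    class = "pondcast_error_alignment"
  )
  expect_error(
    run_treatment(truth, policy_forecast("perfect"), n_days = 4,
                  pond = pond_state(0.3)),
    class = "pondcast_error_horizon"
  )
  expect_error(
    run_treatment(truth, policy_batch(), n_days = 2, pond = pond_state(0.3),
                  start = truth$time[1] + 1800),
    class = "pondcast_error_alignment"
  )
})

test_that("runs are deterministic: same inputs give identical ledgers", {
  truth <- mesa_truth(6)
  a <- run_treatment(truth, policy_forecast("perfect"), n_days = 4,
                     pond = pond_state(0.3))
  b <- run_treatment(truth, policy_forecast("perfect"), n_days = 4,
                     pond = pond_state(0.3))
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$trajectory$concentration, b$trajectory$concentration)
})
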