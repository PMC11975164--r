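test_that("light profile follows the Beer-Lambert closed form", {
  # no attenuation: every layer sees the surface irradiance
  prof <- light_profile(1500, 0, no_optics(8), depth = 0.25)
  expect_equal(prof, rep(1500, 8))

  # total attenuation 10 /m, depth 0.25, 5 layers: first midpoint z = 0.025
  opt <- optics_params(k_water = 10, k_biomass = 0, n_layers = 5)
  prof <- light_profile(2000, 0.7, opt, depth = 0.25)
  expect_equal(prof[1], 2000 * exp(-0.25), tolerance = 1e-12)
  expect_equal(prof, 2000 * exp(-10 * 0.25 * (1:5 - 0.5) / 5), tolerance = 1e-12)
  expect_true(all(diff(prof) < 0))

  # doubling the concentration squares the transmitted fraction
  opt <- optics_params(k_water = 0, k_biomass = 50, n_layers = 6)
  f1 <- light_profile(1000, 0.3, opt) / 1000
  f2 <- light_profile(1000, 0.6, opt) / 1000
  expect_equal(f2, f1^2, tolerance = 1e-12)

  expect_error(optics_params(n_layers = 0), class = "pondcast_error_domain")
})

test_that("rate interpolation is exact at nodes, bilinear inside, clamped outside", {
  st <- default_strain()
  for (i in c(1, 7, length(st$temp_grid))) {
    for (j in c(1, 4, length(st$light_grid))) {
      expect_identical(interp_rate(st, st$temp_grid[i], st$light_grid[j]),
                       st$growth_rate[i, j])
    }
  }
  # midpoint of a cell: mean of the 4 surrounding nodes
  tm <- mean(st$temp_grid[5:6]); lm <- mean(st$light_grid[3:4])
  expect_equal(interp_rate(st, tm, lm), mean(st$growth_rate[5:6, 3:4]),
               tolerance = 1e-12)
  # clamping beyond the grid
  expect_identical(interp_rate(st, 100, st$light_grid[4]),
                   st$growth_rate[nrow(st$growth_rate), 4])
  expect_identical(interp_rate(st, -20, 1e5),
                   st$growth_rate[1, ncol(st$growth_rate)])
  expect_error(interp_rate(st, NaN, 100), class = "pondcast_error_domain")
})

test_that("growth steps match the exponential closed forms", {
  # all-dark pond, uniform loss 0.1 /d, 24 h: c e^-0.1
  st <- constant_strain(mu = 2, loss = 0.1)
  state <- pond_state(concentration = 0.8, water_temp = 25)
  c_dark <- step_growth(state, surface_par = 0, optics = optics_params(),
                        strain = st, dt_hours = 24)
  expect_equal(c_dark, 0.8 * exp(-0.1), tolerance = 1e-12)

  # no attenuation, constant mu: c e^(mu dt/24)
  c_lit <- step_growth(state, surface_par = 500, optics = no_optics(),
                       strain = constant_strain(mu = 1.2, loss = 0),
                       dt_hours = 6)
  expect_equal(c_lit, 0.8 * exp(1.2 * 6 / 24), tolerance = 1e-12)

  # zero is absorbing
  zero <- pond_state(concentration = 0, water_temp = 25)
  expect_identical(step_growth(zero, 1000), 0)
})

test_that("net growth rate is non-increasing in concentration (self-shading)", {
  conc <- seq(0.05, 2, by = 0.05)
  r <- net_growth_rate(conc, surface_par = 1800, water_temp = 30)
  expect_true(all(diff(r) <= 1e-12))
})

test_that("daily areal production has an interior optimum in starting concentration", {
  met <- constant_met(24, par = 1600)
  met$water_temp <- 30
  conc <- seq(0.02, 2.5, by = 0.02)
  prod <- sapply(conc, function(c0) {
    traj <- simulate_growth(pond_state(c0, water_temp = 30), met)
    traj$concentration[25] - c0
  })
  best <- which.max(prod)
  expect_gt(best, 1)
  expect_lt(best, length(conc))
  expect_gt(prod[best], 0)
})

test_that("interval simulation composes and matches the R reference engine", {
  met <- mesa_truth(2)
  wt <- simulate_water_temperature(met)
  met$water_temp <- wt$water_temp
  s0 <- pond_state(0.3, water_temp = met$water_temp[1])

  full <- simulate_growth(s0, met, engine = "cpp")
  ref <- simulate_growth(s0, met, engine = "r")
  expect_equal(full$concentration, ref$concentration, tolerance = 1e-10)

  s1 <- s0
  part1 <- simulate_growth(s0, met[1:24, ])
  s1$concentration <- part1$concentration[25]
  part2 <- simulate_growth(s1, met[25:48, ])
  expect_equal(c(part1$concentration, part2$concentration[-1]),
               full$concentration, tolerance = 1e-12)

  # 24 h of darkness: concentration decreases monotonically
  dark <- constant_met(24, shortwave = 0, par = 0)
  dark$water_temp <- 28
  traj <- simulate_growth(pond_state(0.5, water_temp = 28), dark)
  expect_true(all(diff(traj$concentration) < 0))

  # a lit, warm synthetic day yields positive net daily growth
  bright <- constant_met(24, par = 1500)
  bright$water_temp <- 32
  traj <- simulate_growth(pond_state(0.2, water_temp = 32), bright)
  expect_gt(traj$concentration[25], 0.2)
})

test_that("layer discretisation is converged at the default resolution", {
  met <- mesa_truth(2)[1:24, ]
  wt <- simulate_water_temperature(mesa_truth(2))[1:24, ]
  met$water_temp <- wt$water_temp
  prod <- sapply(c(50, 100, 200), function(m) {
    opt <- optics_params(n_layers = m)
    traj <- simulate_growth(pond_state(0.4, water_temp = met$water_temp[1]),
                            met, optics = opt)
    traj$concentration[25]
  })
  expect_lt(abs(prod[1] - prod[2]) / prod[2], 0.005)
  expect_lt(abs(prod[3] - prod[2]) / prod[2], 0.005)
})

test_that("strain tables round-trip through the delimited format", {
  st <- default_strain()
  f <- withr::local_tempfile(fileext = ".csv")
  write_strain_table(st, f)
  back <- read_strain_table(f)
  expect_equal(back$temp_grid, st$temp_grid)
  expect_equal(back$light_grid, st$light_grid)
  expect_equal(back$growth_rate, st$growth_rate, tolerance = 1e-12)
  expect_equal(back$dark_loss, st$dark_loss, tolerance = 1e-12)
  expect_equal(back$compensation_light, st$compensation_light)

  mangled <- readr::read_csv(f, comment = "#", show_col_types = FALSE)
  readr::write_csv(mangled[-3, ], f)
  expect_error(read_strain_table(f), class = "pondcast_error_schema")
})

test_that("degenerate and invalid strain surfaces are rejected", {
  expect_error(strain_response(c(10, 5), c(0, 100), matrix(1, 2, 2),
                               matrix(0, 2, 2)),
               class = "pondcast_error_domain")
  expect_error(strain_response(c(5, 10), c(0, 100), matrix(NA_real_, 2, 2),
                               matrix(0, 2, 2)),
               class = "pondcast_error_domain")
  expect_error(strain_response(c(5, 10), c(0, 100), matrix(1, 2, 2),
                               matrix(-0.1, 2, 2)),
               class = "pondcast_error_domain")
  expect_error(step_growth(structure(list(concentration = -1, water_temp = 25,
                                          depth = 0.25),
                                     class = "pond_state"), 100),
               class = "pondcast_error_state")
})
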