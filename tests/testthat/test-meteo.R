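test_that("CSV round trip reproduces all values exactly", {
  met <- mesa_truth(2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_meteo_table(met, f)
  back <- read_meteo_table(f)
  expect_identical(nrow(back), nrow(met))
  for (col in c("shortwave", "par", "air_temp", "dewpoint", "wind", "pressure")) {
    expect_identical(back[[col]], met[[col]])
  }
  expect_equal(as.numeric(back$time), as.numeric(met$time))
})

test_that("schema and invariant violations are reported by name and row", {
  met <- mesa_truth(1)
  f <- withr::local_tempfile(fileext = ".csv")

  readr::write_csv(met[, setdiff(names(met), "wind")], f)
  expect_error(read_meteo_table(f), "wind", class = "pondcast_error_schema")

  bad <- met
  bad$dewpoint[7] <- bad$air_temp[7] + 2
  readr::write_csv(bad, f)
  expect_error(read_meteo_table(f), "row 7", class = "pondcast_error_invariant")

  gap <- met[-10, ]
  expect_error(validate_meteo(gap), "gap", class = "pondcast_error_gap")

  shuffled <- met[c(2, 1, 3:24), ]
  expect_error(validate_meteo(shuffled), class = "pondcast_error_ordering")
})

test_that("dialect mapping renames columns and units convert", {
  met <- mesa_truth(1)
  odd <- met
  names(odd)[names(odd) == "shortwave"] <- "dswrf"
  names(odd)[names(odd) == "air_temp"] <- "t2m"
  odd$t2m <- odd$t2m + 273.15
  odd$dewpoint <- odd$dewpoint + 273.15
  odd$pressure <- odd$pressure * 1000
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(odd, f)
  back <- read_meteo_table(f, dialect = c(shortwave = "dswrf", air_temp = "t2m"),
                           units = list(temperature = "K", pressure = "Pa"))
  expect_equal(back$air_temp, met$air_temp, tolerance = 1e-12)
  expect_equal(back$pressure, met$pressure, tolerance = 1e-12)
  expect_error(
    read_meteo_table(f, dialect = c(shortwave = "nope")),
    "nope", class = "pondcast_error_schema"
  )
})

test_that("par is derived from shortwave when the column is absent", {
  met <- mesa_truth(1)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(met[, setdiff(names(met), "par")], f)
  back <- read_meteo_table(f)
  expect_equal(back$par, met$shortwave * 0.45 * 4.57, tolerance = 1e-12)
})

test_that("3-hourly files are detected and disaggregation replicates values", {
  met3 <- mesa_truth(2)[seq(1, 48, by = 3), ]
  expect_equal(meteo_step_hours(met3), 3)

  met1 <- disaggregate_to_hourly(met3)
  expect_equal(nrow(met1), 3 * nrow(met3))
  expect_equal(meteo_step_hours(met1), 1)
  # replication: one 3-h block maps onto 3 identical hours
  expect_equal(met1$shortwave[1:3], rep(met3$shortwave[1], 3))
  # per-variable mean preserved exactly, per block and overall
  for (col in c("shortwave", "par", "air_temp", "dewpoint", "wind", "pressure")) {
    expect_identical(mean(met1[[col]]), mean(rep(met3[[col]], each = 3)))
    block_means <- colMeans(matrix(met1[[col]], nrow = 3))
    expect_equal(block_means, met3[[col]], tolerance = 1e-15)
  }
  expect_error(disaggregate_to_hourly(met1), class = "pondcast_error_step")
})

test_that("shortwave-to-PAR conversion is linear, monotone and exact at anchors", {
  expect_identical(shortwave_to_par(0), 0)
  expect_equal(shortwave_to_par(1000), 2056.5)
  expect_equal(shortwave_to_par(100), 205.65)
  x <- seq(0, 1200, by = 50)
  expect_equal(shortwave_to_par(2 * x), 2 * shortwave_to_par(x))
  expect_true(all(diff(shortwave_to_par(x)) > 0))
  expect_equal(shortwave_to_par(1000, f_par = 0.5, q = 4), 2000)
  expect_error(shortwave_to_par(-1), class = "pondcast_error_domain")
})

test_that("NetCDF ingestion maps CF-style variables onto the canonical schema", {
  skip_if_not_installed("ncdf4")
  met <- mesa_truth(1)
  f <- withr::local_tempfile(fileext = ".nc")
  dim_t <- ncdf4::ncdim_def("time", "hours since 2013-06-01 07:00:00",
                            0:(nrow(met) - 1))
  vars <- list(
    ncdf4::ncvar_def("dswrf", "W m-2", dim_t),
    ncdf4::ncvar_def("t2m", "degC", dim_t),
    ncdf4::ncvar_def("d2m", "degC", dim_t),
    ncdf4::ncvar_def("si10", "m s-1", dim_t),
    ncdf4::ncvar_def("sp", "kPa", dim_t)
  )
  nc <- ncdf4::nc_create(f, vars)
  ncdf4::ncvar_put(nc, "dswrf", met$shortwave)
  ncdf4::ncvar_put(nc, "t2m", met$air_temp)
  ncdf4::ncvar_put(nc, "d2m", met$dewpoint)
  ncdf4::ncvar_put(nc, "si10", met$wind)
  ncdf4::ncvar_put(nc, "sp", met$pressure)
  ncdf4::nc_close(nc)
  back <- read_meteo_table(f, dialect = c(shortwave = "dswrf", air_temp = "t2m",
                                          dewpoint = "d2m", wind = "si10",
                                          pressure = "sp"))
  expect_equal(back$shortwave, met$shortwave, tolerance = 1e-6)
  expect_equal(as.numeric(back$time), as.numeric(met$time))
  expect_equal(back$par, shortwave_to_par(back$shortwave))
})

test_that("ensemble containers enforce shared timestamps and expose members", {
  met <- mesa_truth(1)
  fc <- ensemble_forecast(list(met, met))
  expect_equal(n_members(fc), 2L)
  expect_equal(length(forecast_members(fc)), 2L)
  expect_equal(forecast_members(fc)[[2]]$par, met$par)

  shifted <- met
  shifted$time <- shifted$time + 3600
  expect_error(ensemble_forecast(list(met, shifted)),
               class = "pondcast_error_alignment")
  expect_error(ensemble_forecast(list()), class = "pondcast_error_domain")
})
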