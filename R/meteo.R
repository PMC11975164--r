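#' Meteorological forcing series
#'
#' A meteorological series is an hourly (or 3-hourly) tibble of surface
#' weather used to force the pond thermal and growth models. Canonical
#' columns and units:
#'
#' * `time` — POSIXct, UTC, strictly increasing at a fixed step
#' * `shortwave` — downwelling shortwave radiation, W m-2
#' * `par` — photosynthetically active radiation, umol m-2 s-1
#' * `air_temp` — air temperature, degC
#' * `dewpoint` — dew-point temperature, degC (never above `air_temp`)
#' * `wind` — wind speed, m s-1
#' * `pressure` — air pressure, kPa
#'
#' `validate_meteo()` checks the schema and the physical invariants and
#' returns its input invisibly; readers and generators call it on the way
#' out, model entry points call it on the way in.
#'
#' @param met A data frame with the columns above.
#' @return `validate_meteo()` returns `met` invisibly (as a tibble).
#'   `meteo_step_hours()` returns the step size in hours (1 or 3).
#' @examples
#' met <- generate_truth_weather(weather_config(n_days = 2, seed = 1))
#' validate_meteo(met)
#' meteo_step_hours(met)
#' @export
validate_meteo <- function(met) {
  required <- c("time", "shortwave", "par", "air_temp", "dewpoint",
                "wind", "pressure")
  missing <- setdiff(required, names(met))
  if (length(missing) > 0L) {
    stop_pondcast(
      sprintf("meteorological table is missing column(s): %s",
              paste(missing, collapse = ", ")),
      class = "schema"
    )
  }
  met <- as_tibble(met)
  if (!inherits(met$time, "POSIXct")) {
    stop_pondcast("`time` must be POSIXct (UTC)", class = "schema")
  }
  if (nrow(met) >= 2L) {
    dt <- as.numeric(diff(met$time), units = "hours")
    if (any(dt <= 0)) {
      stop_pondcast(
        sprintf("timestamps must be strictly increasing; first violation after %s",
                format(met$time[which(dt <= 0)[1]], tz = "UTC")),
        class = "ordering"
      )
    }
    step <- dt[1]
    if (any(abs(dt - step) > 1e-6)) {
      bad <- which(abs(dt - step) > 1e-6)[1]
      stop_pondcast(
        sprintf("gap in time steps: expected %g h step, first offending instant %s",
                step, format(met$time[bad + 1L], tz = "UTC")),
        class = "gap"
      )
    }
    if (!isTRUE(all.equal(step, 1)) && !isTRUE(all.equal(step, 3))) {
      stop_pondcast(sprintf("unsupported time step: %g h (expected 1 h or 3 h)", step),
                    class = "step")
    }
  }
  check_nonneg <- function(col) {
    bad <- which(!is.finite(met[[col]]) | met[[col]] < 0)
    if (length(bad) > 0L) {
      stop_pondcast(sprintf("`%s` must be finite and >= 0; first violation at row %d",
                            col, bad[1]), class = "invariant")
    }
  }
  check_nonneg("shortwave"); check_nonneg("par"); check_nonneg("wind")
  for (col in c("air_temp", "dewpoint", "pressure")) {
    if (any(!is.finite(met[[col]]))) {
      stop_pondcast(sprintf("`%s` contains non-finite values", col), class = "invariant")
    }
  }
  bad <- which(met$dewpoint > met$air_temp + 1e-9)
  if (length(bad) > 0L) {
    stop_pondcast(
      sprintf("dewpoint exceeds air temperature at row %d (%s)",
              bad[1], format(met$time[bad[1]], tz = "UTC")),
      class = "invariant"
    )
  }
  invisible(met)
}

#' @rdname validate_meteo
#' @export
meteo_step_hours <- function(met) {
  if (nrow(met) < 2L) return(1)
  round(as.numeric(met$time[2] - met$time[1], units = "hours"), 6)
}

#' Read and write meteorological forcing tables
#'
#' `read_meteo_table()` reads a delimited (CSV) or NetCDF file into the
#' canonical meteorological tibble (see [validate_meteo()]), renaming
#' columns through `dialect`, converting units, deriving `par` from
#' `shortwave` when absent, and validating the result. `write_meteo_table()`
#' writes the canonical CSV form; a read/write round trip preserves all
#' values exactly.
#'
#' @param path File path. Files ending in `.nc` are read with the ncdf4
#'   package (CF-style `time` units attribute, variables named through the
#'   same `dialect` mapping); anything else is read as delimited text with a
#'   header row and ISO-8601 timestamps.
#' @param dialect Named character vector mapping canonical names to the
#'   names used in the file, e.g. `c(shortwave = "dswrf", air_temp = "t2m")`.
#'   Unmapped canonical names are looked up as-is.
#' @param units List of source units to convert from:
#'   `temperature` one of `"degC"` (default) or `"K"` (applied to `air_temp`
#'   and `dewpoint`), `pressure` one of `"kPa"` (default), `"hPa"`, `"Pa"`.
#' @param f_par,q Passed to [shortwave_to_par()] when `par` must be derived.
#' @param met A validated meteorological tibble.
#' @return A validated meteorological tibble; `write_meteo_table()` returns
#'   `met` invisibly.
#' @examples
#' met <- generate_truth_weather(weather_config(n_days = 1, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_meteo_table(met, f)
#' identical_back <- read_meteo_table(f)
#' all.equal(met$par, identical_back$par)
#' @export
read_meteo_table <- function(path, dialect = NULL,
                             units = list(temperature = "degC", pressure = "kPa"),
                             f_par = 0.45, q = 4.57) {
  if (!file.exists(path)) {
    stop_pondcast(sprintf("file does not exist: %s", path), class = "io")
  }
  if (grepl("\\.nc$", path, ignore.case = TRUE)) {
    raw <- read_meteo_netcdf(path, dialect)
  } else {
    # base parser: correctly rounded doubles, so written tables read back
    # bit-for-bit
    raw <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    raw <- rename_dialect(raw, dialect)
    if (!"time" %in% names(raw)) {
      stop_pondcast("meteorological table is missing column(s): time", class = "schema")
    }
    if (!inherits(raw$time, "POSIXct")) {
      raw$time <- lubridate::ymd_hms(raw$time, tz = "UTC", quiet = TRUE)
      if (any(is.na(raw$time))) {
        stop_pondcast("`time` could not be parsed as ISO-8601", class = "schema")
      }
    }
    attr(raw$time, "tzone") <- "UTC"
  }
  tconv <- match.arg(units$temperature %||% "degC", c("degC", "K"))
  if (tconv == "K") {
    raw$air_temp <- raw$air_temp - 273.15
    raw$dewpoint <- raw$dewpoint - 273.15
  }
  pconv <- match.arg(units$pressure %||% "kPa", c("kPa", "hPa", "Pa"))
  raw$pressure <- switch(pconv, kPa = raw$pressure,
                         hPa = raw$pressure / 10, Pa = raw$pressure / 1000)
  if (!"par" %in% names(raw) && "shortwave" %in% names(raw)) {
    raw$par <- shortwave_to_par(raw$shortwave, f_par = f_par, q = q)
  }
  for (col in setdiff(names(raw), "time")) {
    if (is.integer(raw[[col]])) raw[[col]] <- as.double(raw[[col]])
  }
  met <- validate_meteo(raw)
  canonical <- c("time", "shortwave", "par", "air_temp", "dewpoint",
                 "wind", "pressure")
  met[, c(canonical, setdiff(names(met), canonical))]
}

rename_dialect <- function(df, dialect) {
  if (is.null(dialect)) return(df)
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (!src %in% names(df)) {
      stop_pondcast(sprintf("mapped column `%s` (for `%s`) not found in file",
                            src, canon), class = "schema")
    }
    names(df)[names(df) == src] <- canon
  }
  df
}

read_meteo_netcdf <- function(path, dialect) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop_pondcast("reading NetCDF requires the ncdf4 package", class = "io")
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  name_of <- function(canon) {
    if (!is.null(dialect) && canon %in% names(dialect)) dialect[[canon]] else canon
  }
  tname <- name_of("time")
  tvals <- if (tname %in% names(nc$dim)) nc$dim[[tname]]$vals else ncdf4::ncvar_get(nc, tname)
  tunits <- if (tname %in% names(nc$dim)) nc$dim[[tname]]$units else
    ncdf4::ncatt_get(nc, tname, "units")$value
  time <- parse_cf_time(tvals, tunits)
  vars <- c("shortwave", "par", "air_temp", "dewpoint", "wind", "pressure")
  out <- tibble(time = time)
  for (v in vars) {
    src <- name_of(v)
    if (src %in% names(nc$var)) out[[v]] <- as.numeric(ncdf4::ncvar_get(nc, src))
  }
  out
}

parse_cf_time <- function(vals, units) {
  m <- regmatches(units, regexec("^(seconds|minutes|hours|days) since (.+)$", units))[[1]]
  if (length(m) != 3L) {
    stop_pondcast(sprintf("unsupported CF time units: %s", units), class = "schema")
  }
  origin <- lubridate::ymd_hms(m[3], tz = "UTC", quiet = TRUE)
  if (is.na(origin)) origin <- lubridate::ymd(m[3], tz = "UTC", quiet = TRUE)
  if (is.na(origin)) {
    stop_pondcast(sprintf("cannot parse CF time origin: %s", m[3]), class = "schema")
  }
  mult <- c(seconds = 1, minutes = 60, hours = 3600, days = 86400)[[m[2]]]
  origin + vals * mult
}

#' @rdname read_meteo_table
#' @export
write_meteo_table <- function(met, path) {
  met <- validate_meteo(met)
  # 17 significant digits: doubles survive the text round trip bit-for-bit
  out <- met
  for (col in names(out)) {
    if (is.double(out[[col]]) && !inherits(out[[col]], "POSIXct")) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(met)
}

#' Disaggregate a 3-hourly series to hourly steps
#'
#' Each 3-hour value is replicated onto its three constituent hours (all
#' variables are treated as intensive), so the per-variable mean over every
#' 3-hour block — and over the whole series — is preserved exactly. This is
#' the uniform disaggregation conventionally applied to 3-hourly ensemble
#' forecast archives before driving hourly pond models.
#'
#' @param met A meteorological tibble at a 3 h step.
#' @return A meteorological tibble at a 1 h step with `3 * nrow(met)` rows.
#' @examples
#' met3 <- generate_truth_weather(weather_config(n_days = 1, seed = 1))
#' met3 <- met3[seq(1, 24, by = 3), ]
#' met1 <- disaggregate_to_hourly(met3)
#' nrow(met1)      # 24
#' @export
disaggregate_to_hourly <- function(met) {
  met <- validate_meteo(met)
  step <- meteo_step_hours(met)
  if (!isTRUE(all.equal(step, 3))) {
    stop_pondcast(sprintf("disaggregation expects a 3 h step, got %g h", step),
                  class = "step")
  }
  idx <- rep(seq_len(nrow(met)), each = 3L)
  out <- met[idx, ]
  out$time <- met$time[idx] + rep(c(0, 1, 2), times = nrow(met)) * 3600
  validate_meteo(out)
  out
}

#' Convert shortwave irradiance to photosynthetically active radiation
#'
#' PAR is taken as a fixed fraction `f_par` of broadband shortwave energy,
#' converted from W m-2 to umol photons m-2 s-1 with the quantum conversion
#' factor `q`. The defaults (0.45 and 4.57 umol J-1) are the standard
#' radiometric choices; both are exposed because conversion conventions vary
#' between data sets.
#'
#' @param shortwave Shortwave irradiance, W m-2 (vectorised, must be >= 0).
#' @param f_par PAR fraction of shortwave energy.
#' @param q Quantum conversion, umol photons per joule of PAR.
#' @return PAR in umol m-2 s-1.
#' @examples
#' shortwave_to_par(1000)  # 2056.5
#' @export
shortwave_to_par <- function(shortwave, f_par = 0.45, q = 4.57) {
  if (any(!is.finite(shortwave)) || any(shortwave < 0)) {
    stop_pondcast("`shortwave` must be finite and >= 0", class = "domain")
  }
  shortwave * f_par * q
}

#' Ensemble weather forecast
#'
#' An ensemble forecast bundles `E >= 1` member meteorological series that
#' share an issue time, horizon and timestamps. It is stored in long form: a
#' tibble with a `member` column ahead of the canonical meteorological
#' columns, carrying `issue_time` and `horizon_hours` as attributes.
#'
#' @param members A list of meteorological tibbles with identical timestamps.
#' @param issue_time POSIXct issue instant; defaults to the first timestamp.
#' @param horizon_hours Forecast horizon in hours; defaults to the covered
#'   span.
#' @param fc An `ensemble_forecast` object.
#' @return `ensemble_forecast()` returns an `ensemble_forecast` tibble;
#'   `forecast_members()` the list of per-member meteorological tibbles;
#'   `n_members()` the member count E.
#' @examples
#' truth <- generate_truth_weather(weather_config(n_days = 2, seed = 1))
#' fc <- generate_ensemble_forecast(truth, truth$time[1], 24,
#'                                  forecast_error_config(n_members = 3))
#' n_members(fc)
#' @export
ensemble_forecast <- function(members, issue_time = NULL, horizon_hours = NULL) {
  if (!is.list(members) || length(members) < 1L) {
    stop_pondcast("an ensemble needs at least one member", class = "domain")
  }
  members <- lapply(members, function(m) as_tibble(validate_meteo(m)))
  t0 <- members[[1]]$time
  for (m in members[-1]) {
    if (!identical(as.numeric(m$time), as.numeric(t0))) {
      stop_pondcast("all ensemble members must share timestamps", class = "alignment")
    }
  }
  if (is.null(issue_time)) issue_time <- t0[1]
  if (is.null(horizon_hours)) {
    horizon_hours <- as.numeric(t0[length(t0)] - t0[1], units = "hours") +
      meteo_step_hours(members[[1]])
  }
  out <- bind_rows(lapply(seq_along(members), function(i) {
    mutate(members[[i]], member = i, .before = 1)
  }))
  structure(out,
            issue_time = issue_time,
            horizon_hours = horizon_hours,
            class = c("ensemble_forecast", class(tibble())))
}

#' @rdname ensemble_forecast
#' @export
forecast_members <- function(fc) {
  stopifnot(inherits(fc, "ensemble_forecast"))
  dat <- as_tibble(unclass(fc)[setdiff(names(fc), character(0))])
  lapply(split(seq_len(nrow(dat)), dat$member),
         function(i) dat[i, setdiff(names(dat), "member")])
}

#' @rdname ensemble_forecast
#' @export
n_members <- function(fc) {
  stopifnot(inherits(fc, "ensemble_forecast"))
  length(unique(fc$member))
}
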