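#' Experiment configuration and presets
#'
#' Bundles everything a treatment-comparison experiment needs: the
#' cultivation window, pond initial state, optics/thermal/strain
#' parameters, the synthetic weather and forecast-error configurations,
#' and the named operating policies to compare.
#'
#' Two presets reproduce the canonical designs:
#'
#' * `"short_term"` — 8 operation days in late August; treatments batch,
#'   fixed 60% every 3 days, perfect forecast-informed, ensemble
#'   forecast-informed.
#' * `"long_term"` — a 92-day summer season (June-August); treatments
#'   fixed 60% every 3 days, fixed 20% daily, perfect forecast-informed,
#'   ensemble forecast-informed.
#'
#' @param preset `"custom"`, `"short_term"` or `"long_term"`.
#' @param start_date First experiment date (local).
#' @param n_days Number of daily operation cycles.
#' @param harvest_hour Local hour of the daily operation window.
#' @param utc_offset Local-time offset from UTC, hours.
#' @param pond Named list overriding [pond_state()] arguments.
#' @param optics,thermal Named lists overriding [optics_params()] /
#'   [thermal_params()] arguments.
#' @param strain `"default"` for [default_strain()], or a path readable by
#'   [read_strain_table()].
#' @param weather Named list overriding [weather_config()] arguments
#'   (its `start_date`/`n_days`/`seed` are managed by the experiment).
#' @param forecast Named list overriding [forecast_error_config()]
#'   arguments (its seed is managed by the experiment).
#' @param policies Named list of policies (see [policy_batch()]); `NULL`
#'   takes the preset's treatments.
#' @param grid_n Size of the dilution scenario grid.
#' @param seed Master seed: the weather seed is `seed` and the
#'   forecast-error seed is derived from it, so one integer reproduces the
#'   whole experiment.
#' @param out_dir Optional output directory: [run_experiment()] writes the
#'   resolved configuration, ledgers, decisions and the comparison table
#'   there.
#' @return An `experiment_config` list.
#' @examples
#' cfg <- experiment_config("short_term", seed = 7)
#' names(cfg$policies)
#' @export
experiment_config <- function(preset = c("custom", "short_term", "long_term"),
                              start_date = NULL, n_days = NULL,
                              harvest_hour = 18, utc_offset = -7,
                              pond = list(), optics = list(), thermal = list(),
                              strain = "default", weather = list(),
                              forecast = list(), policies = NULL,
                              grid_n = 100, seed = 1, out_dir = NULL) {
  preset <- match.arg(preset)
  if (preset == "short_term") {
    start_date <- start_date %||% "2013-08-25"
    n_days <- n_days %||% 8
    policies <- policies %||% list(
      batch = policy_batch(harvest_hour),
      fixed_60_3 = policy_fixed(0.6, 3, harvest_hour),
      perfect = policy_forecast("perfect", harvest_hour),
      ensemble = policy_forecast("ensemble", harvest_hour)
    )
  } else if (preset == "long_term") {
    start_date <- start_date %||% "2013-06-01"
    n_days <- n_days %||% 92
    policies <- policies %||% list(
      fixed_60_3 = policy_fixed(0.6, 3, harvest_hour),
      fixed_20_1 = policy_fixed(0.2, 1, harvest_hour),
      perfect = policy_forecast("perfect", harvest_hour),
      ensemble = policy_forecast("ensemble", harvest_hour)
    )
  } else {
    if (is.null(start_date) || is.null(n_days) || is.null(policies)) {
      stop_pondcast(
        "custom experiments must set `start_date`, `n_days` and `policies`",
        class = "config"
      )
    }
  }
  stopifnot(all(vapply(policies, inherits, logical(1), "pond_policy")))
  weather <- utils::modifyList(weather, list(
    start_date = start_date, seed = as.integer(seed)
  ))
  forecast <- utils::modifyList(forecast, list(
    seed = as.integer((as.numeric(seed) + 104729) %% .Machine$integer.max)
  ))
  structure(list(
    preset = preset, start_date = as.Date(start_date),
    n_days = as.integer(n_days), harvest_hour = harvest_hour,
    utc_offset = utc_offset,
    pond = do.call(pond_state, pond),
    optics = do.call(optics_params, optics),
    thermal = do.call(thermal_params, thermal),
    strain = strain,
    weather = do.call(weather_config, weather),
    forecast = do.call(forecast_error_config, forecast),
    policies = policies, grid_n = grid_n, seed = as.integer(seed),
    out_dir = out_dir
  ), class = "experiment_config")
}

#' Load and save experiment configurations as YAML
#'
#' `load_config()` parses a YAML file into an [experiment_config()],
#' rejecting unknown keys; `save_config()` writes the fully resolved
#' configuration back out, and `load_config(save_config(cfg))` is
#' semantically identical to `cfg`.
#'
#' Recognised top-level keys: `preset`, `start_date`, `n_days`,
#' `harvest_hour`, `utc_offset`, `seed`, `grid_n`, `strain`, `out_dir`,
#' and the blocks `pond`, `optics`, `thermal`, `weather`, `forecast`
#' (field names as in the corresponding constructors) and `policies`
#' (named entries with `kind` plus `rate`/`period_days`/`source`).
#'
#' @param path YAML file path.
#' @param cfg An [experiment_config()].
#' @return `load_config()` returns an `experiment_config`; `save_config()`
#'   returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("preset", "start_date", "n_days", "harvest_hour", "utc_offset",
             "pond", "optics", "thermal", "strain", "weather", "forecast",
             "policies", "grid_n", "seed", "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop_pondcast(sprintf("unknown configuration key(s): %s",
                          paste(unknown, collapse = ", ")), class = "config")
  }
  pol_known <- c("kind", "rate", "period_days", "source", "harvest_hour")
  policies <- NULL
  if (!is.null(raw$policies)) {
    policies <- lapply(raw$policies, function(p) {
      bad <- setdiff(names(p), pol_known)
      if (length(bad) > 0L) {
        stop_pondcast(sprintf("unknown policy key(s): %s",
                              paste(bad, collapse = ", ")), class = "config")
      }
      hh <- p$harvest_hour %||% raw$harvest_hour %||% 18
      switch(p$kind %||% stop_pondcast("policy needs a `kind`", class = "config"),
             batch = policy_batch(hh),
             fixed = policy_fixed(p$rate %||% 0.6, p$period_days %||% 3, hh),
             forecast_informed = policy_forecast(p$source %||% "perfect", hh),
             stop_pondcast(sprintf("unknown policy kind: %s", p$kind),
                           class = "config"))
    })
  }
  # drop weather/forecast fields the experiment manages itself
  weather <- raw$weather %||% list()
  weather$start_date <- NULL; weather$seed <- NULL; weather$n_days <- NULL
  forecast <- raw$forecast %||% list()
  forecast$seed <- NULL
  experiment_config(
    preset = raw$preset %||% "custom",
    start_date = raw$start_date, n_days = raw$n_days,
    harvest_hour = raw$harvest_hour %||% 18,
    utc_offset = raw$utc_offset %||% -7,
    pond = raw$pond %||% list(), optics = raw$optics %||% list(),
    thermal = raw$thermal %||% list(), strain = raw$strain %||% "default",
    weather = weather, forecast = forecast, policies = policies,
    grid_n = raw$grid_n %||% 100, seed = raw$seed %||% 1,
    out_dir = raw$out_dir
  )
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  pol <- lapply(cfg$policies, function(p) {
    out <- list(kind = p$kind, harvest_hour = p$harvest_hour)
    if (p$kind == "fixed") {
      out$rate <- p$rate; out$period_days <- p$period_days
    }
    if (p$kind == "forecast_informed") out$source <- p$source
    out
  })
  dump <- list(
    preset = cfg$preset, start_date = format(cfg$start_date),
    n_days = cfg$n_days, harvest_hour = cfg$harvest_hour,
    utc_offset = cfg$utc_offset,
    pond = cfg$pond[c("concentration", "volume", "depth", "water_temp")],
    optics = unclass(cfg$optics),
    thermal = unclass(cfg$thermal),
    strain = cfg$strain,
    weather = unclass(cfg$weather)[setdiff(names(cfg$weather),
                                           c("start_date", "seed", "n_days"))],
    forecast = unclass(cfg$forecast)[setdiff(names(cfg$forecast), "seed")],
    policies = pol, grid_n = cfg$grid_n, seed = cfg$seed
  )
  if (!is.null(cfg$out_dir)) dump$out_dir <- cfg$out_dir
  yaml::write_yaml(dump, path)
  invisible(path)
}

#' Run a treatment-comparison experiment
#'
#' Generates (or loads) the truth weather, runs every configured policy on
#' it with [run_treatment()], and assembles the comparison: per-treatment
#' total harvested biomass, pairwise relative differences to the first and
#' second treatments, weekly production series and — when at least two
#' full weeks are available — a one-way ANOVA across treatments.
#'
#' @param cfg An [experiment_config()].
#' @param truth Optional pre-built hourly truth series (otherwise
#'   generated from `cfg$weather` with one extra day of coverage for the
#'   final decision horizon).
#' @return A `fipo_experiment`: list with `comparison` (tibble
#'   `treatment`, `total_g`, `rel_diff_1`, `rel_diff_2`, %), `runs` (named
#'   list of `pond_run`), `weekly` (tibble `treatment`, `week`,
#'   `production_g`), `anova` (tibble or `NULL`), `truth`, `config`.
#' @examples
#' \donttest{
#' cfg <- experiment_config("short_term", seed = 1)
#' exp <- run_experiment(cfg)
#' exp$comparison
#' }
#' @export
run_experiment <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  wcfg <- cfg$weather
  wcfg$n_days <- cfg$n_days + 2  # cover the final decision horizon
  if (is.null(truth)) truth <- generate_truth_weather(wcfg)

  # run origin: harvest_hour local on start_date; timestamps are UTC
  start <- lubridate::as_datetime(cfg$start_date, tz = "UTC") +
    (cfg$harvest_hour - cfg$utc_offset) * 3600
  strain <- if (identical(cfg$strain, "default")) default_strain()
            else read_strain_table(cfg$strain)
  grid <- scenario_grid(cfg$grid_n)

  runs <- lapply(cfg$policies, function(pol) {
    forecasts <- if (pol$kind == "forecast_informed" &&
                     identical(pol$source, "ensemble")) cfg$forecast else NULL
    run_treatment(truth, pol, cfg$n_days, pond = cfg$pond, strain = strain,
                  optics = cfg$optics, tparams = cfg$thermal, start = start,
                  forecasts = forecasts, grid = grid)
  })

  totals <- vapply(runs, function(r) r$total_g, numeric(1))
  comparison <- tibble(
    treatment = names(runs),
    total_g = unname(totals),
    rel_diff_1 = ifelse(seq_along(totals) == 1L, NA_real_,
                        relative_difference(unname(totals), totals[[1]])),
    rel_diff_2 = if (length(totals) >= 2L) {
      ifelse(seq_along(totals) == 2L, NA_real_,
             relative_difference(unname(totals), totals[[2]]))
    } else NA_real_
  )

  weekly <- purrr::map_dfr(names(runs), function(nm) {
    wp <- weekly_production(runs[[nm]])
    if (nrow(wp) > 0L) mutate(wp, treatment = nm, .before = 1) else wp
  })
  anova_tbl <- NULL
  if (nrow(weekly) > 0L && length(unique(weekly$week)) >= 2L &&
      length(runs) >= 2L) {
    anova_tbl <- one_way_anova(split(weekly$production_g, weekly$treatment))
  }

  result <- structure(list(
    comparison = comparison, runs = runs, weekly = weekly,
    anova = anova_tbl, truth = truth, config = cfg
  ), class = "fipo_experiment")
  if (!is.null(cfg$out_dir)) write_experiment(result, cfg$out_dir)
  result
}

#' @export
print.fipo_experiment <- function(x, ...) {
  cat(sprintf("<fipo_experiment> %s: %d treatments over %d day(s)\n",
              x$config$preset, length(x$runs), x$config$n_days))
  cmp <- x$comparison
  cmp$rel_diff_1 <- sprintf("%.1f%%", cmp$rel_diff_1)
  cmp$rel_diff_2 <- sprintf("%.1f%%", cmp$rel_diff_2)
  cmp$total_g <- sprintf("%.2f", cmp$total_g)
  print(as.data.frame(cmp), row.names = FALSE)
  if (!is.null(x$anova)) {
    cat(sprintf("weekly-production ANOVA: F = %.2f, p = %.3f\n",
                x$anova$f_statistic, x$anova$p_value))
  }
  invisible(x)
}

# write resolved config + all CSV outputs for reproducibility
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_config(result$config, file.path(out_dir, "config.yaml"))
  readr::write_csv(result$comparison, file.path(out_dir, "comparison.csv"),
                   progress = FALSE)
  for (nm in names(result$runs)) {
    run <- result$runs[[nm]]
    readr::write_csv(run$ledger, file.path(out_dir, paste0("ledger_", nm, ".csv")),
                     progress = FALSE)
    if (length(run$decisions) > 0L) {
      dec <- purrr::map_dfr(run$decisions, function(d) {
        wide <- setNames(as.list(d$objective$objective_g),
                         sprintf("rate_%02.0f", 100 * d$objective$rate))
        tibble(time = d$time, chosen_rate = d$chosen_rate, !!!wide)
      })
      readr::write_csv(dec, file.path(out_dir, paste0("decisions_", nm, ".csv")),
                       progress = FALSE)
    }
  }
  invisible(out_dir)
}
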