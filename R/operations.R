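#' Apply a dilution/harvest operation to the pond
#'
#' A dilution at rate `d` removes fraction `d` of the culture (harvesting
#' `d * c * V` grams of biomass) and refills to the working volume and
#' depth with fresh, biomass-free medium at the current pond temperature.
#' The mass balance is exact: `c V = harvested + c' V`.
#'
#' @param state A [pond_state()].
#' @param d Dilution rate, in [0, 0.99].
#' @return A list with `state` (the diluted [pond_state()]) and
#'   `harvested_g` (grams of biomass removed).
#' @examples
#' st <- pond_state(concentration = 1, volume = 800)
#' apply_dilution(st, 0.6)$harvested_g  # 480
#' @export
apply_dilution <- function(state, d) {
  stopifnot(inherits(state, "pond_state"))
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0 || d > 0.99) {
    stop_pondcast("dilution rate must be a single value in [0, 0.99]",
                  class = "domain")
  }
  harvested <- d * state$concentration * state$volume
  state$concentration <- state$concentration * (1 - d)
  list(state = state, harvested_g = harvested)
}

#' Operating policies
#'
#' A policy decides the dilution rate applied at the daily operation
#' window (default 18:00 local):
#'
#' * `policy_batch()` — no operation until the final harvest.
#' * `policy_fixed(rate, period_days)` — dilute by `rate` on every day
#'   whose index is a multiple of `period_days` (e.g. 60% every 3 days, or
#'   20% daily).
#' * `policy_forecast(source)` — forecast-informed: the daily rate comes
#'   from [choose_dilution()] run against either a perfect forecast (the
#'   truth weather itself, `source = "perfect"`) or a synthetic NWP-style
#'   ensemble (`source = "ensemble"`).
#'
#' @param rate Dilution rate in [0, 0.99].
#' @param period_days Days between dilutions (>= 1).
#' @param source `"perfect"` or `"ensemble"` forecast source.
#' @param harvest_hour Local hour of the daily operation window.
#' @return A `pond_policy` list with fields `kind`
#'   (`"batch" | "fixed" | "forecast_informed"`), `rate`, `period_days`,
#'   `source`, `harvest_hour`.
#' @export
policy_batch <- function(harvest_hour = 18) {
  new_policy("batch", rate = 0, period_days = Inf, harvest_hour = harvest_hour)
}

#' @rdname policy_batch
#' @export
policy_fixed <- function(rate = 0.6, period_days = 3, harvest_hour = 18) {
  if (rate < 0 || rate > 0.99) {
    stop_pondcast("policy rate must lie in [0, 0.99]", class = "domain")
  }
  check_number(period_days, "period_days", 1)
  new_policy("fixed", rate = rate, period_days = period_days,
             harvest_hour = harvest_hour)
}

#' @rdname policy_batch
#' @export
policy_forecast <- function(source = c("perfect", "ensemble"),
                            harvest_hour = 18) {
  source <- match.arg(source)
  new_policy("forecast_informed", rate = NA_real_, period_days = 1,
             source = source, harvest_hour = harvest_hour)
}

new_policy <- function(kind, rate, period_days, source = NA_character_,
                       harvest_hour = 18) {
  structure(list(kind = kind, rate = rate, period_days = period_days,
                 source = source, harvest_hour = harvest_hour),
            class = "pond_policy")
}

#' @export
print.pond_policy <- function(x, ...) {
  desc <- switch(x$kind,
                 batch = "batch (no operation until final harvest)",
                 fixed = sprintf("fixed %.0f%% every %g day(s)",
                                 100 * x$rate, x$period_days),
                 forecast_informed = sprintf("forecast-informed (%s)", x$source))
  cat(sprintf("<pond_policy> %s, operation at %02d:00 local\n",
              desc, x$harvest_hour))
  invisible(x)
}

#' Scheduled dilution rate of a policy on a given day
#'
#' Pure schedule lookup: batch policies never dilute; fixed policies dilute
#' on days where `day_index %% period_days == 0`; forecast-informed
#' policies return `NA` because their rate is decided at run time by
#' [choose_dilution()].
#'
#' @param policy A policy (see [policy_batch()]).
#' @param day_index Operation day counter starting at 1.
#' @return The dilution rate, or `NA_real_` for forecast-informed policies.
#' @examples
#' sapply(1:9, function(k) scheduled_rate(policy_fixed(0.6, 3), k))
#' @export
scheduled_rate <- function(policy, day_index) {
  stopifnot(inherits(policy, "pond_policy"))
  if (any(day_index < 1)) {
    stop_pondcast("`day_index` starts at 1", class = "domain")
  }
  switch(policy$kind,
         batch = rep(0, length(day_index)),
         fixed = ifelse(day_index %% policy$period_days == 0, policy$rate, 0),
         forecast_informed = rep(NA_real_, length(day_index)))
}

# ledger construction -------------------------------------------------------

empty_ledger <- function() {
  tibble(time = as.POSIXct(character(), tz = "UTC"), day = integer(),
         rate = numeric(), conc_before = numeric(), conc_after = numeric(),
         harvested_g = numeric(), kind = character())
}

ledger_row <- function(time, day, rate, conc_before, conc_after,
                       harvested_g, kind) {
  tibble(time = time, day = as.integer(day), rate = rate,
         conc_before = conc_before, conc_after = conc_after,
         harvested_g = harvested_g, kind = kind)
}

#' Close out an experiment by harvesting the standing biomass
#'
#' Appends a terminal event harvesting the remaining standing biomass
#' `c * V` to the ledger, so that batch totals (where all biomass is
#' standing at the end) are directly comparable with semi-continuous
#' totals.
#'
#' @param state The final [pond_state()].
#' @param ledger A harvest ledger tibble (see [run_treatment()]).
#' @return The ledger with the terminal event appended.
#' @export
finalize_experiment <- function(state, ledger) {
  stopifnot(inherits(state, "pond_state"))
  day <- if (nrow(ledger) > 0L) max(ledger$day) else 0L
  bind_rows(ledger, ledger_row(
    time = state$clock, day = day, rate = NA_real_,
    conc_before = state$concentration, conc_after = 0,
    harvested_g = state$concentration * state$volume, kind = "terminal"))
}

#' Total harvested biomass of a ledger
#'
#' @param ledger A harvest ledger tibble.
#' @return Total grams over all events.
#' @export
ledger_total <- function(ledger) {
  sum(ledger$harvested_g)
}
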