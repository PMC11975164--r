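#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects.
#'
#' * `tidy(pond_run)` — the harvest ledger, one row per event.
#' * `glance(pond_run)` — one row: total harvest, event count, final
#'   concentration.
#' * `tidy(fipo_decision)` — the rate-by-objective table.
#' * `glance(fipo_decision)` — one row: decision time, chosen rate,
#'   members, simulation count.
#' * `tidy(fipo_experiment)` — the treatment comparison table.
#' * `glance(fipo_experiment)` — one row: treatment count, best treatment
#'   and total, weekly-production ANOVA F and p (NA when not computed).
#'
#' @param x A `pond_run`, `fipo_decision` or `fipo_experiment`.
#' @param ... Unused.
#' @return A tibble.
#' @name pondcast-tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname pondcast-tidiers
#' @export
tidy.pond_run <- function(x, ...) {
  x$ledger
}

#' @rdname pondcast-tidiers
#' @export
glance.pond_run <- function(x, ...) {
  tibble(
    policy = x$policy$kind,
    n_days = x$n_days,
    n_events = sum(x$ledger$kind != "terminal"),
    total_g = x$total_g,
    final_concentration =
      x$trajectory$concentration[nrow(x$trajectory)]
  )
}

#' @rdname pondcast-tidiers
#' @export
tidy.fipo_decision <- function(x, ...) {
  x$objective
}

#' @rdname pondcast-tidiers
#' @export
glance.fipo_decision <- function(x, ...) {
  tibble(time = x$time, chosen_rate = x$chosen_rate,
         n_members = x$n_members, n_simulations = x$n_simulations)
}

#' @rdname pondcast-tidiers
#' @export
tidy.fipo_experiment <- function(x, ...) {
  x$comparison
}

#' @rdname pondcast-tidiers
#' @export
glance.fipo_experiment <- function(x, ...) {
  best <- which.max(x$comparison$total_g)
  tibble(
    n_treatments = nrow(x$comparison),
    n_days = x$config$n_days,
    best_treatment = x$comparison$treatment[best],
    best_total_g = x$comparison$total_g[best],
    f_statistic = if (is.null(x$anova)) NA_real_ else x$anova$f_statistic,
    p_value = if (is.null(x$anova)) NA_real_ else x$anova$p_value
  )
}
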