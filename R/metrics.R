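#' Nash-Sutcliffe efficiency
#'
#' `NSE = 1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)`, in
#' `(-Inf, 1]`: 1 is a perfect fit; values at or below 0 mean the observed
#' mean predicts no worse than the model.
#'
#' @param observed Numeric vector of observations (length >= 2, not all
#'   identical).
#' @param simulated Numeric vector of simulations, same length.
#' @return The efficiency, a single number.
#' @examples
#' nse(c(1, 2, 3), c(1, 2, 3))  # 1
#' nse(c(1, 2, 3), rep(2, 3))   # 0
#' nse(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
nse <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    stop_pondcast("`observed` and `simulated` must have equal length",
                  class = "domain")
  }
  if (length(observed) < 2L) {
    stop_pondcast("need at least 2 paired values", class = "domain")
  }
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) {
    stop_pondcast("NSE is undefined for a constant observed series",
                  class = "undefined_metric")
  }
  1 - sum((observed - simulated)^2) / denom
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within mean-square
#' ratio), fitted with [stats::aov()]. When the within-group variance is
#' exactly zero but group means differ, the F statistic is reported as
#' `Inf` with `p = 0` and a warning rather than failing.
#'
#' @param groups A list of >= 2 numeric vectors, each of length >= 2.
#' @return A one-row tibble: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))  # F = 1.5
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_pondcast("need at least 2 groups", class = "domain")
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop_pondcast("each group needs at least 2 values", class = "domain")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  ms_within <- sum(tapply(values, labels, function(x) sum((x - mean(x))^2))) / df_w
  if (ms_within == 0) {
    means <- tapply(values, labels, mean)
    if (max(means) - min(means) > 0) {
      warn("zero within-group variance with unequal means: F is infinite")
      return(tibble(f_statistic = Inf, p_value = 0,
                    df_between = df_b, df_within = df_w))
    }
    return(tibble(f_statistic = 0, p_value = 1,
                  df_between = df_b, df_within = df_w))
  }
  fit <- stats::anova(stats::aov(values ~ labels))
  tibble(f_statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
         df_between = fit$Df[1], df_within = fit$Df[2])
}

#' Relative difference in percent
#'
#' `100 * (a - b) / b`, the form used in treatment-comparison tables
#' ("relative difference to treatment b"). Vectorised over `a`.
#'
#' @param a Value(s) to compare, g.
#' @param b Positive reference value, g.
#' @return Percent difference(s).
#' @examples
#' relative_difference(701.04, 576.03)  # 21.7
#' @export
relative_difference <- function(a, b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop_pondcast("reference value `b` must be a single positive number",
                  class = "domain")
  }
  100 * (a - b) / b
}

#' Weekly harvested production from a ledger
#'
#' Sums harvested biomass over consecutive 7-day blocks of operation days
#' (days 1-7, 8-14, ...). The trailing partial week is dropped, and the
#' terminal standing-biomass event is excluded — it is stock at the end of
#' the run, not production within a week.
#'
#' @param x A `pond_run` (from [run_treatment()]) or a ledger tibble.
#' @param n_days Total operation days (required when `x` is a bare
#'   ledger; taken from the run otherwise).
#' @param ... Unused.
#' @return A tibble `week`, `production_g`, one row per complete week
#'   (possibly zero rows).
#' @export
weekly_production <- function(x, ...) {
  UseMethod("weekly_production")
}

#' @rdname weekly_production
#' @export
weekly_production.pond_run <- function(x, ...) {
  weekly_production(x$ledger, n_days = x$n_days)
}

#' @rdname weekly_production
#' @export
weekly_production.data.frame <- function(x, n_days, ...) {
  check_number(n_days, "n_days", 0)
  n_weeks <- floor(n_days / 7)
  if (n_weeks < 1L) {
    return(tibble(week = integer(), production_g = numeric()))
  }
  events <- x[x$kind != "terminal" & x$day <= 7 * n_weeks, ]
  week <- seq_len(n_weeks)
  prod <- vapply(week, function(w) {
    sum(events$harvested_g[events$day > 7 * (w - 1) & events$day <= 7 * w])
  }, numeric(1))
  tibble(week = as.integer(week), production_g = prod)
}
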