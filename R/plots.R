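#' Plot a cultivation run
#'
#' Biomass concentration against time; each harvest operation appears as a
#' vertical drop.
#'
#' @param object A `pond_run` from [run_treatment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pond_run <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$time, y = .data$concentration)) +
    ggplot2::geom_line(colour = "#1b7837") +
    ggplot2::labs(x = NULL, y = "biomass (g AFDW/L)",
                  title = sprintf("%s cultivation, %.1f g harvested",
                                  object$policy$kind, object$total_g)) +
    ggplot2::theme_minimal()
}

#' Plot a daily dilution decision
#'
#' The ensemble-mean production objective across the dilution-rate grid,
#' the per-member objectives, and the chosen rate.
#'
#' @param object A `fipo_decision` from [choose_dilution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fipo_decision <- function(object, ...) {
  members <- as_tibble(as.data.frame(t(object$member_objectives)))
  members$rate <- object$objective$rate
  long <- tidyr::pivot_longer(members, -"rate",
                              names_to = "member", values_to = "objective_g")
  ggplot2::ggplot(object$objective,
                  ggplot2::aes(x = .data$rate, y = .data$objective_g)) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(group = .data$member),
                       colour = "grey75", linewidth = 0.3) +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$chosen_rate,
                        linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(x = "dilution rate", y = "predicted production (g)",
                  title = sprintf("decision %s: d = %.2f",
                                  format(object$time, "%Y-%m-%d"),
                                  object$chosen_rate)) +
    ggplot2::theme_minimal()
}

#' Plot a treatment-comparison experiment
#'
#' Biomass trajectories of all treatments, faceted, with harvests visible
#' as drops.
#'
#' @param object A `fipo_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fipo_experiment <- function(object, ...) {
  traj <- purrr::map_dfr(names(object$runs), function(nm) {
    mutate(object$runs[[nm]]$trajectory, treatment = nm, .before = 1)
  })
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$concentration)) +
    ggplot2::geom_line(colour = "#1b7837") +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = NULL, y = "biomass (g AFDW/L)") +
    ggplot2::theme_minimal()
}

#' Plot meteorological forcing
#'
#' PAR and air temperature panels of a meteorological series.
#'
#' @param met A meteorological tibble (see [validate_meteo()]).
#' @return A ggplot.
#' @export
plot_meteo <- function(met) {
  met <- validate_meteo(met)
  long <- tidyr::pivot_longer(
    met[, c("time", "par", "air_temp")], -"time",
    names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, c("par", "air_temp"),
                          c("PAR (umol/m2/s)", "air temperature (degC)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
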