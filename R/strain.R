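#' Strain growth and dark-loss rate surfaces
#'
#' A strain response holds tabulated specific growth rate and dark-loss
#' (respiration) rate, both in d-1, over a (temperature x irradiance) grid,
#' plus the light compensation threshold below which a culture layer is
#' classed as dark. Rates between grid nodes are obtained by clamped
#' bilinear interpolation ([interp_rate()]); in the field these tables come
#' from laboratory growth experiments at matrices of temperature and light
#' levels.
#'
#' @param temp_grid Strictly ascending temperatures, degC (>= 2 values).
#' @param light_grid Strictly ascending irradiances, umol m-2 s-1 (>= 2
#'   values).
#' @param growth_rate Numeric matrix `length(temp_grid)` x
#'   `length(light_grid)`, d-1 (finite).
#' @param dark_loss Matrix of the same shape, d-1 (>= 0). Strains whose
#'   respiration depends only on temperature simply tabulate columns of a
#'   constant value.
#' @param compensation_light Irradiance threshold, umol m-2 s-1: layers at
#'   or above it grow, layers below it respire.
#' @return A `strain_response` object.
#' @seealso [default_strain()], [read_strain_table()]
#' @export
strain_response <- function(temp_grid, light_grid, growth_rate, dark_loss,
                            compensation_light = 10) {
  if (length(temp_grid) < 2L || any(diff(temp_grid) <= 0)) {
    stop_pondcast("`temp_grid` must be strictly ascending with >= 2 values",
                  class = "domain")
  }
  if (length(light_grid) < 2L || any(diff(light_grid) <= 0)) {
    stop_pondcast("`light_grid` must be strictly ascending with >= 2 values",
                  class = "domain")
  }
  growth_rate <- as.matrix(growth_rate)
  dark_loss <- as.matrix(dark_loss)
  dims <- c(length(temp_grid), length(light_grid))
  if (!all(dim(growth_rate) == dims) || !all(dim(dark_loss) == dims)) {
    stop_pondcast("rate tables must be length(temp_grid) x length(light_grid)",
                  class = "domain")
  }
  if (any(!is.finite(growth_rate))) {
    stop_pondcast("`growth_rate` must be finite", class = "domain")
  }
  if (any(!is.finite(dark_loss)) || any(dark_loss < 0)) {
    stop_pondcast("`dark_loss` must be finite and >= 0", class = "domain")
  }
  check_number(compensation_light, "compensation_light", 0)
  structure(list(temp_grid = as.numeric(temp_grid),
                 light_grid = as.numeric(light_grid),
                 growth_rate = unname(growth_rate),
                 dark_loss = unname(dark_loss),
                 compensation_light = compensation_light),
            class = "strain_response")
}

#' @export
print.strain_response <- function(x, ...) {
  cat(sprintf(
    "<strain_response> %d temps (%.1f-%.1f degC) x %d light levels (%.0f-%.0f umol/m2/s)\n",
    length(x$temp_grid), min(x$temp_grid), max(x$temp_grid),
    length(x$light_grid), min(x$light_grid), max(x$light_grid)))
  cat(sprintf("  growth rate: %.2f to %.2f /d; dark loss: %.3f to %.3f /d; compensation light %.0f\n",
              min(x$growth_rate), max(x$growth_rate),
              min(x$dark_loss), max(x$dark_loss), x$compensation_light))
  invisible(x)
}

#' Built-in synthetic strain response surface
#'
#' A parametric stand-in for a laboratory-derived rate table of a
#' fast-growing thermotolerant chlorophyte (a *Chlorella sorokiniana*-like
#' ideotype), sampled onto a (temperature x irradiance) grid so that
#' downstream code exercises the same interpolation path as a measured
#' table. All constants are invented defaults, not measurements:
#'
#' * temperature factor: cardinal temperature model with inflexion (CTMI)
#'   with `t_min`, `t_opt`, `t_max`;
#' * light factor: Monod saturation `I / (I + k_light)`;
#' * dark loss: `dark_loss_ref * q10 ^ ((T - 20) / 10)`, light-independent.
#'
#' @param temp_grid,light_grid Grid nodes to sample onto.
#' @param mu_max Maximum specific growth rate at `t_opt` under saturating
#'   light, d-1.
#' @param t_min,t_opt,t_max Cardinal temperatures, degC.
#' @param k_light Light half-saturation, umol m-2 s-1.
#' @param dark_loss_ref Dark loss at 20 degC, d-1.
#' @param q10 Temperature sensitivity of dark loss.
#' @param compensation_light Passed to [strain_response()].
#' @return A [strain_response()].
#' @examples
#' st <- default_strain()
#' interp_rate(st, 30, 500)
#' @export
default_strain <- function(temp_grid = seq(0, 45, by = 2.5),
                           light_grid = c(0, 10, 20, 40, 80, 160, 320,
                                          640, 1280, 2560),
                           mu_max = 3.0, t_min = 5, t_opt = 36, t_max = 42,
                           k_light = 120, dark_loss_ref = 0.08, q10 = 2,
                           compensation_light = 10) {
  tf <- ctmi_factor(temp_grid, t_min, t_opt, t_max)
  lf <- light_grid / (light_grid + k_light)
  growth <- mu_max * outer(tf, lf)
  dark <- matrix(dark_loss_ref * q10^((temp_grid - 20) / 10),
                 nrow = length(temp_grid), ncol = length(light_grid))
  strain_response(temp_grid, light_grid, growth, dark,
                  compensation_light = compensation_light)
}

# cardinal temperature model with inflexion (Rosso), in [0, 1]
ctmi_factor <- function(temp, t_min, t_opt, t_max) {
  num <- (temp - t_max) * (temp - t_min)^2
  den <- (t_opt - t_min) *
    ((t_opt - t_min) * (temp - t_opt) - (t_opt - t_max) * (t_opt + t_min - 2 * temp))
  out <- ifelse(temp > t_min & temp < t_max & abs(den) > 0, num / den, 0)
  pmax(0, pmin(1, out))
}

#' Read and write strain parameter tables
#'
#' The on-disk form is a long delimited table with a header row and columns
#' `temperature` (degC), `light` (umol m-2 s-1), `growth_rate` (d-1),
#' `dark_loss` (d-1), one row per grid node; `#`-prefixed comment lines
#' (e.g. unit notes) are ignored. The compensation-light threshold is
#' carried in a `compensation_light` column (constant) if present.
#'
#' @param path File path.
#' @param strain A [strain_response()].
#' @param compensation_light Override for files without the column.
#' @return `read_strain_table()` returns a [strain_response()];
#'   `write_strain_table()` returns `strain` invisibly.
#' @export
read_strain_table <- function(path, compensation_light = NULL) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("temperature", "light", "growth_rate", "dark_loss")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_pondcast(sprintf("strain table is missing column(s): %s",
                          paste(missing, collapse = ", ")), class = "schema")
  }
  tg <- sort(unique(df$temperature))
  lg <- sort(unique(df$light))
  if (nrow(df) != length(tg) * length(lg)) {
    stop_pondcast("strain table must be a complete temperature x light grid",
                  class = "schema")
  }
  key <- function(t, l) match(paste(t, l), paste(df$temperature, df$light))
  idx <- outer(tg, lg, key)
  cl <- compensation_light %||%
    (if ("compensation_light" %in% names(df)) df$compensation_light[1] else 10)
  strain_response(tg, lg,
                  matrix(df$growth_rate[idx], nrow = length(tg)),
                  matrix(df$dark_loss[idx], nrow = length(tg)),
                  compensation_light = cl)
}

#' @rdname read_strain_table
#' @export
write_strain_table <- function(strain, path) {
  stopifnot(inherits(strain, "strain_response"))
  grid <- tidyr::expand_grid(temperature = strain$temp_grid,
                             light = strain$light_grid)
  ti <- match(grid$temperature, strain$temp_grid)
  li <- match(grid$light, strain$light_grid)
  grid$growth_rate <- strain$growth_rate[cbind(ti, li)]
  grid$dark_loss <- strain$dark_loss[cbind(ti, li)]
  grid$compensation_light <- strain$compensation_light
  header <- paste0(
    "# strain response surface: temperature degC, light umol/m2/s, ",
    "growth_rate and dark_loss 1/d\n")
  writeLines(sub("\n$", "", header), path)
  readr::write_csv(grid, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(strain)
}

#' Interpolate a strain rate surface
#'
#' Clamped bilinear interpolation: exact at grid nodes, bilinear inside
#' cells, and clamped to the nearest edge value outside the tabulated
#' range (queries never extrapolate).
#'
#' @param strain A [strain_response()].
#' @param temp Temperature query, degC (vectorised).
#' @param light Irradiance query, umol m-2 s-1 (vectorised, recycled
#'   against `temp`).
#' @param what `"growth"` or `"dark_loss"`.
#' @return Interpolated rate(s), d-1.
#' @examples
#' st <- default_strain()
#' interp_rate(st, st$temp_grid[5], st$light_grid[4])  # exact node value
#' @export
interp_rate <- function(strain, temp, light, what = c("growth", "dark_loss")) {
  what <- match.arg(what)
  if (any(!is.finite(temp)) || any(!is.finite(light))) {
    stop_pondcast("`temp` and `light` must be finite", class = "domain")
  }
  z <- if (what == "growth") strain$growth_rate else strain$dark_loss
  bilinear_clamp(strain$temp_grid, strain$light_grid, z, temp, light)
}

# clamped bilinear interpolation on an ascending rectilinear grid
bilinear_clamp <- function(xg, yg, z, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  i <- pmin(pmax(findInterval(x, xg), 1L), length(xg) - 1L)
  j <- pmin(pmax(findInterval(y, yg), 1L), length(yg) - 1L)
  tx <- pmin(pmax((x - xg[i]) / (xg[i + 1L] - xg[i]), 0), 1)
  ty <- pmin(pmax((y - yg[j]) / (yg[j + 1L] - yg[j]), 0), 1)
  (1 - tx) * (1 - ty) * z[cbind(i, j)] +
    tx * (1 - ty) * z[cbind(i + 1L, j)] +
    (1 - tx) * ty * z[cbind(i, j + 1L)] +
    tx * ty * z[cbind(i + 1L, j + 1L)]
}
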