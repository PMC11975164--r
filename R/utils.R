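# internal helpers shared across modules

stop_pondcast <- function(message, class, ...) {
  abort(message, class = c(paste0("pondcast_error_", class), "pondcast_error"), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)) ||
      x < min || x > max) {
    stop_pondcast(
      sprintf("`%s` must be a single number in [%s, %s], got %s",
              name, format(min), format(max), paste(format(x), collapse = ", ")),
      class = "domain"
    )
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps generators reproducible without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Stationary AR(1) process: lag-1 coefficient `phi`, marginal sd `sd`.
# sd = 0 returns exact zeros so degenerate configurations stay bit-exact.
ar1_series <- function(n, phi, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  if (n > 1L) {
    e <- rnorm(n - 1L, 0, innov_sd)
    for (t in 2:n) x[t] <- phi * x[t - 1L] + e[t - 1L]
  }
  x
}

# Magnus saturation vapor pressure over water, kPa, T in degC
saturation_vapor_pressure <- function(temp_c) {
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}
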