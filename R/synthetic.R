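#' Configuration for the synthetic multi-station panel generator
#'
#' The generator emulates the structure that motivates joint multi-indicator
#' forecasting: at each station, a latent AR(1) water-condition factor drives
#' all four indicators through per-indicator loadings, on top of
#' indicator-specific AR(1) dynamics, annual seasonality and observation
#' noise.  Cross-indicator correlation is therefore tunable through the
#' loadings and noise scales.
#'
#' @param n_stations,n_weeks panel dimensions (after discarding burn-in).
#' @param phi_shared AR(1) coefficient of the shared latent factor,
#'   `|phi| < 1`.  The factor innovation variance is chosen so the stationary
#'   latent standard deviation is exactly `latent_sd`.
#' @param phi_idio AR(1) coefficient of the indicator-specific component.
#' @param latent_sd stationary standard deviation of the shared factor.
#' @param loadings named per-indicator loadings on the shared factor.
#' @param mu named per-indicator mean levels (pH unitless, others mg/L).
#' @param sigma_idio named stationary standard deviations of the
#'   indicator-specific AR(1) components.
#' @param sigma_noise named observation-noise standard deviations.
#' @param amplitude,period,phase seasonal term `A * sin(2*pi*t/period + phase)`
#'   per indicator; period defaults to 52 weeks.
#' @param seed integer seed; identical configurations give bit-identical panels.
#' @param burn_in leading steps discarded so the AR components reach their
#'   stationary regime.
#' @param indicators indicator names (default the four water-quality targets).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_stations = 8L, n_weeks = 200L,
                             phi_shared = 0.8, phi_idio = 0.5,
                             latent_sd = 1,
                             loadings = NULL, mu = NULL,
                             sigma_idio = NULL, sigma_noise = NULL,
                             amplitude = NULL, period = 52, phase = NULL,
                             seed = 1L, burn_in = 100L,
                             indicators = WQ_INDICATORS) {
  named <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.null(names(x))) x <- setNames(rep_len(x, length(indicators)), indicators)
    x[indicators]
  }
  cfg <- structure(list(
    n_stations = as.integer(n_stations), n_weeks = as.integer(n_weeks),
    phi_shared = phi_shared, phi_idio = phi_idio, latent_sd = latent_sd,
    loadings = named(loadings, c(pH = 0.2, DO = 0.8, CODMn = 0.5, NH3N = 0.08)),
    mu = named(mu, c(pH = 7.5, DO = 8, CODMn = 4, NH3N = 0.5)),
    sigma_idio = named(sigma_idio, c(pH = 0.1, DO = 0.4, CODMn = 0.3, NH3N = 0.05)),
    sigma_noise = named(sigma_noise, c(pH = 0.05, DO = 0.2, CODMn = 0.15, NH3N = 0.03)),
    amplitude = named(amplitude, c(pH = 0.1, DO = 1, CODMn = 0.5, NH3N = 0.05)),
    period = period,
    phase = named(phase, c(pH = 0, DO = pi, CODMn = pi / 2, NH3N = 0)),
    seed = as.integer(seed), burn_in = as.integer(burn_in),
    indicators = indicators
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  wq_assert(abs(cfg$phi_shared) < 1, "phi_shared must lie in (-1, 1)",
            "aquamtl_config_error")
  wq_assert(abs(cfg$phi_idio) < 1, "phi_idio must lie in (-1, 1)",
            "aquamtl_config_error")
  wq_assert(all(cfg$sigma_noise >= 0) && all(cfg$sigma_idio >= 0),
            "noise standard deviations must be >= 0", "aquamtl_config_error")
  wq_assert(cfg$n_weeks >= 1 && cfg$n_stations >= 1,
            "panel dimensions must be positive", "aquamtl_config_error")
  invisible(cfg)
}

#' Default synthetic configuration in plausible surface-water ranges
#'
#' Mean levels of roughly pH 7.5, DO 8 mg/L, CODMn 4 mg/L and NH3N 0.5 mg/L
#' with moderate co-movement through the shared factor.  These are plausible
#' conventions for clean-to-lightly-polluted river water, not estimates from
#' any particular monitoring network.
#'
#' @param ... overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
default_water_config <- function(...) synthetic_config(...)

# Deterministic sub-seed per (station, indicator) stream so that adding a
# station never perturbs the draws of existing ones.  Kept below 2^31 - 1.
sub_seed <- function(seed, station, component) {
  ((as.double(seed) %% 1e6) * 1009 + station * 131071 + component * 8191) %%
    2147483647
}

# Simulate an AR(1) with innovation sd chosen to hit a stationary sd.
sim_ar1 <- function(n, phi, stationary_sd, burn_in) {
  eps_sd <- stationary_sd * sqrt(1 - phi^2)
  e <- rnorm(n + burn_in, sd = eps_sd)
  x <- numeric(n + burn_in)
  x[1L] <- rnorm(1L, sd = stationary_sd)
  for (t in seq_len(n + burn_in - 1L)) x[t + 1L] <- phi * x[t] + e[t + 1L]
  x[(burn_in + 1L):(burn_in + n)]
}

#' Generate a synthetic multi-station water-quality panel
#'
#' @param config a [synthetic_config()].
#' @return An [indicator_panel()] of dimension
#'   (`n_stations`, `n_weeks`, indicators).  pH is clipped to stay strictly
#'   positive and the concentration indicators to stay non-negative; with the
#'   default parameters clipping is essentially never active.
#' @export
generate_panel <- function(config) {
  validate_synthetic_config(config)
  ns <- config$n_stations; nt <- config$n_weeks
  ind <- config$indicators
  v <- array(0, dim = c(ns, nt, length(ind)))
  tvec <- seq_len(nt)
  seasonal <- sapply(ind, function(i) {
    config$amplitude[[i]] * sin(2 * pi * tvec / config$period + config$phase[[i]])
  })
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  for (s in seq_len(ns)) {
    set.seed(sub_seed(config$seed, s, 0L))
    z <- sim_ar1(nt, config$phi_shared, config$latent_sd, config$burn_in)
    for (i in seq_along(ind)) {
      nm <- ind[i]
      set.seed(sub_seed(config$seed, s, i))
      u <- if (config$sigma_idio[[nm]] > 0) {
        sim_ar1(nt, config$phi_idio, config$sigma_idio[[nm]], config$burn_in)
      } else numeric(nt)
      noise <- if (config$sigma_noise[[nm]] > 0) {
        rnorm(nt, sd = config$sigma_noise[[nm]])
      } else numeric(nt)
      x <- config$mu[[nm]] + config$loadings[[nm]] * z + u + seasonal[, i] + noise
      floor_val <- if (nm == "pH") 1e-6 else 0
      v[s, , i] <- pmax(x, floor_val)
    }
  }
  indicator_panel(v, as.Date("2013-01-07") + 7 * (tvec - 1L),
                  sprintf("S%03d", seq_len(ns)), ind)
}
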