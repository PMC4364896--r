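# Synthetic fixtures with the statistical structure the analysis assumes:
# i.i.d.-normal summer temperatures, log-linear delta-T-driven seedfall with
# residual noise, and quarterly abundance observed as forward-simulated
# model output under multiplicative lognormal noise. Every pipeline stage is
# testable against these generators without any field-data download.

#' Generate an i.i.d. normal summer-temperature series
#'
#' Mean summer temperatures are well described as independent normal draws
#' with no serial correlation, which is what makes the long-horizon
#' temperature resampling of the outbreak analysis valid.
#'
#' @param n Number of years (>= 3).
#' @param mean,sd Normal parameters (degrees C); `sd >= 0`.
#' @param seed RNG seed; the series is deterministic given the seed.
#' @param start_year First calendar year.
#' @return [annual_series] of temperatures.
#' @export
gen_temperatures <- function(n, mean = 16.4, sd = 0.7, seed = 1,
                             start_year = 1968) {
  if (n < 3) stop("`n` must be >= 3", call. = FALSE)
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  vals <- with_seed(seed, rnorm(n, mean = mean, sd = sd))
  annual_series(start_year + seq_len(n) - 1, vals, units = "degC")
}

#' Generate seedfall driven by the delta-T mast model
#'
#' For every year with a delta-T predictor,
#' `log10(F + offset) = a + b (T_{y-1} - T_{y-2}) + N(0, residual_sd)`,
#' back-transformed with flooring at zero.
#'
#' @param temps [annual_series] of temperatures (length >= 3).
#' @param a,b Regression intercept and slope (log10 seeds m^-2 and per
#'   degree C).
#' @param residual_sd Residual SD on the log10 scale.
#' @param log_offset Seeds m^-2 added before the log transform.
#' @param seed RNG seed.
#' @return [annual_series] of seedfall (seeds m^-2), two years shorter than
#'   the temperature record.
#' @export
gen_seedfall <- function(temps, a = 0.33, b = 0.97, residual_sd = 0.45,
                         log_offset = 1, seed = 1) {
  dt <- compute_delta_t(temps)
  eps <- with_seed(seed, rnorm(nrow(dt), sd = residual_sd))
  f <- pmax(0, 10 ^ (a + b * dt$value + eps) - log_offset)
  annual_series(dt$year, f, units = "seeds/m2")
}

#' Generate noisy quarterly abundance observations
#'
#' Forward-simulates the consumer model, extracts quarter-start abundances,
#' and multiplies each by lognormal noise with unit median (`meanlog = 0`)
#' and the given coefficient of variation — an observation layer standing in
#' for trap-catch sampling variability of the index.
#'
#' @param params A [consumer_params].
#' @param seedfall [annual_series] of annual seed crops.
#' @param m0 Initial abundance (C/100TN).
#' @param obs_noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 returns the model extractions exactly).
#' @param seed RNG seed.
#' @param dt Integration step (years).
#' @return A [quarterly_series] of observed abundances.
#' @export
gen_mouse_observations <- function(params, seedfall, m0 = 1,
                                   obs_noise_cv = 0.1, seed = 1,
                                   dt = 1 / 400) {
  if (obs_noise_cv < 0) stop("`obs_noise_cv` must be >= 0", call. = FALSE)
  sim <- simulate_consumer(params, seedfall, m0 = m0, dt = dt)
  q <- sim$quarterly
  if (obs_noise_cv > 0) {
    sdlog <- sqrt(log(1 + obs_noise_cv^2))
    noise <- with_seed(seed, exp(rnorm(nrow(q), mean = 0, sd = sdlog)))
    q$value <- q$value * noise
  }
  quarterly_series(q$year, q$quarter, q$value)
}

#' Fixture configuration
#'
#' Default constants emulate the motivating field system: a 43-year annual
#' temperature/seedfall record containing a 25-year (100-observation)
#' quarterly abundance record; the printed delta-T regression
#' (a = 0.33, b = 0.97) with a synthetic residual SD chosen to give a
#' mast-like minority of high-seedfall years; and the fitted Ivlev consumer
#' parameters. The temperature mean/SD are synthetic stand-ins, not station
#' estimates.
#'
#' @param n_years_seedfall Length of the annual seedfall record.
#' @param n_years_quarterly Length of the quarterly abundance record
#'   (<= `n_years_seedfall`).
#' @param temp_mean,temp_sd Temperature generator parameters (degrees C).
#' @param a,b,residual_sd Seedfall regression constants (log10 scale).
#' @param log_offset Seeds m^-2 offset for the log transform.
#' @param params [consumer_params] used to simulate abundance.
#' @param obs_noise_cv Observation-noise CV on the quarterly index.
#' @param m0 Initial abundance (C/100TN).
#' @param start_year First seedfall year.
#' @param quarterly_start_year First quarterly year.
#' @param seed Master seed (sub-seeds are derived from it).
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_years_seedfall = 43, n_years_quarterly = 25,
                           temp_mean = 16.4, temp_sd = 0.7,
                           a = 0.33, b = 0.97, residual_sd = 0.45,
                           log_offset = 1,
                           params = default_consumer_params(),
                           obs_noise_cv = 0.1, m0 = 1,
                           start_year = 1968,
                           quarterly_start_year = 1972, seed = 1) {
  if (n_years_quarterly > n_years_seedfall) {
    stop("`n_years_quarterly` must be <= `n_years_seedfall`", call. = FALSE)
  }
  if (quarterly_start_year < start_year ||
      quarterly_start_year + n_years_quarterly - 1 > start_year + n_years_seedfall - 1) {
    stop("quarterly record must lie within the seedfall record", call. = FALSE)
  }
  structure(list(n_years_seedfall = n_years_seedfall,
                 n_years_quarterly = n_years_quarterly,
                 temp_mean = temp_mean, temp_sd = temp_sd,
                 a = a, b = b, residual_sd = residual_sd,
                 log_offset = log_offset, params = params,
                 obs_noise_cv = obs_noise_cv, m0 = m0,
                 start_year = start_year,
                 quarterly_start_year = quarterly_start_year, seed = seed),
            class = "fixture_config")
}

#' Reference consumer parameters
#'
#' The Ivlev (exponential-saturation) functional response with the
#' observed-seedfall best-fit parameter set of the motivating analysis:
#' c2 = 6.74, e = 1.08, mu1 = -1.23, mu2 = 0.76, h = 9.48, simplified
#' structure (alpha = 1, no consumption feedback).
#'
#' @return A [consumer_params].
#' @export
default_consumer_params <- function() {
  consumer_params(functional_response_spec("ivlev", c = 6.74, shape = 1.08),
                  mu1 = -1.23, mu2 = 0.76, h = 9.48)
}

#' Generate a complete synthetic fixture
#'
#' Produces the three linked series the pipeline consumes — temperatures,
#' seedfall and quarterly abundance — and optionally writes them as CSVs
#' (values formatted to 6 significant digits, so files are byte-identical
#' across platforms for a given seed) together with a JSON provenance record
#' of the configuration.
#'
#' @param config A [fixture_config].
#' @param out_dir Optional directory; when given, writes `temperature.csv`,
#'   `seedfall.csv`, `quarterly.csv` and `fixture_config.json`.
#' @return List with `temps`, `seedfall`, `quarterly`, `config` (and
#'   `paths` when written).
#' @export
make_fixture <- function(config = fixture_config(), out_dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  # temperatures need a 2-year lead-in so the first seedfall year has delta-T
  temps <- gen_temperatures(config$n_years_seedfall + 2,
                            mean = config$temp_mean, sd = config$temp_sd,
                            seed = config$seed,
                            start_year = config$start_year - 2)
  seedfall <- gen_seedfall(temps, a = config$a, b = config$b,
                           residual_sd = config$residual_sd,
                           log_offset = config$log_offset,
                           seed = config$seed + 1000L)
  q_years <- config$quarterly_start_year:
    (config$quarterly_start_year + config$n_years_quarterly - 1)
  sf_q <- annual_series(q_years, seedfall$value[match(q_years, seedfall$year)])
  quarterly <- gen_mouse_observations(config$params, sf_q, m0 = config$m0,
                                      obs_noise_cv = config$obs_noise_cv,
                                      seed = config$seed + 2000L)
  out <- list(temps = temps, seedfall = seedfall, quarterly = quarterly,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fmt <- function(x) signif(x, 6)
    paths <- c(temperature = file.path(out_dir, "temperature.csv"),
               seedfall = file.path(out_dir, "seedfall.csv"),
               quarterly = file.path(out_dir, "quarterly.csv"),
               config = file.path(out_dir, "fixture_config.json"))
    write_annual(annual_series(temps$year, fmt(temps$value)),
                 paths["temperature"], value_name = "temp_degC")
    write_annual(annual_series(seedfall$year, fmt(seedfall$value)),
                 paths["seedfall"], value_name = "seeds_per_m2")
    write_quarterly(quarterly_series(quarterly$year, quarterly$quarter,
                                     fmt(quarterly$value)),
                    paths["quarterly"])
    cfg <- config
    cfg$params <- list(fr_kind = config$params$fr$kind,
                       c = config$params$fr$c,
                       shape = config$params$fr$shape,
                       mu1 = config$params$mu1, mu2 = config$params$mu2,
                       h = config$params$h, alpha = config$params$alpha,
                       consumption_feedback = config$params$consumption_feedback)
    jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
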