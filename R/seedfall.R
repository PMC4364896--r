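# Seedfall prediction from summer temperature, mast-year classification,
# climate thresholds, mast-frequency statistics and scenario bias adjustment.

#' Fit a log-linear seedfall regression on temperature
#'
#' Ordinary least squares of `log10(F_y + offset)` on a temperature predictor:
#' the previous summer's mean temperature `T_{y-1}` (mode `"T"`) or the change
#' between the two preceding summers `T_{y-1} - T_{y-2}` (mode `"dT"`). The
#' additive offset guards near-zero seedfall years before the log transform;
#' it is subtracted again on back-transform with flooring at zero.
#'
#' @param temps [annual_series] of mean summer temperatures (degrees C).
#' @param seedfall [annual_series] of annual seedfall (seeds m^-2), values
#'   >= 0.
#' @param mode `"dT"` (default) or `"T"`: which predictor to use.
#' @param log_offset Seeds m^-2 added before the log10 transform (default 1).
#' @return An object of class `seedfall_regression`: list with `a`
#'   (intercept), `b` (slope), `r_squared`, `p_value` (two-sided, slope),
#'   `residual_sd`, `mode`, `log_offset`, `n`.
#' @export
fit_seedfall_regression <- function(temps, seedfall, mode = c("dT", "T"),
                                    log_offset = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(temps, "annual_series"), inherits(seedfall, "annual_series"))
  if (any(seedfall$value < 0)) stop("seedfall values must be >= 0", call. = FALSE)
  pred <- seedfall_predictor(temps, mode)
  years <- intersect(seedfall$year, pred$year)
  if (length(years) < 5) stop("insufficient overlap between predictor and seedfall (need >= 5 years)", call. = FALSE)
  x <- pred$value[match(years, pred$year)]
  y <- log10(seedfall$value[match(years, seedfall$year)] + log_offset)
  if (stats::var(x) == 0) stop("zero predictor variance", call. = FALSE)
  if (stats::var(y) == 0) {
    # constant response: slope 0, nothing explained
    return(structure(list(a = y[1], b = 0, r_squared = 0, p_value = 1,
                          residual_sd = 0, mode = mode,
                          log_offset = log_offset, n = length(years)),
                     class = "seedfall_regression"))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    a = unname(coef(fit)[1]),
    b = unname(coef(fit)[2]),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    residual_sd = sm$sigma,
    mode = mode,
    log_offset = log_offset,
    n = length(years)
  ), class = "seedfall_regression")
}

#' @export
print.seedfall_regression <- function(x, ...) {
  pred_lab <- if (x$mode == "dT") "(T[y-1] - T[y-2])" else "T[y-1]"
  cat(sprintf("log10(F + %g) = %.3f + %.3f * %s\n", x$log_offset, x$a, x$b, pred_lab))
  cat(sprintf("  r^2 = %.3f, p = %.3g, residual SD = %.3f, n = %d\n",
              x$r_squared, x$p_value, x$residual_sd, x$n))
  invisible(x)
}

# Predictor series indexed by the seedfall year it predicts.
seedfall_predictor <- function(temps, mode) {
  if (mode == "dT") {
    compute_delta_t(temps)
  } else {
    n <- nrow(temps)
    if (n < 2) stop("temperature series too short", call. = FALSE)
    annual_series(temps$year[2:n] , temps$value[1:(n - 1)], units = "degC")
  }
}

#' Predict annual seedfall from a fitted regression
#'
#' Back-transforms the linear predictor: `F_y = max(0, 10^(a + b x_y) -
#' offset)` where `x_y` is the regression's temperature predictor for year
#' `y`. Years whose temperature lags are not covered are dropped.
#'
#' @param reg A `seedfall_regression`.
#' @param temps [annual_series] of mean summer temperatures.
#' @return [annual_series] of predicted seedfall (seeds m^-2), non-negative.
#' @export
predict_seedfall <- function(reg, temps) {
  stopifnot(inherits(reg, "seedfall_regression"))
  pred <- seedfall_predictor(temps, reg$mode)
  f <- pmax(0, 10 ^ (reg$a + reg$b * pred$value) - reg$log_offset)
  annual_series(pred$year, f, units = "seeds/m2")
}

#' Classify mast years by standardized deviates
#'
#' Each year's seedfall is expressed in standard-deviation units from the
#' long-term mean: `AD_y = (F_y - mean(F)) / sd(F)` (sample SD, n-1
#' denominator). The mast threshold is the smallest absolute deviate in the
#' record, `AD_thres = min |AD_y|`, and mast years are those with
#' `AD_y > AD_thres` (strict: ties are not masts).
#'
#' @param seedfall [annual_series] of annual seedfall, length >= 3,
#'   non-constant.
#' @return An object of class `mast_record`: list with `years`, `ad`
#'   (standardized deviates), `ad_thres`, `flags` (logical mast indicator),
#'   and `t_thres`/`dt_thres` slots filled by [climate_thresholds()].
#' @export
classify_masts <- function(seedfall) {
  stopifnot(inherits(seedfall, "annual_series"))
  if (nrow(seedfall) < 3) stop("need >= 3 years to classify masts", call. = FALSE)
  s <- sd(seedfall$value)
  if (s == 0) stop("constant seedfall series: standardized deviates undefined", call. = FALSE)
  ad <- (seedfall$value - mean(seedfall$value)) / s
  ad_thres <- min(abs(ad))
  structure(list(
    years = seedfall$year,
    ad = ad,
    ad_thres = ad_thres,
    flags = ad > ad_thres,
    t_thres = NA_real_,
    dt_thres = NA_real_
  ), class = "mast_record")
}

#' @export
print.mast_record <- function(x, ...) {
  cat(sprintf("<mast_record> %d years, %d mast years (AD_thres = %.3f)\n",
              length(x$years), sum(x$flags), x$ad_thres))
  if (sum(x$flags)) cat("  mast years:", paste(x$years[x$flags], collapse = ", "), "\n")
  if (!is.na(x$t_thres)) {
    cat(sprintf("  T_thres = %.2f degC, dT_thres = %.2f degC\n", x$t_thres, x$dt_thres))
  }
  invisible(x)
}

#' Climate thresholds for mast years
#'
#' The minimum predictor values over the identified mast years: `T_thres` is
#' the minimum of `T_{y-1}` and `dT_thres` the minimum of
#' `T_{y-1} - T_{y-2}` across mast years `y`. Years above these thresholds
#' are the climate-based mast predictions used in scenario analysis.
#'
#' @param mast A `mast_record` from [classify_masts()].
#' @param temps [annual_series] of mean summer temperatures covering the
#'   required lags for every mast year.
#' @return The `mast_record` with `t_thres` and `dt_thres` filled in.
#' @export
climate_thresholds <- function(mast, temps) {
  stopifnot(inherits(mast, "mast_record"), inherits(temps, "annual_series"))
  mast_years <- mast$years[mast$flags]
  if (!length(mast_years)) stop("no mast years: thresholds undefined", call. = FALSE)
  t_prev <- seedfall_predictor(temps, "T")
  dt <- compute_delta_t(temps)
  if (!all(mast_years %in% t_prev$year) || !all(mast_years %in% dt$year)) {
    stop("temperature record does not cover the lags of every mast year", call. = FALSE)
  }
  mast$t_thres <- min(t_prev$value[match(mast_years, t_prev$year)])
  mast$dt_thres <- min(dt$value[match(mast_years, dt$year)])
  mast
}

#' Mast-frequency statistics from a flag sequence
#'
#' Summarises a per-year logical mast indicator: the proportion of years that
#' are mast years, the proportion of years that begin a double mast (two
#' consecutive mast years), and the mean gap in years between successive mast
#' events (a gap of 1 means consecutive years).
#'
#' @param flags Logical vector, one entry per year, length >= 2.
#' @return List with `prop_single`, `prop_double`, `mean_gap` (`NA` with
#'   fewer than two events) and `n_events`.
#' @export
mast_interval_stats <- function(flags) {
  flags <- as.logical(flags)
  n <- length(flags)
  if (n < 2) stop("need >= 2 years", call. = FALSE)
  if (anyNA(flags)) stop("flags must not contain NA", call. = FALSE)
  idx <- which(flags)
  list(
    prop_single = length(idx) / n,
    prop_double = sum(flags[-n] & flags[-1]) / n,
    mean_gap = if (length(idx) >= 2) mean(diff(idx)) else NA_real_,
    n_events = length(idx)
  )
}

#' Bias-adjust a climate-scenario temperature series
#'
#' Affine moment matching: the scenario series is rescaled so that its mean
#' and SD over the years overlapping the reference record equal the
#' reference's overlap mean and SD. Corrects the systematic cold/damped bias
#' of grid-interpolated scenario temperatures relative to a station record.
#'
#' @param scenario [annual_series] of scenario temperatures.
#' @param reference [annual_series] of observed temperatures; must share >= 3
#'   years with the scenario.
#' @return The full scenario series, adjusted.
#' @export
adjust_scenario <- function(scenario, reference) {
  stopifnot(inherits(scenario, "annual_series"), inherits(reference, "annual_series"))
  overlap <- intersect(scenario$year, reference$year)
  if (length(overlap) < 3) stop("need >= 3 overlapping years", call. = FALSE)
  xs <- scenario$value[match(overlap, scenario$year)]
  xr <- reference$value[match(overlap, reference$year)]
  m_s <- mean(xs); s_s <- sd(xs)
  if (s_s == 0) stop("zero scenario variance on overlap", call. = FALSE)
  m_r <- mean(xr); s_r <- sd(xr)
  annual_series(scenario$year, (scenario$value - m_s) / s_s * s_r + m_r,
                units = attr(reference, "units") %||% "degC")
}

#' Distributional and autocorrelation checks for an annual series
#'
#' Thin wrapper over the standard two-sample Kolmogorov-Smirnov test (against
#' a comparison series) and Ljung-Box portmanteau tests at lags 1-5, used to
#' check that predicted seedfall matches the observed distribution and that
#' temperature/seedfall series carry no serial correlation.
#'
#' @param series [annual_series] with at least 10 values.
#' @param comparison Optional [annual_series] for the KS test.
#' @return List with `ks` (`statistic`, `p_value`; `NULL` when no comparison
#'   given) and `ljung_box` (data frame of lag, statistic, p_value).
#' @export
distribution_checks <- function(series, comparison = NULL) {
  stopifnot(inherits(series, "annual_series"))
  if (nrow(series) < 10) stop("series too short (need >= 10 values)", call. = FALSE)
  ks <- NULL
  if (!is.null(comparison)) {
    kt <- suppressWarnings(ks.test(series$value, comparison$value))
    ks <- list(statistic = unname(kt$statistic), p_value = kt$p.value)
  }
  lb <- do.call(rbind, lapply(1:5, function(k) {
    bt <- Box.test(series$value, lag = k, type = "Ljung-Box")
    data.frame(lag = k, statistic = unname(bt$statistic), p_value = bt$p.value)
  }))
  list(ks = ks, ljung_box = lb)
}
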