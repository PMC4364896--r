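# Long-horizon outbreak analysis: annual spring peak and late-summer to
# early-spring increase extracted from quarterly output, logistic versus
# linear dose-response fits against delta-T and log10 seedfall, and the
# model/data correlation triplet.

#' Annual spring (August) abundance
#'
#' Projects the early-spring value of the abundance index out of a quarterly
#' series: mouse populations approach their annual peak in the August
#' post-seedfall quarter. Years without an August record are omitted.
#'
#' @param q A [quarterly_series].
#' @return [annual_series] of August abundances.
#' @export
spring_peak_series <- function(q) {
  stopifnot(inherits(q, "quarterly_series"))
  aug <- q[q$quarter == "Aug", ]
  if (!nrow(aug)) stop("no August records", call. = FALSE)
  as_annual_maybe_gappy(aug$year, aug$value, units = "C/100TN")
}

# Missing sessions can leave gap years, which the strict annual-series
# contract rejects; fall back to a plain (year, value) data frame then.
as_annual_maybe_gappy <- function(years, values, units = "") {
  if (length(years) < 2 || all(diff(years) == 1)) {
    annual_series(years, values, units = units)
  } else {
    data.frame(year = years, value = values)
  }
}

#' Annual late-summer to early-spring rate of increase
#'
#' The finite rate of increase over mid-February to mid-August of each year:
#' `M_Aug / max(M_Feb, floor)`. The floor guards division by a zero or
#' near-zero February index. Years lacking either record are omitted.
#'
#' @param q A [quarterly_series].
#' @param floor Denominator floor (C/100TN), default 0.1.
#' @return [annual_series] of dimensionless ratios.
#' @export
winter_increase_series <- function(q, floor = 0.1) {
  stopifnot(inherits(q, "quarterly_series"))
  feb <- q[q$quarter == "Feb", ]
  aug <- q[q$quarter == "Aug", ]
  yrs <- intersect(feb$year, aug$year)
  if (!length(yrs)) stop("no year has both February and August records", call. = FALSE)
  ratio <- aug$value[match(yrs, aug$year)] / pmax(feb$value[match(yrs, feb$year)], floor)
  as_annual_maybe_gappy(yrs, ratio, units = "ratio")
}

#' Fit a four-parameter logistic curve by least squares
#'
#' `y = A + (B - A) / (1 + exp(-s (x - x0)))` with both asymptotes free
#' (outbreak responses plateau at a nonzero background level). Fitted by
#' Levenberg-Marquardt least squares from a seeded multi-start initial grid;
#' degenerate (constant-`y`) inputs return a flat fit rather than an error.
#'
#' @param x Predictor values (non-constant, length >= 8).
#' @param y Response values.
#' @param n_starts Number of initialisations.
#' @param seed Seed for the initialisation draws.
#' @return An object of class `logistic_fit`: `A`, `B`, `x0`, `s`, `fitted`,
#'   `rss`, `aicc` (K = 5 including the error variance), `pearson_r`
#'   (fitted vs observed).
#' @export
fit_logistic <- function(x, y, n_starts = 12, seed = 7) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 8) stop("need >= 8 points", call. = FALSE)
  if (sd(x) == 0) stop("constant predictor", call. = FALSE)
  n <- length(x)
  if (sd(y) == 0) {
    fitted <- rep(mean(y), n)
    return(structure(list(A = mean(y), B = mean(y), x0 = median(x), s = 0,
                          fitted = fitted, rss = 0,
                          aicc = logistic_aicc(0, n),
                          pearson_r = NA_real_, converged = TRUE),
                     class = "logistic_fit"))
  }
  ql <- quantile(y, c(0.05, 0.95), names = FALSE)
  xr <- range(x)
  starts <- with_seed(seed, {
    data.frame(
      A = runif(n_starts, min(y), ql[1] + 0.25 * diff(ql)),
      B = runif(n_starts, ql[2] - 0.25 * diff(ql), max(y)),
      x0 = runif(n_starts, xr[1], xr[2]),
      s = 10 ^ runif(n_starts, -1, 1.5) / max(diff(xr), 1e-8)
    )
  })
  # one deterministic start at the data's gross shape
  starts <- rbind(data.frame(A = ql[1], B = ql[2], x0 = median(x),
                             s = 4 / max(diff(xr), 1e-8)), starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A + (B - A) / (1 + exp(-s * (x - x0))),
        start = as.list(starts[i, ]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("logistic fit failed to converge from any start", call. = FALSE)
  cf <- coef(best$fit)
  # orient so that s >= 0 is not forced; keep as fitted
  fitted <- as.numeric(predict(best$fit))
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                 x0 = unname(cf["x0"]), s = unname(cf["s"]),
                 fitted = fitted, rss = best$rss,
                 aicc = logistic_aicc(best$rss, n),
                 pearson_r = if (sd(fitted) > 0) cor(fitted, y) else NA_real_,
                 converged = TRUE),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> A = %.4g, B = %.4g, x0 = %.4g, s = %.4g\n",
              x$A, x$B, x$x0, x$s))
  cat(sprintf("  RSS = %.4g, AICc = %.2f, Pearson r = %.4f\n",
              x$rss, x$aicc, x$pearson_r))
  invisible(x)
}

# Least-squares AICc from an RSS; K parameters including the error variance.
rss_aicc <- function(rss, n, K) {
  sigma2 <- max(rss / n, 1e-300)  # guard log(0) for exact fits
  n * log(sigma2) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}
logistic_aicc <- function(rss, n) rss_aicc(rss, n, 5)

#' Predict from a logistic fit
#'
#' @param object A `logistic_fit`.
#' @param newdata Predictor values.
#' @param ... Unused.
#' @return Fitted response at `newdata`.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  object$A + (object$B - object$A) /
    (1 + exp(-object$s * (newdata - object$x0)))
}

#' Compare logistic and linear dose-response fits
#'
#' Fits the 4-parameter logistic and a simple linear regression to the same
#' points and returns the AICc improvement of the logistic
#' (`delta_aicc = AICc_linear - AICc_logistic`; positive values favour the
#' logistic, i.e. threshold-like, relationship). The linear model counts
#' K = 3 parameters (slope, intercept, error variance).
#'
#' @param x Predictor values.
#' @param y Response values.
#' @param ... Passed to [fit_logistic()].
#' @return List with `delta_aicc`, `logistic` (a `logistic_fit`), `linear`
#'   (list with `coef`, `rss`, `aicc`, `pearson_r`).
#' @export
compare_logistic_linear <- function(x, y, ...) {
  lg <- fit_logistic(x, y, ...)
  lf <- lm(y ~ x)
  rss <- sum(resid(lf)^2)
  lin <- list(coef = coef(lf), rss = rss,
              aicc = rss_aicc(rss, length(x), 3),
              pearson_r = if (sd(fitted(lf)) > 0) cor(fitted(lf), y) else NA_real_)
  list(delta_aicc = lin$aicc - lg$aicc, logistic = lg, linear = lin)
}

#' Model/data correlation triplet for one dose-response pairing
#'
#' Fits logistic curves to the model output and to the observed data
#' separately, then reports `r_mm` (model points vs the model-fitted curve),
#' `r_dd` (data points vs the data-fitted curve) and `r_dm` (data points vs
#' the model-fitted curve evaluated at the data's predictor values).
#'
#' @param model_x,model_y Model-output predictor/response points.
#' @param data_x,data_y Observed predictor/response points.
#' @param ... Passed to [fit_logistic()].
#' @return List with `r_mm`, `r_dd`, `r_dm` and the two `logistic_fit`s.
#' @export
correlation_triplet <- function(model_x, model_y, data_x, data_y, ...) {
  fm <- fit_logistic(model_x, model_y, ...)
  fd <- fit_logistic(data_x, data_y, ...)
  dm_pred <- predict(fm, data_x)
  if (sd(dm_pred) == 0) stop("constant predictor: model curve is flat over the data", call. = FALSE)
  list(r_mm = fm$pearson_r,
       r_dd = fd$pearson_r,
       r_dm = cor(data_y, dm_pred),
       model_fit = fm, data_fit = fd)
}

#' Long-horizon outbreak-threshold analysis
#'
#' Generates a synthetic multi-century record of mean summer temperatures
#' (i.i.d. normal), converts them to delta-T and to predicted seedfall via a
#' fitted regression, forward-simulates the consumer model, and extracts the
#' annual spring (August) peak and the February-to-August rate of increase.
#' Each response is then regressed on each predictor (delta-T; log10
#' seedfall) with logistic and linear fits compared by AICc.
#'
#' @param params A [consumer_params] (typically the fitted Ivlev model).
#' @param reg A `seedfall_regression` (typically the delta-T model).
#' @param horizon Number of simulated years (>= 100; default 1000).
#' @param temp_mean,temp_sd Mean and SD of the summer-temperature generator
#'   (degrees C).
#' @param seed RNG seed; the report is deterministic given the seed.
#' @param m0 Initial abundance (C/100TN).
#' @param floor Denominator floor for the rate of increase.
#' @param dt Integration step (years).
#' @return An object of class `outbreak_report`: list with `pairings` (named
#'   list of [compare_logistic_linear()] results for
#'   `peak_vs_dt`, `peak_vs_logF`, `increase_vs_dt`, `increase_vs_logF`),
#'   `annual` (data frame of year, delta_t, seedfall, log10_seedfall, peak,
#'   increase), and the generator settings.
#' @export
run_step4 <- function(params, reg, horizon = 1000, temp_mean = 16.4,
                      temp_sd = 0.7, seed = 1, m0 = 1, floor = 0.1,
                      dt = 1 / 400) {
  stopifnot(inherits(params, "consumer_params"), inherits(reg, "seedfall_regression"))
  if (horizon < 100) stop("`horizon` must be >= 100", call. = FALSE)
  # two lead-in years so every simulated year has a delta-T predictor
  temps <- gen_temperatures(horizon + 2, mean = temp_mean, sd = temp_sd,
                            seed = seed, start_year = -1)
  dtemp <- compute_delta_t(temps)
  seedfall <- predict_seedfall(reg, temps)
  sim <- simulate_consumer(params, seedfall, m0 = m0, dt = dt)
  peak <- spring_peak_series(sim$quarterly)
  incr <- winter_increase_series(sim$quarterly, floor = floor)
  yrs <- seedfall$year
  annual <- data.frame(
    year = yrs,
    delta_t = dtemp$value[match(yrs, dtemp$year)],
    seedfall = seedfall$value,
    log10_seedfall = log10(seedfall$value + reg$log_offset),
    peak = peak$value[match(yrs, peak$year)],
    increase = incr$value[match(yrs, incr$year)]
  )
  pairings <- list(
    peak_vs_dt = compare_logistic_linear(annual$delta_t, annual$peak),
    peak_vs_logF = compare_logistic_linear(annual$log10_seedfall, annual$peak),
    increase_vs_dt = compare_logistic_linear(annual$delta_t, annual$increase),
    increase_vs_logF = compare_logistic_linear(annual$log10_seedfall, annual$increase)
  )
  structure(list(pairings = pairings, annual = annual,
                 horizon = horizon, temp_mean = temp_mean,
                 temp_sd = temp_sd, seed = seed, params = params, reg = reg),
            class = "outbreak_report")
}

#' @export
print.outbreak_report <- function(x, ...) {
  cat(sprintf("<outbreak_report> %d-year simulation (temp ~ N(%.1f, %.2f^2), seed %d)\n",
              x$horizon, x$temp_mean, x$temp_sd, x$seed))
  for (nm in names(x$pairings)) {
    p <- x$pairings[[nm]]
    cat(sprintf("  %-17s dAICc(linear - logistic) = %8.1f, r_mm = %.4f\n",
                nm, p$delta_aicc, p$logistic$pearson_r))
  }
  invisible(x)
}
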