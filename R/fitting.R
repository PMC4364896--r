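# RMSE-based fitting of the consumer-resource model to quarterly abundance
# data, nonparametric bootstrap confidence intervals, and AICc comparison.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Fitting configuration
#'
#' Controls the multi-start derivative-free (Nelder-Mead) optimisation.
#' Positive-valued parameters are searched on a log scale inside box bounds
#' via a logistic reparameterisation, so the simplex is unconstrained.
#' Defaults: 20 seeded starts, objective relative tolerance 1e-8.
#'
#' @param n_starts Number of multi-starts for a full fit.
#' @param maxit Simplex iteration cap per start.
#' @param polish_maxit Iteration cap for the final polish restart.
#' @param boot_starts Extra random starts per bootstrap replicate (each
#'   replicate is also warm-started from the point estimate).
#' @param boot_maxit Simplex iteration cap per bootstrap start.
#' @param start_seed Seed for drawing the start grid.
#' @param reltol Objective relative convergence tolerance.
#' @param dt Integration step passed to [simulate_consumer()].
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, maxit = 500, polish_maxit = 1000,
                       boot_starts = 2, boot_maxit = 300, start_seed = 20,
                       reltol = 1e-8, dt = 1 / 400,
                       bounds = list(c = c(1e-3, 100),
                                     shape = c(0.01, 50),
                                     alpha = c(0.01, 100),
                                     mu1 = c(-10, 10),
                                     mu2 = c(-10, 10),
                                     h = c(0, 30))) {
  structure(list(n_starts = n_starts, maxit = maxit,
                 polish_maxit = polish_maxit, boot_starts = boot_starts,
                 boot_maxit = boot_maxit, start_seed = start_seed,
                 reltol = reltol, dt = dt, bounds = bounds),
            class = "fit_config")
}

# Free-parameter layout for one functional response / structure combination.
# log-scaled parameters are searched as log-box logistic transforms.
param_spec <- function(fr_kind, structure) {
  nm <- c("c", if (fr_kind != "uncapped") "shape",
          if (structure == "full") "alpha", "mu1", "mu2", "h")
  log_scaled <- nm %in% c("c", "shape", "alpha")
  list(names = nm, log = log_scaled)
}

# Map unconstrained theta to bounded natural parameters and back.
theta_to_params <- function(theta, spec, bounds) {
  p <- numeric(length(theta))
  for (i in seq_along(theta)) {
    b <- bounds[[spec$names[i]]]
    if (spec$log[i]) {
      lo <- log(b[1]); hi <- log(b[2])
      p[i] <- exp(lo + (hi - lo) * plogis(theta[i]))
    } else {
      p[i] <- b[1] + (b[2] - b[1]) * plogis(theta[i])
    }
  }
  setNames(p, spec$names)
}

params_to_theta <- function(p, spec, bounds) {
  th <- numeric(length(p))
  for (i in seq_along(p)) {
    b <- bounds[[spec$names[i]]]
    if (spec$log[i]) {
      lo <- log(b[1]); hi <- log(b[2])
      f <- (log(p[i]) - lo) / (hi - lo)
    } else {
      f <- (p[i] - b[1]) / (b[2] - b[1])
    }
    th[i] <- qlogis(min(max(f, 1e-8), 1 - 1e-8))
  }
  th
}

vec_to_consumer_params <- function(p, fr_kind, structure) {
  fr <- functional_response_spec(fr_kind, c = p[["c"]],
                                 shape = if (fr_kind == "uncapped") NULL else p[["shape"]])
  consumer_params(fr,
                  mu1 = p[["mu1"]], mu2 = p[["mu2"]], h = p[["h"]],
                  alpha = if (structure == "full") p[["alpha"]] else 1,
                  consumption_feedback = structure == "full")
}

# Align observations with a simulation window. The simulation starts at the
# first observed February; observations before it are rejected.
fit_frame <- function(data, seedfall) {
  stopifnot(inherits(data, "quarterly_series"), inherits(seedfall, "annual_series"))
  feb <- data[data$quarter == "Feb", ]
  if (!nrow(feb)) stop("no February observation: cannot set initial abundance", call. = FALSE)
  y0 <- min(feb$year)
  if (any(data$time < y0)) {
    stop("observations precede the first observed February", call. = FALSE)
  }
  y1 <- max(data$year)
  if (!all(y0:y1 %in% seedfall$year)) {
    stop("seedfall record does not cover the observation years ", y0, "-", y1, call. = FALSE)
  }
  sf <- seedfall[match(y0:y1, seedfall$year), ]
  list(m0 = feb$value[feb$year == y0],
       seedfall = annual_series(sf$year, sf$value))
}

#' Root-mean-square error of the model against quarterly observations
#'
#' Simulates the model over the observation window (initial abundance = the
#' first observed February value), extracts predictions at each observed
#' (year, quarter), and returns the square root of the weighted mean squared
#' error. Weights default to 1; the bootstrap supplies resampling
#' multiplicities.
#'
#' @param params A [consumer_params].
#' @param data A [quarterly_series] of observed abundances.
#' @param seedfall [annual_series] covering every observation year.
#' @param weights Per-observation non-negative weights.
#' @param dt Integration step (years).
#' @return RMSE in C/100TN.
#' @export
rmse_objective <- function(params, data, seedfall, weights = NULL,
                           dt = 1 / 400) {
  fr <- fit_frame(data, seedfall)
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (length(weights) != nrow(data)) stop("one weight per observation required", call. = FALSE)
  sim <- simulate_consumer(params, fr$seedfall, m0 = fr$m0, dt = dt)
  pred <- sim$quarterly$value[match(data$time, sim$quarterly$time)]
  if (anyNA(pred)) stop("internal error: unmatched observation time", call. = FALSE)
  sqrt(sum(weights * (pred - data$value)^2) / sum(weights))
}

# Internal: predictions at the observed times for a parameter vector.
predict_at_obs <- function(params, data, seedfall, dt) {
  fr <- fit_frame(data, seedfall)
  sim <- simulate_consumer(params, fr$seedfall, m0 = fr$m0, dt = dt)
  sim$quarterly$value[match(data$time, sim$quarterly$time)]
}

# Internal fast objective: identical arithmetic to rmse_objective() but with
# the observation alignment precomputed and the compiled integrator called
# directly, avoiding per-evaluation data-frame construction. The optimiser
# calls this thousands of times per fit.
build_objective <- function(data, seedfall, fr_kind, structure, config,
                            weights) {
  frame <- fit_frame(data, seedfall)
  fy <- frame$seedfall$value
  y0 <- frame$seedfall$year[1]
  obs_idx <- as.integer(round((data$time - y0) * 4)) + 1L
  stopifnot(all(obs_idx >= 1L), all(obs_idx <= 4L * length(fy)))
  obs <- data$value
  w <- weights
  wsum <- sum(w)
  kind <- unname(FR_KINDS[fr_kind])
  steps <- max(10L, as.integer(round(0.25 / config$dt)))
  full <- structure == "full"
  function(p) {
    res <- simulate_rk4_cpp(frame$m0, fy, kind,
                            p[["c"]],
                            if (fr_kind == "uncapped") 1 else p[["shape"]],
                            if (full) p[["alpha"]] else 1,
                            p[["mu1"]], p[["mu2"]], p[["h"]],
                            full, steps, FALSE)
    pred <- res$q_M[obs_idx]
    sqrt(sum(w * (pred - obs)^2) / wsum)
  }
}

#' Corrected Akaike information criterion from an RMSE
#'
#' Least-squares AICc with the error variance counted as a fitted parameter:
#' `AICc = n log(rmse^2) + 2K + 2K(K+1)/(n - K - 1)` with
#' `K = k_params + 1`. Only differences across models fitted to identical
#' data are meaningful.
#'
#' @param rmse Root-mean-square error, > 0.
#' @param n Number of observations.
#' @param k_params Number of fitted model parameters (excluding the error
#'   variance).
#' @return AICc (dimensionless).
#' @export
aicc <- function(rmse, n, k_params) {
  K <- k_params + 1
  if (n <= K + 1) stop("AICc undefined: need n > k_params + 2", call. = FALSE)
  n * log(rmse^2) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Fit the consumer-resource model to quarterly abundance data
#'
#' Minimises [rmse_objective()] by multi-start Nelder-Mead simplex over a
#' seeded start grid (log-spaced for positive parameters) inside box bounds,
#' keeping the best start and polishing it with a simplex restart. The
#' simplified structure (the one selected for all headline fits) fixes
#' `alpha = 1` and removes consumer feedback on the resource; the full
#' structure frees `alpha` and keeps the feedback term.
#'
#' @param data A [quarterly_series] of observed abundances.
#' @param seedfall [annual_series] covering every observation year.
#' @param fr_kind Functional response: `"piecewise"`, `"ivlev"`,
#'   `"holling2"` or `"uncapped"`.
#' @param structure `"simplified"` (default) or `"full"`.
#' @param config A [fit_config].
#' @param weights Optional per-observation weights (bootstrap
#'   multiplicities).
#' @param start_theta Optional matrix of extra start points (unconstrained
#'   scale), prepended to the seeded grid.
#' @param n_starts Overrides `config$n_starts`.
#' @param maxit Overrides `config$maxit`.
#' @return An object of class `fit_result`: `params` ([consumer_params]),
#'   `estimate` (named vector of free parameters), `rmse`, `pearson_r`,
#'   `aicc`, `n`, `k`, `fr_kind`, `structure`, `convergence`.
#' @export
fit_consumer_model <- function(data, seedfall,
                               fr_kind = c("ivlev", "piecewise", "holling2", "uncapped"),
                               structure = c("simplified", "full"),
                               config = fit_config(), weights = NULL,
                               start_theta = NULL, n_starts = NULL,
                               maxit = NULL) {
  fr_kind <- match.arg(fr_kind)
  structure <- match.arg(structure)
  spec <- param_spec(fr_kind, structure)
  k <- length(spec$names)
  if (nrow(data) < 5 * k) {
    stop("need >= 5 observations per free parameter (", 5 * k, ")", call. = FALSE)
  }
  n_starts <- n_starts %||% config$n_starts
  maxit <- maxit %||% config$maxit
  if (is.null(weights)) weights <- rep(1, nrow(data))

  rmse_of <- build_objective(data, seedfall, fr_kind, structure, config,
                             weights)
  obj <- function(theta) {
    p <- theta_to_params(theta, spec, config$bounds)
    val <- tryCatch(rmse_of(p), error = function(e) NA_real_)
    if (!is.finite(val)) 1e6 else val
  }

  starts <- with_seed(config$start_seed,
                      matrix(rnorm(n_starts * k, sd = 2),
                             nrow = n_starts, ncol = k))
  if (!is.null(start_theta)) starts <- rbind(start_theta, starts)

  best <- NULL
  n_fail <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = config$reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  polish <- optim(best$par, obj, method = "Nelder-Mead",
                  control = list(maxit = config$polish_maxit,
                                 reltol = config$reltol))
  if (polish$value <= best$value) best <- polish

  p <- theta_to_params(best$par, spec, config$bounds)
  cp <- vec_to_consumer_params(p, fr_kind, structure)
  rmse <- rmse_objective(cp, data, seedfall, weights = weights, dt = config$dt)
  pred <- predict_at_obs(cp, data, seedfall, config$dt)
  structure2 <- list(
    params = cp, estimate = p, theta = best$par, rmse = rmse,
    pearson_r = if (sd(pred) > 0) cor(pred, data$value) else NA_real_,
    aicc = aicc(rmse, nrow(data), k),
    n = nrow(data), k = k, fr_kind = fr_kind, structure = structure,
    convergence = best$convergence, n_failed_starts = n_fail,
    data_id = paste0(nrow(data), ":", signif(sum(data$value), 12)),
    config = config
  )
  class(structure2) <- "fit_result"
  structure2
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (%s structure), n = %d, k = %d\n",
              x$fr_kind, x$structure, x$n, x$k))
  cat(sprintf("  RMSE = %.4f C/100TN, Pearson r = %.3f, AICc = %.2f\n",
              x$rmse, x$pearson_r, x$aicc))
  est <- x$estimate
  cat("  ", paste(sprintf("%s = %.3g", names(est), est), collapse = ", "), "\n")
  if (!is.null(x$ci)) {
    cat("  95% bootstrap CIs:\n")
    for (nm in rownames(x$ci)) {
      cat(sprintf("    %s: (%.3g, %.3g)\n", nm, x$ci[nm, 1], x$ci[nm, 2]))
    }
  }
  invisible(x)
}

#' Nonparametric bootstrap confidence intervals for fitted parameters
#'
#' Case resampling of the quarterly observations: each replicate draws `n`
#' observation indices with replacement (entering the objective as
#' multiplicity weights) and refits, warm-started from the point estimate
#' plus a few random starts. Percentile (2.5%, 97.5%) intervals over the
#' replicate estimates. Deterministic for a given seed.
#'
#' @param data,seedfall,fr_kind,structure,config As [fit_consumer_model()].
#' @param n_boot Number of replicates (>= 50; the reference analysis uses
#'   100).
#' @param seed RNG seed for the resampling draws.
#' @param fit Optional precomputed point fit (avoids refitting).
#' @return List with `ci` (matrix: parameter x c(lower, upper)),
#'   `replicates` (data frame of per-replicate estimates), `n_boot`, `seed`,
#'   `n_failed`.
#' @export
bootstrap_ci <- function(data, seedfall, fr_kind, structure = "simplified",
                         n_boot = 100, seed = 1, config = fit_config(),
                         fit = NULL) {
  if (n_boot < 50) stop("`n_boot` must be >= 50", call. = FALSE)
  if (is.null(fit)) {
    fit <- fit_consumer_model(data, seedfall, fr_kind, structure, config)
  }
  n <- nrow(data)
  idx_draws <- with_seed(seed, {
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  })
  start_extra <- with_seed(seed + 1L, {
    matrix(rnorm(config$boot_starts * length(fit$theta), sd = 2),
           nrow = config$boot_starts)
  })
  reps <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    w <- tabulate(idx_draws[b, ], nbins = n)
    rb <- tryCatch(
      fit_consumer_model(data, seedfall, fr_kind, structure, config,
                         weights = w,
                         start_theta = rbind(fit$theta, start_extra),
                         n_starts = 0, maxit = config$boot_maxit),
      error = function(e) NULL)
    if (is.null(rb)) { n_failed <- n_failed + 1L; next }
    reps[[b]] <- rb$estimate
  }
  if (n_failed > 0.2 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap refits failed", call. = FALSE)
  }
  mat <- do.call(rbind, reps)
  ci <- t(apply(mat, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, replicates = as.data.frame(mat), n_boot = n_boot,
       seed = seed, n_failed = n_failed, point = fit$estimate)
}

#' Compare fitted models by AICc
#'
#' Tabulates fits of different model variants to the same data, sorted by
#' AICc with differences relative to the best model. AICc ties are broken by
#' fewer parameters, then by label.
#'
#' @param fits Named list of `fit_result` objects on identical data.
#' @return Data frame with columns `model`, `k`, `rmse`, `pearson_r`, `aicc`,
#'   `delta_aicc`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "fit_result")))
  ids <- vapply(fits, `[[`, "", "data_id")
  if (length(unique(ids)) != 1) stop("fits are not on identical data", call. = FALSE)
  labels <- names(fits) %||% vapply(fits, function(f) paste(f$fr_kind, f$structure, sep = "/"), "")
  if (is.null(names(fits))) names(fits) <- labels
  df <- data.frame(
    model = labels,
    k = vapply(fits, `[[`, 0L, "k"),
    rmse = vapply(fits, `[[`, 0, "rmse"),
    pearson_r = vapply(fits, `[[`, 0, "pearson_r"),
    aicc = vapply(fits, `[[`, 0, "aicc"),
    row.names = NULL
  )
  df <- df[order(df$aicc, df$k, df$model), ]
  df$delta_aicc <- df$aicc - min(df$aicc)
  rownames(df) <- NULL
  df
}
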