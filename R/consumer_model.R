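# Mechanistic consumer-resource model: pulsed seed input, exponential seed
# loss, four candidate functional responses, and house-mouse demographic
# dynamics. The population equation is
#   dM/dt = (alpha * g(F) - mu1 - mu2 * M) * M
# and the resource equation
#   dF/dt = S(t) - h * F - [g(F) * M if consumption feedback is on],
# with the annual seed crop F_y delivered at constant rate over the first
# quarter of a February-start year and F reset to 0 at each year start.

FR_KINDS <- c(piecewise = 0L, ivlev = 1L, holling2 = 2L, uncapped = 3L)

#' Specify a functional response
#'
#' Four candidate forms for the per-capita seed consumption rate `g(F)`:
#' \describe{
#'   \item{piecewise}{Holling type I, `g(F) = c * min(F, K)`; `shape` is the
#'     cap `K` (seeds m^-2).}
#'   \item{ivlev}{Holling type II (Ivlev), `g(F) = c * (1 - exp(-e F))`;
#'     `shape` is the foraging efficiency `e` ((seeds m^-2)^-1).}
#'   \item{holling2}{Holling type II (standard), `g(F) = c * F / (F + K)`;
#'     `shape` is the half-saturation constant `K` (seeds m^-2).}
#'   \item{uncapped}{`g(F) = c * F`; no `shape` parameter.}
#' }
#' For piecewise/uncapped, `c` is the feeding rate c1 (mouse^-1 year^-1);
#' for ivlev/holling2 it is the maximum per-capita feeding rate c2
#' (seeds m^-2 mouse^-1 year^-1).
#'
#' @param kind One of `"piecewise"`, `"ivlev"`, `"holling2"`, `"uncapped"`.
#' @param c Feeding-rate parameter, > 0.
#' @param shape Cap/efficiency/half-saturation parameter, > 0; absent
#'   (`NULL`) for `"uncapped"`.
#' @return An object of class `functional_response_spec`.
#' @export
functional_response_spec <- function(kind = c("piecewise", "ivlev", "holling2", "uncapped"),
                                     c, shape = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(c) || length(c) != 1 || c <= 0) {
    stop("`c` must be a positive scalar", call. = FALSE)
  }
  if (kind == "uncapped") {
    if (!is.null(shape)) stop("the uncapped response has no shape parameter", call. = FALSE)
  } else {
    if (!is.numeric(shape) || length(shape) != 1 || shape <= 0) {
      stop("`shape` must be a positive scalar for ", kind, call. = FALSE)
    }
  }
  structure(list(kind = kind, c = c, shape = shape),
            class = "functional_response_spec")
}

#' Evaluate a functional response
#'
#' @param fr A [functional_response_spec].
#' @param F Seed availability (seeds m^-2), >= 0; vectorised.
#' @return Per-capita consumption rate at each `F`; 0 at `F = 0`.
#' @export
functional_response <- function(fr, F) {
  stopifnot(inherits(fr, "functional_response_spec"))
  if (any(F < 0)) stop("negative seed availability", call. = FALSE)
  switch(fr$kind,
    piecewise = fr$c * pmin(F, fr$shape),
    ivlev     = fr$c * (1 - exp(-fr$shape * F)),
    holling2  = fr$c * F / (F + fr$shape),
    uncapped  = fr$c * F
  )
}

#' Consumer model parameters
#'
#' Collects every parameter of the consumer-resource equations for one model
#' structure. `mu1` is stored with its fitted sign (negative values mean
#' positive density-independent growth, since the growth term is `-mu1`);
#' `mu2` is the density-dependent rate. The simplified structure used for all
#' headline fits sets `alpha = 1` and drops the consumption term from the
#' resource equation (`consumption_feedback = FALSE`), because the full
#' structure is unstable to fitting (the product `alpha * c` is what the data
#' identify).
#'
#' @param fr A [functional_response_spec].
#' @param mu1 Density-independent rate (year^-1), signed as fitted.
#' @param mu2 Density-dependent rate (mouse^-1 year^-1).
#' @param h External seed-loss rate (year^-1), >= 0.
#' @param alpha Demographic efficiency (dimensionless); fixed 1 in the
#'   simplified structure.
#' @param consumption_feedback Whether seed consumption `g(F) M` depletes the
#'   resource equation.
#' @return An object of class `consumer_params`.
#' @export
consumer_params <- function(fr, mu1, mu2, h, alpha = 1,
                            consumption_feedback = FALSE) {
  stopifnot(inherits(fr, "functional_response_spec"))
  if (h < 0) stop("`h` must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  structure(list(fr = fr, mu1 = mu1, mu2 = mu2, h = h, alpha = alpha,
                 consumption_feedback = consumption_feedback),
            class = "consumer_params")
}

#' @export
print.consumer_params <- function(x, ...) {
  cat(sprintf("<consumer_params> %s: c = %.3g%s, mu1 = %.3g, mu2 = %.3g, h = %.3g\n",
              x$fr$kind, x$fr$c,
              if (is.null(x$fr$shape)) "" else sprintf(", shape = %.3g", x$fr$shape),
              x$mu1, x$mu2, x$h))
  cat(sprintf("  alpha = %.3g, consumption feedback %s\n", x$alpha,
              if (x$consumption_feedback) "on" else "off"))
  invisible(x)
}

#' Seed delivery rate within the annual cycle
#'
#' The annual crop `F_year` is delivered at a constant rate over the first
#' quarter of the February-start year (February-April): `F_year / 0.25` while
#' the fractional part of `t` is in `[0, 0.25)`, 0 otherwise. The rate
#' integrates to `F_year` over the year.
#'
#' @param F_year Annual seedfall (seeds m^-2), >= 0.
#' @param t Fractional-year time(s).
#' @return Seed input rate (seeds m^-2 year^-1); vectorised over `t`.
#' @export
seed_input_rate <- function(F_year, t) {
  if (any(F_year < 0)) stop("`F_year` must be >= 0", call. = FALSE)
  frac <- t - floor(t)
  ifelse(frac < 0.25, F_year / 0.25, 0)
}

#' Time derivatives of the consumer-resource system
#'
#' Pure R evaluation of the right-hand side, used for inspection and as a
#' cross-check of the compiled integrator.
#'
#' @param M Consumer abundance (C/100TN), >= 0.
#' @param F Seed availability (seeds m^-2), >= 0.
#' @param t Fractional-year time (drives the seed input window).
#' @param params A [consumer_params].
#' @param F_year Annual seedfall for the current annual cycle.
#' @return Named numeric vector `c(dM, dF)`.
#' @export
derivatives <- function(M, F, t, params, F_year) {
  stopifnot(inherits(params, "consumer_params"))
  if (M < 0 || F < 0) stop("negative state", call. = FALSE)
  g <- functional_response(params$fr, F)
  dM <- (params$alpha * g - params$mu1 - params$mu2 * M) * M
  dF <- seed_input_rate(F_year, t) - params$h * F -
    if (params$consumption_feedback) g * M else 0
  c(dM = dM, dF = dF)
}

#' Simulate the consumer-resource model
#'
#' Forward-simulates the system with a classical 4th-order fixed-step scheme,
#' integrating each quarter as a separate segment so the seed-input
#' discontinuity and the year-start seed reset fall exactly on segment
#' boundaries (adaptive error control is unreliable across such jumps).
#' Consumer abundance is recorded at the start of every quarter, matching
#' quarterly trap-catch sessions; states are floored at 0 after each step.
#'
#' @param params A [consumer_params].
#' @param seedfall [annual_series] of annual seed crops (seeds m^-2) or a
#'   bare numeric vector, one value per simulated year.
#' @param m0 Initial consumer abundance at the first February (C/100TN).
#' @param dt Integration step (years); must be <= 0.025 (ten steps per
#'   quarter). Default 1/400.
#' @param dense Also return the dense trajectory (`t`, `M`, `F`)?
#' @return An object of class `simulation_output`: list with `quarterly` (a
#'   [quarterly_series]), `n_floored` (count of flooring corrections), and,
#'   when `dense = TRUE`, a `trajectory` data frame.
#' @export
simulate_consumer <- function(params, seedfall, m0, dt = 1 / 400,
                              dense = FALSE) {
  stopifnot(inherits(params, "consumer_params"))
  if (m0 < 0) stop("`m0` must be >= 0", call. = FALSE)
  if (dt > 0.25 / 10 + 1e-12) stop("`dt` must be <= 0.025 years", call. = FALSE)
  if (inherits(seedfall, "annual_series")) {
    years <- seedfall$year
    fy <- seedfall$value
  } else {
    fy <- as.numeric(seedfall)
    years <- seq_along(fy)
  }
  if (any(fy < 0)) stop("seedfall must be >= 0", call. = FALSE)
  steps <- max(10L, as.integer(round(0.25 / dt)))
  res <- simulate_rk4_cpp(
    m0, fy, unname(FR_KINDS[params$fr$kind]),
    params$fr$c, params$fr$shape %||% 1, params$alpha,
    params$mu1, params$mu2, params$h,
    params$consumption_feedback, steps, dense
  )
  qs <- quarterly_series(years[res$q_year + 1L],
                         names(QUARTERS)[res$q_quarter + 1L],
                         res$q_M)
  out <- list(quarterly = qs, n_floored = res$n_floored, params = params,
              m0 = m0, dt = 0.25 / steps)
  if (dense) {
    out$trajectory <- data.frame(
      t = res$t + years[1], M = res$M, F = res$F)
  }
  class(out) <- "simulation_output"
  out
}

#' @export
print.simulation_output <- function(x, ...) {
  cat(sprintf("<simulation_output> %d quarters (%d years), dt = %g yr\n",
              nrow(x$quarterly), nrow(x$quarterly) / 4, x$dt))
  if (x$n_floored > 0) {
    cat(sprintf("  %d step(s) floored at 0\n", as.integer(x$n_floored)))
  }
  invisible(x)
}

#' Seed-free equilibrium abundance
#'
#' With no seed input the population equation reduces to logistic growth
#' `dM/dt = (-mu1 - mu2 M) M`, whose carrying capacity is `-mu1 / mu2`: the
#' expected background consumer abundance between masts.
#'
#' @param params A [consumer_params] (or a list with `mu1`, `mu2`).
#' @return Equilibrium abundance (C/100TN).
#' @export
equilibrium_abundance <- function(params) {
  if (params$mu2 == 0) stop("`mu2` = 0: no finite equilibrium", call. = FALSE)
  -params$mu1 / params$mu2
}

#' Seed survival under external loss
#'
#' The fraction of seed remaining after time `t` under exponential loss at
#' rate `h`, absent consumption: `exp(-h t)`. The associated half-life is
#' `log(2) / h`.
#'
#' @param h Seed-loss rate (year^-1), >= 0.
#' @param t Elapsed time (years), >= 0; vectorised.
#' @return Surviving fraction in `[0, 1]`.
#' @export
seed_survival <- function(h, t) {
  if (h < 0 || any(t < 0)) stop("`h` and `t` must be >= 0", call. = FALSE)
  exp(-h * t)
}

#' @rdname seed_survival
#' @export
seed_half_life <- function(h) {
  if (h <= 0) stop("`h` must be > 0", call. = FALSE)
  log(2) / h
}
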