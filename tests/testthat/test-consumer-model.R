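test_that("functional responses evaluate to their closed forms", {
  ivlev <- functional_response_spec("ivlev", c = 6.74, shape = 1.08)
  expect_equal(functional_response(ivlev, 0), 0)
  expect_equal(functional_response(ivlev, 100), 6.74, tolerance = 1e-6)

  h2 <- functional_response_spec("holling2", c = 6.95, shape = 0.67)
  expect_equal(functional_response(h2, 0.67), 6.95 / 2)  # half-saturation

  pw <- functional_response_spec("piecewise", c = 4.41, shape = 1.49)
  expect_equal(functional_response(pw, 1), 4.41)
  expect_equal(functional_response(pw, 10), 4.41 * 1.49)  # capped at c K

  un <- functional_response_spec("uncapped", c = 2)
  expect_equal(functional_response(un, c(0, 3)), c(0, 6))
  expect_error(functional_response(un, -1), "negative")
  expect_error(functional_response_spec("uncapped", c = 2, shape = 1), "no shape")
  expect_error(functional_response_spec("ivlev", c = -1, shape = 1), "positive")
})

test_that("seed input is confined to the first quarter and conserves the crop", {
  expect_equal(seed_input_rate(10, 1980 + 0.1), 40)
  expect_equal(seed_input_rate(10, 1980 + 0.3), 0)
  expect_equal(seed_input_rate(10, 1980 + 0.25), 0)  # window is [0, 0.25)
  total <- integrate(function(t) seed_input_rate(10, t), 0, 0.25)$value +
    integrate(function(t) seed_input_rate(10, t), 0.25, 1)$value
  expect_equal(total, 10, tolerance = 1e-9)
})

test_that("derivatives implement the model equations", {
  p <- ref_params()
  expect_equal(derivatives(0, 5, 0.1, p, 20)[["dM"]], 0)  # extinction absorbing
  # seed-free equilibrium: dM = 0 at M = -mu1/mu2
  eq <- equilibrium_abundance(p)
  expect_equal(derivatives(eq, 0, 0.5, p, 0)[["dM"]], 0, tolerance = 1e-12)
  # without consumption feedback dF is independent of M
  d1 <- derivatives(1, 5, 0.1, p, 20)[["dF"]]
  d2 <- derivatives(50, 5, 0.1, p, 20)[["dF"]]
  expect_equal(d1, d2)
  # with feedback the consumption term appears
  pf <- consumer_params(p$fr, mu1 = p$mu1, mu2 = p$mu2, h = p$h,
                        consumption_feedback = TRUE)
  g <- functional_response(p$fr, 5)
  expect_equal(derivatives(2, 5, 0.1, pf, 20)[["dF"]], d1 - g * 2)
  expect_error(derivatives(-1, 0, 0, p, 0), "negative state")
})

test_that("equilibrium abundance is -mu1/mu2 and scale invariant", {
  expect_equal(equilibrium_abundance(list(mu1 = -1.23, mu2 = 0.76)),
               1.6184211, tolerance = 1e-6)
  expect_equal(equilibrium_abundance(list(mu1 = 0, mu2 = 0.5)), 0)
  expect_equal(equilibrium_abundance(list(mu1 = -2.46, mu2 = 1.52)),
               equilibrium_abundance(list(mu1 = -1.23, mu2 = 0.76)))
  expect_error(equilibrium_abundance(list(mu1 = 1, mu2 = 0)), "mu2")
})

test_that("seed survival is exponential with half-life log(2)/h", {
  expect_equal(seed_survival(9.18, 0.5), exp(-4.59))
  expect_lt(seed_survival(9.18, 0.5), 0.05)
  expect_equal(seed_survival(5, 0), 1)
  expect_equal(seed_survival(log(2), 1), 0.5)
  expect_equal(seed_half_life(log(2)), 1)
})

test_that("with no seed the population follows the logistic closed form", {
  p <- ref_params()
  sim <- simulate_consumer(p, annual_series(1:25, rep(0, 25)), m0 = 1)
  expect_equal(sim$quarterly$value,
               logistic_growth(sim$quarterly$time - 1, 1, p$mu1, p$mu2),
               tolerance = 1e-4)
  # equilibrium start stays put to within 0.1%
  eq <- equilibrium_abundance(p)
  sim_eq <- simulate_consumer(p, annual_series(1:25, rep(0, 25)), m0 = eq)
  expect_true(all(abs(sim_eq$quarterly$value - eq) / eq < 1e-3))
})

test_that("the integrator matches the closed-form resource trajectory", {
  p <- ref_params()  # consumption feedback off: F decouples from M
  sim <- simulate_consumer(p, annual_series(1:3, c(12, 0, 30)), m0 = 1,
                           dense = TRUE)
  tr <- sim$trajectory
  for (y in 1:3) {
    Fy <- c(12, 0, 30)[y]
    # the dense point exactly at a year boundary is the previous year's
    # endpoint (recorded before the seed reset), so compare strictly inside
    at <- tr$t > y & tr$t < y + 1
    expect_equal(tr$F[at], closed_form_F(tr$t[at] - y, Fy, p$h),
                 tolerance = 1e-6)
  }
  # exact seed conservation when nothing removes seed
  p0 <- consumer_params(p$fr, mu1 = p$mu1, mu2 = p$mu2, h = 0)
  sim0 <- simulate_consumer(p0, annual_series(1:1, 17), m0 = 1, dense = TRUE)
  F_end_q1 <- sim0$trajectory$F[which.min(abs(sim0$trajectory$t - 1.25))]
  expect_equal(F_end_q1, 17, tolerance = 1e-9)
})

test_that("states stay non-negative and food resets each year", {
  p <- ref_params()
  fx <- noise_free_fixture()
  sim <- simulate_consumer(p, fx$seedfall, m0 = 1, dense = TRUE)
  expect_true(all(sim$trajectory$M >= 0))
  expect_true(all(sim$trajectory$F >= 0))
  expect_equal(sim$trajectory$F[1], 0)  # year starts from the reset state
})

test_that("a pulse year peaks in its August extraction", {
  p <- ref_params()
  sf <- annual_series(1:7, c(0, 0, 0, 25, 0, 0, 0))
  sim <- simulate_consumer(p, sf, m0 = 1)
  q <- sim$quarterly
  pulse <- q[q$year == 4, ]
  expect_equal(pulse$quarter[which.max(pulse$value)], "Aug")
  # and the annual August peak is the global maximum of the whole series
  expect_equal(q$year[which.max(q$value)], 4L)
})

test_that("annual peak abundance is non-decreasing in the seed crop", {
  for (kind in c("piecewise", "ivlev", "holling2")) {
    fr <- switch(kind,
                 piecewise = functional_response_spec("piecewise", 4.41, 1.49),
                 ivlev = functional_response_spec("ivlev", 6.74, 1.08),
                 holling2 = functional_response_spec("holling2", 6.95, 0.67))
    p <- consumer_params(fr, mu1 = -1.23, mu2 = 0.76, h = 9.48)
    peaks <- vapply(c(0, 1, 2, 5, 10, 20, 50), function(f) {
      max(simulate_consumer(p, annual_series(1:2, c(f, 0)), m0 = 1,
                            dt = 1 / 100)$quarterly$value)
    }, 0)
    expect_true(all(diff(peaks) >= -1e-9))
  }
})

test_that("halving the step changes quarterly extractions by less than 1e-4", {
  p <- ref_params()
  fx <- noise_free_fixture()
  a <- simulate_consumer(p, fx$seedfall, m0 = 1, dt = 1 / 400)
  b <- simulate_consumer(p, fx$seedfall, m0 = 1, dt = 1 / 800)
  expect_lt(max(abs(a$quarterly$value - b$quarterly$value)), 1e-4)
})

test_that("the compiled integrator agrees with an independent ODE solver", {
  p <- consumer_params(functional_response_spec("ivlev", 6.74, 1.08),
                       mu1 = -1.23, mu2 = 0.76, h = 9.48, alpha = 1,
                       consumption_feedback = TRUE)
  sf <- c(15, 0, 4)
  ours <- simulate_consumer(p, annual_series(1:3, sf), m0 = 1.2)
  rhs <- function(t, state, parms) {
    g <- 6.74 * (1 - exp(-1.08 * max(state[2], 0)))
    list(c((g - p$mu1 - p$mu2 * state[1]) * state[1],
           parms$S - p$h * state[2] - g * state[1]))
  }
  state <- c(M = 1.2, F = 0)
  theirs <- numeric(0)
  for (y in 1:3) {
    state[2] <- 0
    for (q in 1:4) {
      theirs <- c(theirs, state[1])
      S <- if (q == 1) sf[y] / 0.25 else 0
      out <- deSolve::lsoda(state, c(0, 0.25), rhs, list(S = S),
                            rtol = 1e-10, atol = 1e-10)
      state <- c(M = out[2, 2], F = out[2, 3])
    }
  }
  expect_equal(ours$quarterly$value, unname(theirs), tolerance = 1e-5)
})

test_that("simulation guards invalid inputs", {
  p <- ref_params()
  expect_error(simulate_consumer(p, annual_series(1:3, c(1, -2, 1)), m0 = 1),
               ">= 0")
  expect_error(simulate_consumer(p, annual_series(1:3, rep(1, 3)), m0 = -1),
               "m0")
  expect_error(simulate_consumer(p, annual_series(1:3, rep(1, 3)), m0 = 1,
                                 dt = 0.05), "dt")
})
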