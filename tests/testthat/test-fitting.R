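# Fitting tests use a reduced optimiser budget (test_fit_config) and a
# coarser, convergence-verified integration step; the data conditions
# (25 years, 100 quarterly observations) stay at the study scale.

test_that("the objective is ~zero at the generating parameters", {
  fx <- noise_free_fixture()
  p <- ref_params()
  expect_lt(rmse_objective(p, fx$quarterly, fx$seedfall), 1e-10)
  # and RMSE is exactly the root mean square residual for a perturbed model
  p2 <- consumer_params(p$fr, mu1 = p$mu1 * 1.5, mu2 = p$mu2, h = p$h)
  r <- rmse_objective(p2, fx$quarterly, fx$seedfall)
  expect_gt(r, 0)
})

test_that("perturbing mu1 away from truth strictly increases the objective", {
  fx <- noise_free_fixture()
  p <- ref_params()
  rmse_at <- vapply(c(0.7, 0.85, 1, 1.15, 1.3), function(f) {
    pp <- consumer_params(p$fr, mu1 = p$mu1 * f, mu2 = p$mu2, h = p$h)
    rmse_objective(pp, fx$quarterly, fx$seedfall)
  }, 0)
  expect_equal(which.min(rmse_at), 3L)
  expect_true(all(diff(rmse_at[1:3]) < 0))
  expect_true(all(diff(rmse_at[3:5]) > 0))
})

test_that("weights act as resampling multiplicities", {
  fx <- noise_free_fixture()
  p <- ref_params()
  n <- nrow(fx$quarterly)
  w <- rep(1, n); w[1] <- 3  # tripling one observation
  r1 <- rmse_objective(p, fx$quarterly, fx$seedfall, weights = w)
  expect_gte(r1, 0)
  expect_error(rmse_objective(p, fx$quarterly, fx$seedfall, weights = w[-1]),
               "one weight per observation")
})

test_that("AICc follows the least-squares formula with the variance counted", {
  # frozen arithmetic oracle: Delta for (1.78, n=100, K=4) vs (1.45, n=100, K=6)
  expect_equal(aicc(1.45, 100, 5), 87.215937, tolerance = 1e-6)
  expect_equal(aicc(1.78, 100, 3) - aicc(1.45, 100, 5), 36.527788,
               tolerance = 1e-6)
  # same rmse and K give Delta = 0; more parameters at fixed rmse cost more
  expect_equal(aicc(1.2, 50, 4), aicc(1.2, 50, 4))
  expect_gt(aicc(1.2, 50, 5), aicc(1.2, 50, 4))
  expect_error(aicc(1, 5, 4), "undefined")
})

test_that("noise-free parameter recovery is within 5% of truth", {
  fx <- noise_free_fixture()
  fit <- fit_consumer_model(fx$quarterly, fx$seedfall, "ivlev",
                            config = test_fit_config())
  truth <- c(c = 6.74, shape = 1.08, mu1 = -1.23, mu2 = 0.76, h = 9.48)
  expect_true(all(abs(fit$estimate - truth) / abs(truth) < 0.05))
  expect_lt(fit$rmse, 0.05)
  expect_equal(fit$k, 5)
  expect_equal(fit$n, 100)
})

test_that("the uncapped response scores worse than the generating family", {
  fx <- noise_free_fixture()
  cfg <- test_fit_config()
  fit_iv <- fit_consumer_model(fx$quarterly, fx$seedfall, "ivlev", config = cfg)
  fit_un <- fit_consumer_model(fx$quarterly, fx$seedfall, "uncapped", config = cfg)
  expect_gt(fit_un$aicc, fit_iv$aicc)
  expect_equal(fit_un$k, 4)  # no shape parameter
  cmp <- compare_models(list(ivlev = fit_iv, uncapped = fit_un))
  expect_equal(cmp$model[1], "ivlev")
  expect_equal(cmp$delta_aicc[1], 0)
  expect_equal(cmp$delta_aicc[2], fit_un$aicc - fit_iv$aicc)
})

test_that("model comparison orders by AICc with deterministic tie-breaks", {
  fx <- noise_free_fixture()
  cfg <- test_fit_config()
  f1 <- fit_consumer_model(fx$quarterly, fx$seedfall, "ivlev", config = cfg)
  expect_equal(compare_models(list(only = f1))$delta_aicc, 0)
  # synthesise ties: clone the fit under two labels, and a worse variant
  f2 <- f1
  f3 <- f1; f3$aicc <- f1$aicc + 20
  cmp <- compare_models(list(b_tie = f2, a_tie = f1, worse = f3))
  expect_equal(cmp$model, c("a_tie", "b_tie", "worse"))
  expect_equal(cmp$delta_aicc, c(0, 0, 20))
  # refuses fits on different data
  f4 <- f1; f4$data_id <- "other"
  expect_error(compare_models(list(f1, f4)), "identical data")
})

test_that("bootstrap draws are deterministic per seed and differ across seeds", {
  fx <- make_fixture(fixture_config(obs_noise_cv = 0.1, seed = 3))
  cfg <- test_fit_config()
  fit <- fit_consumer_model(fx$quarterly, fx$seedfall, "ivlev", config = cfg)
  b1 <- bootstrap_ci(fx$quarterly, fx$seedfall, "ivlev", n_boot = 50,
                     seed = 9, config = cfg, fit = fit)
  b2 <- bootstrap_ci(fx$quarterly, fx$seedfall, "ivlev", n_boot = 50,
                     seed = 9, config = cfg, fit = fit)
  b3 <- bootstrap_ci(fx$quarterly, fx$seedfall, "ivlev", n_boot = 50,
                     seed = 10, config = cfg, fit = fit)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$replicates, b2$replicates)
  expect_false(identical(b1$replicates, b3$replicates))
  expect_error(bootstrap_ci(fx$quarterly, fx$seedfall, "ivlev", n_boot = 10,
                            seed = 1, config = cfg, fit = fit), ">= 50")
})

test_that("bootstrap intervals tighten as observation noise vanishes", {
  cfg <- test_fit_config()
  widths <- vapply(c(0, 0.1, 0.3), function(cv) {
    fx <- make_fixture(fixture_config(obs_noise_cv = cv, seed = 5))
    fit <- fit_consumer_model(fx$quarterly, fx$seedfall, "ivlev", config = cfg)
    bs <- bootstrap_ci(fx$quarterly, fx$seedfall, "ivlev", n_boot = 50,
                       seed = 2, config = cfg, fit = fit)
    mean((bs$ci[, "upper"] - bs$ci[, "lower"]) / abs(bs$point))
  }, 0)
  expect_true(all(diff(widths) > 0))
  expect_lt(widths[1], 0.01)
})

test_that("the full structure is unstable: alpha spreads more than mu2", {
  # the data identify only the product alpha * c, so bootstrap replicates
  # wander along that ridge while mu2 stays pinned
  fx <- make_fixture(fixture_config(obs_noise_cv = 0.1, seed = 8))
  cfg <- test_fit_config(boot_starts = 3)
  fit <- fit_consumer_model(fx$quarterly, fx$seedfall, "ivlev",
                            structure = "full", config = cfg)
  bs <- bootstrap_ci(fx$quarterly, fx$seedfall, "ivlev", structure = "full",
                     n_boot = 50, seed = 4, config = cfg, fit = fit)
  cv <- function(v) sd(v) / abs(mean(v))
  expect_gt(cv(bs$replicates$alpha), cv(bs$replicates$mu2))
})
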