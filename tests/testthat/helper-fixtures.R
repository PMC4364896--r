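# Shared fixtures and independent mini-oracles used across test files.

# Reference Ivlev parameter set (observed-seedfall best fit).
ref_params <- function() default_consumer_params()

# A seedfall_regression object without going through lm(), for closed-form
# prediction tests.
make_regression <- function(a, b, mode = "dT", log_offset = 1) {
  structure(list(a = a, b = b, r_squared = NA_real_, p_value = NA_real_,
                 residual_sd = NA_real_, mode = mode,
                 log_offset = log_offset, n = NA_integer_),
            class = "seedfall_regression")
}

# Closed-form logistic growth for dM/dt = (-mu1 - mu2 M) M with F = 0.
logistic_growth <- function(t, m0, mu1, mu2) {
  r <- -mu1
  K <- -mu1 / mu2
  K / (1 + (K / m0 - 1) * exp(-r * t))
}

# Closed-form resource trajectory for dF/dt = S(t) - h F with F(0) = 0 and
# S constant over [0, 0.25), zero after (consumption feedback off). Valid
# within one annual cycle; t is the within-year offset.
closed_form_F <- function(t, F_year, h) {
  S <- F_year / 0.25
  Fq <- if (h == 0) S * 0.25 else S / h * (1 - exp(-h * 0.25))
  ifelse(t < 0.25,
         if (h == 0) S * t else S / h * (1 - exp(-h * t)),
         Fq * exp(-h * (t - 0.25)))
}

# Brute-force mast interval statistics by direct enumeration, independent of
# the package implementation.
brute_interval_stats <- function(flags) {
  n <- length(flags)
  singles <- 0L; doubles <- 0L
  for (i in seq_len(n)) {
    if (flags[i]) singles <- singles + 1L
    if (i < n && flags[i] && flags[i + 1]) doubles <- doubles + 1L
  }
  idx <- which(flags)
  gaps <- if (length(idx) >= 2) {
    g <- numeric(length(idx) - 1)
    for (j in 2:length(idx)) g[j - 1] <- idx[j] - idx[j - 1]
    mean(g)
  } else NA_real_
  list(prop_single = singles / n, prop_double = doubles / n, mean_gap = gaps)
}

# Cheap fitting configuration for tests that exercise the optimiser many
# times: fewer starts and a coarser (still convergent) integration step.
test_fit_config <- function(...) {
  defaults <- list(n_starts = 6, boot_starts = 1, boot_maxit = 250, dt = 1 / 100)
  do.call(fit_config, utils::modifyList(defaults, list(...)))
}

# Noise-free synthetic observation set at the reference parameters.
noise_free_fixture <- function(n_years = 25, seed = 1) {
  make_fixture(fixture_config(obs_noise_cv = 0, seed = seed,
                              n_years_quarterly = n_years))
}
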