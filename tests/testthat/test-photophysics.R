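pp <- photophys_params(k_c = 0.05, phi_eq = 0.8, k_740 = 2)

test_that("photoconversion rates are linear in intensity with the fixed 80:20 split", {
  expect_identical(rate_on_to_off(pp, 0), 0)
  expect_equal(rate_on_to_off(pp, 100), 1.0) # (1 - 0.8) * 0.05 * 100
  expect_equal(rate_off_to_on(pp, 100), 4.0)
  # linearity through the origin
  for (I in c(1, 7, 50)) {
    expect_equal(rate_on_to_off(pp, 2 * I) - rate_on_to_off(pp, I),
                 rate_on_to_off(pp, I))
  }
  expect_error(rate_on_to_off(pp, -1), "non-negative")
  expect_error(rate_on_to_off(pp, 101), "100")
})

test_that("photoequilibrium ON fraction is phi_eq at every positive intensity", {
  expect_equal(on_fraction_steady_state(pp, 2), 0.80)
  expect_equal(on_fraction_steady_state(pp, 100), 0.80)
  expect_equal(unique(on_fraction_steady_state(pp, c(1, 5, 33, 100))), 0.80)
  expect_error(on_fraction_steady_state(pp, 0), "no photoequilibrium in dark")
})

test_that("deterministic trajectories: fixed point, dark stability, 740 nm shut-off", {
  # photoequilibrium is a fixed point at any intensity
  pr <- protocol_constant_660(13, 200)
  traj <- simulate_on_fraction(pp, pr, f0 = 0.8, times = seq(0, 200, 20))
  expect_equal(traj$on_fraction, rep(0.8, 11))
  # dark holds the state for the full experiment duration
  dark <- illumination_protocol("dark", 600)
  traj <- simulate_on_fraction(pp, dark, f0 = 0.8, times = c(0, 60, 600))
  expect_equal(traj$on_fraction, rep(0.8, 3))
  # a 1 s full-intensity 740 nm pulse empties the ON state
  pr740 <- illumination_protocol(c("740", "dark"), c(1, 100))
  traj <- simulate_on_fraction(pp, pr740, f0 = 0.8, times = c(1, 50))
  expect_lt(max(traj$on_fraction), 0.15) # e^-2 with default k_740
  pp_fast <- photophys_params(0.05, k_740 = 6)
  traj <- simulate_on_fraction(pp_fast, pr740, f0 = 0.8, times = c(1, 50))
  expect_lt(max(traj$on_fraction), 0.01)
  expect_error(simulate_on_fraction(pp, dark, f0 = 0.8, times = 700),
               "within the protocol")
})

test_that("trajectories are continuous across segment boundaries", {
  pr <- illumination_protocol(c("660", "dark", "660"), c(5, 10, 5), c(100, 0, 20))
  eps <- 1e-9
  for (tb in c(5, 15)) {
    f <- simulate_on_fraction(pp, pr, f0 = 0.1, times = c(tb - eps, tb, tb + eps))
    expect_lt(diff(range(f$on_fraction)), 1e-6)
  }
})

test_that("pulse-trapped ON fraction: zero, saturation, analytic half-saturation", {
  expect_equal(pulse_trapped_on_fraction(pp, 100, 0), 0)
  expect_equal(pulse_trapped_on_fraction(pp, 100, 1e6), 0.80)
  # k_c * I = 0.1 s^-1 at I = 2; half-saturation at ln 2 / 0.1
  expect_equal(pulse_trapped_on_fraction(pp, 2, log(2) / 0.1), 0.40)
  # monotone increasing in duration
  d <- seq(0, 60, 1)
  expect_true(all(diff(pulse_trapped_on_fraction(pp, 10, d)) > 0))
  expect_error(pulse_trapped_on_fraction(pp, 10, -1), "non-negative")
  # exact agreement with the piecewise simulation at the end of the pulse
  for (d in c(0.5, 2, 10)) {
    pr <- protocol_pulse_trap(32, d)
    f_end <- simulate_on_fraction(pp, pr, f0 = 0, times = d)$on_fraction
    expect_equal(pulse_trapped_on_fraction(pp, 32, d), f_end)
  }
})

test_that("stochastic per-molecule oracle matches the closed forms", {
  # dark: empirical fraction equals the initial assignment exactly
  dark <- illumination_protocol("dark", 100)
  tr <- stochastic_switch_oracle(pp, dark, n_molecules = 1000,
                                 times = c(0, 100), f0 = 0.37, seed = 4)
  expect_equal(tr$on_fraction, rep(0.37, 2))
  # long constant 660 nm: photoequilibrium within 3 binomial SEs
  n <- 2e4
  pr <- protocol_constant_660(20, 60)
  tr <- stochastic_switch_oracle(pp, pr, n, times = 60, f0 = 0, seed = 11)
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(tr$on_fraction - 0.8), 3 * se)
  # pointwise agreement with the deterministic trajectory on a pulse-trap
  # protocol crossing a segment boundary
  pr <- protocol_pulse_trap(100, pulse_s = 0.4, dark_s = 20)
  times <- c(0.1, 0.25, 0.4, 5, 20)
  emp <- stochastic_switch_oracle(pp, pr, n, times = times, f0 = 0, seed = 12)
  det <- simulate_on_fraction(pp, pr, f0 = 0, times = times)
  se <- sqrt(pmax(det$on_fraction * (1 - det$on_fraction), 1e-4) / n)
  expect_true(all(abs(emp$on_fraction - det$on_fraction) < 3 * se + 1e-3))
  # reproducibility
  tr2 <- stochastic_switch_oracle(pp, pr, 500, times = times, f0 = 0, seed = 12)
  tr3 <- stochastic_switch_oracle(pp, pr, 500, times = times, f0 = 0, seed = 12)
  expect_identical(tr2, tr3)
})

test_that("first-order association rate fit inverts noiseless data and flags degenerate input", {
  t <- seq(0, 300, by = 10)
  y <- 2 * (1 - exp(-0.05 * t))
  fit <- fit_first_order_rate(t, y)
  expect_lt(abs(fit$k - 0.05) / 0.05, 1e-6)
  expect_equal(fit$y_max, 2, tolerance = 1e-6)
  expect_error(fit_first_order_rate(t, rep(3, length(t))), "constant")
  expect_error(fit_first_order_rate(t, 5 - 0.01 * t), "converge|identifiable")
})

test_that("first-order rate recovery is within 2 SE on most noisy replicates", {
  t <- seq(0, 300, by = 10)
  mu <- 2 * (1 - exp(-0.05 * t))
  set.seed(42)
  hits <- vapply(1:50, function(i) {
    y <- mu + rnorm(length(t), 0, 0.02 * 2)
    fit <- fit_first_order_rate(t, y)
    abs(fit$k - 0.05) <= 2 * fit$se_k
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
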