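p <- default_model_params()

test_that("effective off-rate is affine in intensity with the dark limit k_off", {
  expect_equal(effective_off_rate(p, 0), p$binding$k_off)
  for (I in c(4, 25, 50)) {
    expect_equal(effective_off_rate(p, 2 * I) - effective_off_rate(p, 0),
                 2 * (effective_off_rate(p, I) - effective_off_rate(p, 0)))
  }
})

test_that("complex half-life: definition, monotonicity, fitted-regime anchors", {
  p60 <- model_params(k_c = 0.02, k_off = log(2) / 60, K0 = 100, tau_kpr = 5, A = 1)
  expect_equal(complex_half_life(p60, 0), 60)
  hl <- complex_half_life(p, seq(0, 100, 5))
  expect_true(all(diff(hl) < 0))
  # the default truth is anchored to the 40 s (at 2%) -> 2 s (at 100%) span
  expect_equal(complex_half_life(p, 2), 40)
  expect_equal(complex_half_life(p, 100), 2)
})

test_that("effective Kd is K0 in the dark and doubles when k_i equals k_off", {
  expect_equal(effective_Kd(p, 0), p$binding$K0)
  # construct params with k_i(50) = k_off exactly
  q <- model_params(k_c = 0.002, k_off = 0.2 * 0.002 * 50, K0 = 300,
                    tau_kpr = 8, A = 1)
  expect_equal(effective_Kd(q, 50), 2 * 300)
  # affinity falls with intensity -> bound signal decreases
  b <- predicted_binding(p, c(0, 2, 8, 32, 100), 20)
  expect_true(all(diff(b) < 0))
})

test_that("steady-state occupancy: saturation, half-saturation, kinetic integration oracle", {
  expect_gt(steady_state_occupancy(p, 10, 1e9), 0.9999)
  # half-saturation when ON-ligand equals K_eff
  I <- 16
  L_half <- effective_Kd(p, I) / p$photophys$phi_eq
  expect_equal(steady_state_occupancy(p, I, L_half), 0.5)
  expect_error(steady_state_occupancy(p, 10, -5), "non-negative")
  # independent oracle: RK4 integration of db/dt = kon*Lon*(1-b) - keff*b
  kon <- p$binding$k_off / p$binding$K0
  for (I in c(0, 8, 64)) {
    keff <- effective_off_rate(p, I)
    Lon <- p$photophys$phi_eq * 20
    f <- function(b) kon * Lon * (1 - b) - keff * b
    b <- 0; h <- 0.01
    for (i in seq_len(400000)) {
      k1 <- f(b); k2 <- f(b + h / 2 * k1); k3 <- f(b + h / 2 * k2)
      k4 <- f(b + h * k3)
      b <- b + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    expect_equal(steady_state_occupancy(p, I, 20), b, tolerance = 1e-8)
  }
})

test_that("KPR survival: occupancy limit, half-maximum identity, lifetime Monte Carlo", {
  expect_identical(kpr_survival(0, 0.3), 1)
  # survival is exactly 1/2 when the complex half-life equals the KPR time
  tau <- 8
  expect_equal(kpr_survival(tau, log(2) / tau), 0.5)
  # Monte-Carlo lifetime oracle
  set.seed(21)
  keff <- 0.11; n <- 1e5
  frac <- mean(rexp(n, keff) > tau)
  se <- sqrt(frac * (1 - frac) / n)
  expect_lt(abs(frac - kpr_survival(tau, keff)), 3 * se)
})

test_that("steady-state calcium: dark limit, monotone decay, null-model reduction", {
  # I -> 0+ limit equals the dark-trapped maximum
  lim <- p$obs$A * steady_state_occupancy(p, 0, 20) *
    exp(-p$binding$k_off * p$kpr$tau_kpr)
  expect_equal(calcium_steady_state(p, 1e-12, 20), lim, tolerance = 1e-9)
  expect_true(all(diff(calcium_steady_state(p, seq(0, 100, 2), 20)) < 0))
  # tau = 0 reduces bit-level to the pure occupancy readout
  p0 <- model_params(p$photophys$k_c, p$binding$k_off, p$binding$K0, 0, p$obs$A)
  I <- c(0, 2, 7, 31, 100)
  expect_identical(calcium_steady_state(p0, I, 20),
                   p0$obs$A * steady_state_occupancy(p0, I, 20))
  # KPR only attenuates
  expect_true(all(calcium_steady_state(p, I, 20) <=
                    p$obs$A * steady_state_occupancy(p, I, 20)))
})

test_that("log-ratio of KPR to occupancy predictions is affine in intensity", {
  I <- seq(2, 100, length.out = 25)
  p0 <- model_params(p$photophys$k_c, p$binding$k_off, p$binding$K0, 0, p$obs$A)
  lr <- log(calcium_steady_state(p, I, 20)) - log(calcium_steady_state(p0, I, 20))
  cf <- coef(lm(lr ~ I))
  slope_expected <- -p$kpr$tau_kpr * (1 - p$photophys$phi_eq) * p$photophys$k_c
  expect_equal(unname(cf[2]), slope_expected, tolerance = 1e-10)
  expect_lt(max(abs(residuals(lm(lr ~ I)))), 1e-10)
})

test_that("pulse response: zero at d = 0, saturates at the dark-trapped response, composes", {
  expect_equal(calcium_after_pulse(p, 100, 0, 20), 0)
  expect_equal(calcium_after_pulse(p, 100, 1e7, 20),
               calcium_steady_state(p, 0, 20))
  d <- c(0, 0.5, 1, 2, 5, 10, 20, 30)
  y <- calcium_after_pulse(p, 32, d, 6.3)
  expect_true(all(diff(y) > 0))
  expect_error(calcium_after_pulse(p, 32, -1, 20), "non-negative")
  # compositional consistency: equals the dark steady state at the trapped
  # ON-ligand concentration
  for (d in c(0.5, 3, 12)) {
    f <- pulse_trapped_on_fraction(p$photophys, 32, d)
    L_equiv <- 20 * f / p$photophys$phi_eq
    expect_equal(calcium_after_pulse(p, 32, d, 20),
                 calcium_steady_state(p, 0, L_equiv))
  }
})

test_that("predictions are invariant under joint rescaling of K0 and ligand", {
  c_scale <- 3.7
  p2 <- model_params(p$photophys$k_c, p$binding$k_off,
                     c_scale * p$binding$K0, p$kpr$tau_kpr, p$obs$A)
  I <- c(0, 5, 40)
  expect_equal(calcium_steady_state(p, I, 20),
               calcium_steady_state(p2, I, c_scale * 20))
  expect_equal(calcium_after_pulse(p, 100, 4, 20),
               calcium_after_pulse(p2, 100, 4, c_scale * 20))
})

test_that("threshold intensity: closed-form null-model oracle, KPR monotonicity, regime", {
  # tau = 0: occupancy halves where K_eff(I) = 2 K_eff(0) + phi_eq * L
  p0 <- model_params(p$photophys$k_c, p$binding$k_off, p$binding$K0, 0, p$obs$A)
  L <- 20
  I_closed <- (p0$binding$K0 + p0$photophys$phi_eq * L) * p0$binding$k_off /
    ((1 - p0$photophys$phi_eq) * p0$photophys$k_c * p0$binding$K0)
  expect_equal(threshold_intensity(p0, L), I_closed, tolerance = 1e-6)
  # larger KPR time -> smaller threshold
  taus <- c(0, 4, 8, 16)
  thr <- vapply(taus, function(tv) {
    threshold_intensity(model_params(p$photophys$k_c, p$binding$k_off,
                                     p$binding$K0, tv, p$obs$A), L)
  }, numeric(1))
  expect_true(all(diff(thr) < 0))
  # default truth: threshold ~3%, approximately ligand-independent
  th <- vapply(c(6.3, 20, 100), function(L) threshold_intensity(p, L), numeric(1))
  expect_true(all(th > 2 & th < 4))
  expect_lt(diff(range(th)) / mean(th), 0.25)
})
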