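truth <- default_truth
data <- default_bundle

test_that("negative log-likelihood matches a direct-summation oracle", {
  p <- truth$params
  # naive two-loop reimplementation of the concentrated objective
  naive_rss <- function(df, pred_fun, value_col) {
    rss <- 0
    for (i in seq_len(nrow(df))) {
      rss <- rss + (df[[value_col]][i] - pred_fun(df[i, ]))^2
    }
    rss
  }
  rss_c <- naive_rss(data$calcium, function(r)
    calcium_steady_state(p, r$intensity_percent, r$ligand_nM), "calcium_au")
  rss_k <- naive_rss(data$kinetics, function(r)
    calcium_after_pulse(p, r$intensity_percent, r$duration_s, r$ligand_nM),
    "calcium_au")
  # binding scale profiled by least squares through the origin
  occ <- steady_state_occupancy(p, data$binding$intensity_percent,
                                data$binding$ligand_nM)
  s_hat <- coef(lm(data$binding$bound_mfi ~ 0 + occ))[[1]]
  rss_b <- sum((data$binding$bound_mfi - s_hat * occ)^2)
  n <- vapply(data, nrow, integer(1))
  oracle <- n[["calcium"]] / 2 * log(rss_c / n[["calcium"]]) +
    n[["binding"]] / 2 * log(rss_b / n[["binding"]]) +
    n[["kinetics"]] / 2 * log(rss_k / n[["kinetics"]])
  expect_equal(negative_log_likelihood(p, data), oracle, tolerance = 1e-10)
  # fixed-sigma form
  oracle_fixed <- (rss_c + rss_b + rss_k) / (2 * 0.1^2)
  expect_equal(negative_log_likelihood(p, data, error_model = "fixed",
                                       sigma = 0.1), oracle_fixed,
               tolerance = 1e-10)
})

test_that("the objective is minimal at the truth on noiseless data", {
  p <- noiseless_truth$params
  v0 <- negative_log_likelihood(p, noiseless_bundle, error_model = "fixed")
  expect_lt(v0, 1e-12)
  for (fac in c(0.9, 1.1)) {
    p2 <- model_params(p$photophys$k_c * fac, p$binding$k_off,
                       p$binding$K0, p$kpr$tau_kpr, p$obs$A)
    expect_gt(negative_log_likelihood(p2, noiseless_bundle,
                                      error_model = "fixed"), v0)
  }
})

test_that("noiseless joint fit recovers all five parameters to <= 1%", {
  fit <- fit_model(noiseless_bundle, "kpr", n_starts = 10, seed = 2,
                   error_model = "fixed")
  true_p <- structural_params(noiseless_truth$params)
  expect_true(all(abs(fit$estimates - true_p) / true_p <= 0.01))
  # k_c is pinned hardest by the pulse curves
  expect_lt(abs(fit$estimates[["k_c"]] - true_p[["k_c"]]) / true_p[["k_c"]],
            0.001)
})

test_that("a coarse grid search around the optimum finds nothing better", {
  fit <- fit_model(data, "kpr", n_starts = 8, seed = 1)
  e <- fit$estimates
  grids <- lapply(names(e), function(nm) {
    if (nm == "tau_kpr") pmax(e[[nm]] + seq(-2, 2, length.out = 5), 0)
    else e[[nm]] * exp(seq(-0.2, 0.2, length.out = 5))
  })
  names(grids) <- names(e)
  gr <- expand.grid(grids)
  vals <- apply(gr, 1, function(row) {
    negative_log_likelihood(model_params(row[["k_c"]], row[["k_off"]],
                                         row[["K0"]], row[["tau_kpr"]],
                                         row[["A"]]), data)
  })
  expect_gte(min(vals), fit$objective - 1e-6)
})

test_that("fit respects nesting and ties are reproducible under a fixed seed", {
  lrt <- likelihood_ratio_test(data, n_starts = 6, seed = 3)
  expect_gte(lrt$fit_kpr$logLik, lrt$fit_null$logLik - 1e-9)
  expect_identical(lrt$fit_null$estimates[["tau_kpr"]], 0)
  fit_a <- fit_model(data, "kpr", n_starts = 5, seed = 9)
  fit_b <- fit_model(data, "kpr", n_starts = 5, seed = 9)
  expect_identical(fit_a$estimates, fit_b$estimates)
})

test_that("boundary-mixture p-values: conventions and chi-square tail oracle", {
  expect_equal(lrt_pvalue(0)$p_boundary, 1)
  expect_equal(lrt_pvalue(-1e-12)$p_boundary, 1)
  # independent tail oracle: P(chi2_1 >= D) = 2 * (1 - Phi(sqrt(D)))
  for (D in c(0.5, 2, 7.3, 20)) {
    oracle <- 2 * (1 - pnorm(sqrt(D)))
    expect_lt(abs(lrt_pvalue(D)$p_boundary - 0.5 * oracle), 1e-10)
    expect_lt(abs(lrt_pvalue(D)$p_chisq1 - oracle), 1e-10)
  }
})

test_that("model predictions are invariant to the (k_on, k_off) reparameterization", {
  p <- truth$params
  # independent route: build predictions from k_on = k_off / K0 directly
  k_on <- p$binding$k_off / p$binding$K0
  I <- c(0, 4, 33, 100)
  keff <- p$binding$k_off + (1 - p$photophys$phi_eq) * p$photophys$k_c * I
  Lon <- p$photophys$phi_eq * 20
  occ_via_kon <- k_on * Lon / (k_on * Lon + keff)
  expect_equal(steady_state_occupancy(p, I, 20), occ_via_kon,
               tolerance = 1e-12)
})

test_that("profile likelihood is internally consistent and brackets the estimate", {
  fit <- fit_model(data, "kpr", n_starts = 8, seed = 1)
  prof <- profile_likelihood_tau(data, fit = fit, seed = 1)
  # profile maximum equals the joint maximum
  i_hat <- which.min(abs(prof$profile$tau_kpr - prof$tau_hat))
  expect_equal(prof$profile$loglik[i_hat], fit$logLik, tolerance = 1e-6)
  expect_true(all(prof$profile$delta2 > -1e-6))
  # CI contains the best estimate and its endpoints sit on the threshold
  expect_gt(prof$tau_hat, prof$ci[["lower"]])
  expect_lt(prof$tau_hat, prof$ci[["upper"]])
  for (tau_end in prof$ci) {
    sub <- fit_model(data, "kpr", n_starts = 6, seed = 4,
                     bounds = kpr_bounds(tau_kpr = tau_end + c(0, 1e-6)))
    expect_equal(2 * (sub$objective - fit$objective), prof$threshold,
                 tolerance = 0.05)
  }
  # an upper endpoint beyond the grid raises a widen-grid error
  expect_error(profile_likelihood_tau(data, fit = fit,
                                      tau_grid = c(0.5, 1, 2)),
               "widen the tau grid")
})

test_that("dataset validation names the missing column", {
  bad <- data
  bad$calcium$calcium_au <- NULL
  expect_error(fit_model(bad, "kpr", n_starts = 1),
               "calcium_au")
  expect_error(fit_model(list(), "kpr"), "no datasets")
  expect_error(fit_model(list(junk = data$calcium), "kpr"), "unknown dataset")
})

test_that("tau * k_off is recovered from noiseless steady-state data even though tau is not", {
  ss <- noiseless_bundle[c("calcium", "binding")]
  fit <- fit_model(ss, "kpr", n_starts = 12, seed = 5, error_model = "fixed")
  true_prod <- noiseless_truth$params$kpr$tau_kpr *
    noiseless_truth$params$binding$k_off
  est_prod <- fit$estimates[["tau_kpr"]] * fit$estimates[["k_off"]]
  expect_lt(abs(est_prod - true_prod) / true_prod, 0.02)
})
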