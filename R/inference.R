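#' Optimizer bounds for the five structural parameters
#'
#' Box bounds for the multi-start bounded optimization, on the natural
#' scales. The search itself runs in log coordinates for all parameters
#' except the KPR time, whose 0 boundary is the occupancy null.
#'
#' @param k_c,k_off,K0,tau_kpr,A Two-element `c(lower, upper)` vectors.
#' @return A list with named `lower` and `upper` vectors.
#' @export
kpr_bounds <- function(k_c = c(1e-4, 1), k_off = c(1e-3, 1),
                       K0 = c(0.1, 1e3), tau_kpr = c(0, 120),
                       A = c(1e-2, 1e2)) {
  list(lower = c(k_c = k_c[1], k_off = k_off[1], K0 = K0[1],
                 tau_kpr = tau_kpr[1], A = A[1]),
       upper = c(k_c = k_c[2], k_off = k_off[2], K0 = K0[2],
                 tau_kpr = tau_kpr[2], A = A[2]))
}

# ---- dataset validation ----------------------------------------------------

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("the ", what, " dataset is missing column(s): ",
         paste(miss, collapse = ", "))
}

.validate_bundle <- function(data) {
  if (inherits(data, "data.frame"))
    stop("'data' must be a list with elements among 'calcium', 'binding', 'kinetics'")
  known <- c("calcium", "binding", "kinetics")
  extra <- setdiff(names(data), known)
  if (length(extra))
    stop("unknown dataset element(s): ", paste(extra, collapse = ", "))
  data <- data[intersect(known, names(data))]
  data <- Filter(Negate(is.null), data)
  if (length(data) == 0) stop("no datasets supplied")
  if (!is.null(data$calcium)) {
    .require_cols(data$calcium, c("intensity_percent", "ligand_nM", "calcium_au"),
                  "steady-state calcium")
    with(data$calcium, {
      if (any(intensity_percent < 0 | intensity_percent > 100))
        stop("calcium: intensities must lie in [0, 100]")
      if (any(ligand_nM <= 0)) stop("calcium: ligand concentrations must be positive")
      if (length(unique(intensity_percent)) < 2)
        stop("calcium: need at least 2 distinct intensities")
    })
  }
  if (!is.null(data$binding)) {
    .require_cols(data$binding, c("intensity_percent", "ligand_nM", "bound_mfi"),
                  "binding")
    with(data$binding, {
      if (any(intensity_percent < 0 | intensity_percent > 100))
        stop("binding: intensities must lie in [0, 100]")
      if (any(ligand_nM <= 0)) stop("binding: ligand concentrations must be positive")
      if (length(unique(intensity_percent)) < 2)
        stop("binding: need at least 2 distinct intensities")
    })
  }
  if (!is.null(data$kinetics)) {
    .require_cols(data$kinetics,
                  c("duration_s", "intensity_percent", "ligand_nM", "calcium_au"),
                  "pulse-kinetics")
    with(data$kinetics, {
      if (any(duration_s < 0)) stop("kinetics: pulse durations must be >= 0")
      if (any(intensity_percent < 0 | intensity_percent > 100))
        stop("kinetics: intensities must lie in [0, 100]")
      if (any(ligand_nM <= 0)) stop("kinetics: ligand concentrations must be positive")
    })
  }
  data
}

# ---- likelihood ------------------------------------------------------------

# Closure factory: precomputes the design vectors once, then evaluates the
# (concentrated) Gaussian objective cheaply. The binding scale s_bind is
# profiled by linear least squares through the origin at every evaluation;
# with error_model = "profiled" each dataset's noise variance is profiled
# analytically (sigma^2 = RSS/n) so the objective reduces to
# sum_d n_d/2 * log(RSS_d / n_d) (constants dropped).
.make_model_nll <- function(data, phi_eq = 0.8,
                            error_model = c("profiled", "fixed"),
                            sigma = 0.1) {
  error_model <- match.arg(error_model)
  data <- .validate_bundle(data)
  has_c <- !is.null(data$calcium)
  has_b <- !is.null(data$binding)
  has_k <- !is.null(data$kinetics)
  if (has_c) {
    I_c <- as.numeric(data$calcium$intensity_percent)
    L_c <- as.numeric(data$calcium$ligand_nM)
    y_c <- as.numeric(data$calcium$calcium_au)
  }
  if (has_b) {
    I_b <- as.numeric(data$binding$intensity_percent)
    L_b <- as.numeric(data$binding$ligand_nM)
    y_b <- as.numeric(data$binding$bound_mfi)
  }
  if (has_k) {
    d_k <- as.numeric(data$kinetics$duration_s)
    I_k <- as.numeric(data$kinetics$intensity_percent)
    L_k <- as.numeric(data$kinetics$ligand_nM)
    y_k <- as.numeric(data$kinetics$calcium_au)
  }

  detail <- function(p) {
    k_c <- p[[1]]; k_off <- p[[2]]; K0 <- p[[3]]; tau <- p[[4]]; A <- p[[5]]
    out <- list()
    if (has_c) {
      keff <- k_off + (1 - phi_eq) * k_c * I_c
      Lon <- phi_eq * L_c
      pred <- A * Lon / (Lon + K0 * keff / k_off) * exp(-keff * tau)
      out$calcium <- list(pred = pred, rss = sum((y_c - pred)^2),
                          n = length(y_c))
    }
    if (has_b) {
      keff <- k_off + (1 - phi_eq) * k_c * I_b
      Lon <- phi_eq * L_b
      occ <- Lon / (Lon + K0 * keff / k_off)
      s_hat <- sum(y_b * occ) / sum(occ^2)
      pred <- s_hat * occ
      out$binding <- list(pred = pred, rss = sum((y_b - pred)^2),
                          n = length(y_b), s_bind = s_hat)
    }
    if (has_k) {
      f <- phi_eq * (1 - exp(-k_c * I_k * d_k))
      Lon <- L_k * f
      pred <- A * Lon / (Lon + K0) * exp(-k_off * tau)
      out$kinetics <- list(pred = pred, rss = sum((y_k - pred)^2),
                           n = length(y_k))
    }
    out
  }

  value <- function(p) {
    det <- detail(p)
    rss <- vapply(det, function(d) d$rss, numeric(1))
    n <- vapply(det, function(d) d$n, numeric(1))
    if (any(!is.finite(rss))) return(Inf)
    if (error_model == "profiled")
      sum(n / 2 * log(pmax(rss, n * 1e-20) / n))
    else
      sum(rss) / (2 * sigma^2)
  }

  loglik <- function(p) {
    det <- detail(p)
    rss <- vapply(det, function(d) d$rss, numeric(1))
    n <- vapply(det, function(d) d$n, numeric(1))
    if (error_model == "profiled")
      -sum(n / 2 * (log(2 * pi * pmax(rss, n * 1e-20) / n) + 1))
    else
      -sum(rss) / (2 * sigma^2) - sum(n) / 2 * log(2 * pi * sigma^2)
  }

  list(value = value, loglik = loglik, detail = detail,
       error_model = error_model, sigma = sigma,
       n = c(calcium = if (has_c) length(y_c) else 0L,
             binding = if (has_b) length(y_b) else 0L,
             kinetics = if (has_k) length(y_k) else 0L))
}

#' Joint negative log-likelihood of the model on a dataset bundle
#'
#' Independent Gaussian residuals per data point, with the binding scale
#' profiled by linear least squares at every evaluation. With
#' `error_model = "profiled"` (default) each dataset's noise variance is
#' profiled analytically, giving the concentrated objective
#' `sum_d n_d/2 log(RSS_d/n_d)` up to an additive constant; with `"fixed"`
#' the objective is `sum RSS / (2 sigma^2)` plus its normalizing constant.
#' The fixed-sigma form is the one to use on noiseless data, where profiled
#' variances degenerate.
#'
#' @param params A [model_params()] object.
#' @param data Named list with any of `calcium`, `binding`, `kinetics`
#'   tibbles (schemas as produced by [generate_dataset_bundle()]).
#' @param error_model `"profiled"` or `"fixed"`.
#' @param sigma Noise standard deviation for `error_model = "fixed"`.
#' @return The negative log-likelihood (up to a constant for `"profiled"`).
#' @export
negative_log_likelihood <- function(params, data,
                                    error_model = c("profiled", "fixed"),
                                    sigma = 0.1) {
  stopifnot(inherits(params, "model_params"))
  nll <- .make_model_nll(data, phi_eq = params$photophys$phi_eq,
                         error_model = match.arg(error_model), sigma = sigma)
  nll$value(structural_params(params))
}

# ---- model fitting ---------------------------------------------------------

#' Fit the photoswitching-binding-KPR model by maximum likelihood
#'
#' Multi-start bounded optimization (L-BFGS-B over log coordinates, Latin
#' hypercube starts) of the five structural parameters `k_c`, `k_off`, `K0`,
#' `tau_kpr`, `A`; the `"occupancy"` variant fixes `tau_kpr = 0` (the
#' no-proofreading null). Deterministic for a fixed seed. Ties between
#' starts are broken by the lower objective, then the lower KPR time.
#'
#' @inheritParams negative_log_likelihood
#' @param variant `"kpr"` (default) or `"occupancy"`.
#' @param n_starts Number of Latin-hypercube starts.
#' @param seed Integer seed controlling the starts.
#' @param bounds Parameter box from [kpr_bounds()].
#' @param phi_eq Fixed photoequilibrium ON fraction.
#' @param extra_starts Optional list of named 5-vectors
#'   `(k_c, k_off, K0, tau_kpr, A)` used as additional starts.
#' @param control Passed to [stats::optim()].
#' @return An object of class `kpr_fit`: list with `estimates` (named
#'   5-vector), `s_bind`, `sigma_hat`, `logLik`, `objective`, `convergence`,
#'   `variant`, `n_starts`, `seed`.
#' @export
fit_model <- function(data, variant = c("kpr", "occupancy"), n_starts = 20,
                      seed = 1, error_model = c("profiled", "fixed"),
                      sigma = 0.1, bounds = kpr_bounds(), phi_eq = 0.8,
                      extra_starts = NULL, control = list(maxit = 500)) {
  variant <- match.arg(variant)
  error_model <- match.arg(error_model)
  nll <- .make_model_nll(data, phi_eq = phi_eq, error_model = error_model,
                         sigma = sigma)
  lower_th <- .theta_of_p(bounds$lower)
  upper_th <- .theta_of_p(bounds$upper)
  free <- if (variant == "kpr") 1:5 else c(1:3, 5)
  theta_fixed <- .theta_of_p(pmax(bounds$lower, 1e-12))
  theta_fixed[4] <- 0 # tau for the occupancy variant

  # Starts: LHS over the box (tau capped at 60 s for starting values only),
  # the box midpoint, and any user-supplied extra starts.
  start_upper <- upper_th
  start_upper[4] <- min(upper_th[4], 60)
  starts <- .with_seed(seed, .lhs_starts(n_starts, lower_th[free],
                                         start_upper[free]))
  starts <- c(starts, list((lower_th[free] + start_upper[free]) / 2))
  for (es in extra_starts)
    starts <- c(starts, list(.theta_of_p(es)[free]))

  best <- .fit_sub(nll$value, theta_fixed, free, starts, lower_th, upper_th,
                   control)
  # Polish the winner once from its own solution.
  best <- .fit_sub(nll$value, theta_fixed, free, list(best$theta[free]),
                   lower_th, upper_th, control)

  det <- nll$detail(best$p)
  sigma_hat <- vapply(det, function(d) sqrt(d$rss / d$n), numeric(1))
  structure(list(
    estimates = best$p,
    s_bind = if (!is.null(det$binding)) det$binding$s_bind else NA_real_,
    sigma_hat = sigma_hat,
    logLik = nll$loglik(best$p),
    objective = best$value,
    convergence = best$convergence,
    variant = variant, error_model = error_model, sigma = sigma,
    phi_eq = phi_eq, bounds = bounds,
    n_starts = n_starts, seed = seed, n_obs = nll$n
  ), class = "kpr_fit")
}

#' @export
print.kpr_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit (%s model, %s error model)\n",
              x$variant, x$error_model))
  print(signif(x$estimates, 4))
  cat(sprintf("  logLik %.4f   convergence %d\n", x$logLik, x$convergence))
  invisible(x)
}

#' Convert fitted estimates to a `model_params` object
#' @param fit A `kpr_fit` object.
#' @return A [model_params()] object at the fitted estimates.
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "kpr_fit"))
  e <- fit$estimates
  s <- if (is.finite(fit$s_bind)) fit$s_bind else 1
  model_params(e[["k_c"]], e[["k_off"]], e[["K0"]], e[["tau_kpr"]], e[["A"]],
               phi_eq = fit$phi_eq, s_bind = max(s, .Machine$double.eps))
}

# ---- likelihood-ratio test -------------------------------------------------

#' P-value of the KPR likelihood-ratio statistic at the boundary
#'
#' Because `tau_kpr = 0` lies on the boundary of the parameter space, the
#' null distribution of `D = 2 (lnL_KPR - lnL_null)` is the mixture
#' `1/2 chi2_0 + 1/2 chi2_1`; the resulting p-value is 1 for `D <= 0` and
#' `1/2 P(chi2_1 >= D)` otherwise. The plain chi2_1 p-value is returned
#' alongside for comparison.
#'
#' @param D Likelihood-ratio statistic(s), >= 0.
#' @return A list with `p_boundary` and `p_chisq1`.
#' @export
lrt_pvalue <- function(D) {
  p_b <- ifelse(D <= 0, 1, 0.5 * stats::pchisq(D, df = 1, lower.tail = FALSE))
  p_1 <- stats::pchisq(pmax(D, 0), df = 1, lower.tail = FALSE)
  list(p_boundary = p_b, p_chisq1 = p_1)
}

#' Likelihood-ratio test of kinetic proofreading against the occupancy null
#'
#' Fits both model variants on the same data (the alternative is additionally
#' started from the null's optimum, which guarantees `lnL_KPR >= lnL_null` up
#' to optimizer tolerance) and computes `D = 2 (lnL_KPR - lnL_null)` with the
#' boundary-corrected p-value of [lrt_pvalue()].
#'
#' @inheritParams fit_model
#' @param ... Further arguments passed to [fit_model()].
#' @return An object of class `kpr_lrt`: list with `statistic`, `p_value`
#'   (boundary mixture), `p_value_chisq1`, `fit_kpr`, `fit_null`, `df`.
#' @export
likelihood_ratio_test <- function(data, n_starts = 20, seed = 1,
                                  extra_starts = NULL, ...) {
  fit0 <- fit_model(data, variant = "occupancy", n_starts = n_starts,
                    seed = seed, extra_starts = extra_starts, ...)
  null_start <- fit0$estimates
  null_start[["tau_kpr"]] <- 0
  fit1 <- fit_model(data, variant = "kpr", n_starts = n_starts, seed = seed,
                    extra_starts = c(extra_starts, list(null_start)), ...)
  D <- 2 * (fit1$logLik - fit0$logLik)
  if (D < -1e-6)
    stop("optimizer failure: the KPR fit is worse than its nested null (D = ",
         signif(D, 3), ")")
  D <- max(D, 0)
  p <- lrt_pvalue(D)
  structure(list(statistic = D, p_value = p$p_boundary,
                 p_value_chisq1 = p$p_chisq1,
                 df = "boundary mixture 0.5*chi2_0 + 0.5*chi2_1",
                 fit_kpr = fit1, fit_null = fit0),
            class = "kpr_lrt")
}

#' @export
print.kpr_lrt <- function(x, ...) {
  cat("Likelihood-ratio test: KPR vs occupancy (tau_KPR = 0 on the boundary)\n")
  cat(sprintf("  D = %.4f,  p = %.3g (mixture null),  p = %.3g (chi2_1)\n",
              x$statistic, x$p_value, x$p_value_chisq1))
  invisible(x)
}

# ---- profile likelihood ----------------------------------------------------

#' Profile likelihood and confidence interval for the KPR time
#'
#' At each grid value of `tau_kpr` all other parameters are re-optimized
#' (warm-started by sweeping outward from the joint optimum). The
#' `conf_level` confidence interval is the set where
#' `2 (lnL_hat - lnL_profile(tau)) <= qchisq(conf_level, 1)`; endpoints are
#' refined by root-finding between grid points, each evaluation re-optimizing
#' the nuisance parameters. `tau = 0` is always appended to the grid, so a
#' lower endpoint at the boundary is reported as 0 rather than an error; an
#' upper endpoint beyond the grid maximum raises a widen-the-grid error.
#'
#' @inheritParams fit_model
#' @param tau_grid Grid of KPR times, seconds; default 25 log-spaced points
#'   on \[0.5, 60\].
#' @param conf_level Confidence level (default 0.95).
#' @param fit Optional precomputed `kpr_fit` of the full model on `data`.
#' @param ... Further arguments passed to [fit_model()] when `fit` is NULL.
#' @return An object of class `kpr_profile`: list with `profile` (tibble of
#'   `tau_kpr`, `loglik`, `delta2`), `tau_hat`, `ci`, `threshold`,
#'   `conf_level`, `fit`.
#' @export
profile_likelihood_tau <- function(data, tau_grid = NULL, seed = 1,
                                   n_starts = 20, conf_level = 0.95,
                                   fit = NULL,
                                   error_model = c("profiled", "fixed"),
                                   sigma = 0.1, bounds = kpr_bounds(),
                                   phi_eq = 0.8, control = list(maxit = 500),
                                   ...) {
  error_model <- match.arg(error_model)
  if (is.null(fit))
    fit <- fit_model(data, "kpr", n_starts = n_starts, seed = seed,
                     error_model = error_model, sigma = sigma,
                     bounds = bounds, phi_eq = phi_eq, control = control, ...)
  if (is.null(tau_grid))
    tau_grid <- exp(seq(log(0.5), log(60), length.out = 25))
  tau_hat <- fit$estimates[["tau_kpr"]]
  grid <- sort(unique(c(0, tau_grid, tau_hat)))

  nll <- .make_model_nll(data, phi_eq = phi_eq, error_model = error_model,
                         sigma = sigma)
  lower_th <- .theta_of_p(bounds$lower)
  upper_th <- .theta_of_p(bounds$upper)
  free <- c(1:3, 5)
  theta_hat <- .theta_of_p(fit$estimates)

  solve_at <- function(tau, warm) {
    theta_fixed <- theta_hat
    theta_fixed[4] <- tau
    .fit_sub(nll$value, theta_fixed, free, warm, lower_th, upper_th, control)
  }

  i_hat <- which.min(abs(grid - tau_hat))
  obj_grid <- rep(NA_real_, length(grid))
  sol_grid <- vector("list", length(grid))
  # Sweep outward from the MLE, chaining warm starts.
  for (dir in list(i_hat:length(grid), i_hat:1)) {
    warm <- list(theta_hat[free])
    for (i in dir) {
      if (!is.na(obj_grid[i])) { warm <- list(sol_grid[[i]]$theta[free]); next }
      sol <- solve_at(grid[i], c(warm, list(theta_hat[free])))
      obj_grid[i] <- sol$value
      sol_grid[[i]] <- sol
      warm <- list(sol$theta[free])
    }
  }

  ref <- min(fit$objective, min(obj_grid))
  if (ref < fit$objective - 1e-6)
    warning("profile found a better optimum than the supplied fit; ",
            "using the profile minimum as reference")
  delta2 <- 2 * (obj_grid - ref)
  threshold <- stats::qchisq(conf_level, df = 1)

  prof_obj <- function(tau) {
    i <- which.min(abs(grid - tau))
    solve_at(tau, list(sol_grid[[i]]$theta[free], theta_hat[free]))$value
  }
  g <- function(tau) 2 * (prof_obj(tau) - ref) - threshold

  i_best <- which.min(obj_grid)
  # Lower endpoint.
  below <- which(grid < grid[i_best] & delta2 > threshold)
  if (length(below)) {
    i0 <- max(below)
    lower <- stats::uniroot(g, interval = c(grid[i0], grid[i0 + 1]),
                            tol = 1e-3)$root
  } else lower <- grid[1]
  # Upper endpoint.
  above <- which(grid > grid[i_best] & delta2 > threshold)
  if (length(above)) {
    i1 <- min(above)
    upper <- stats::uniroot(g, interval = c(grid[i1 - 1], grid[i1]),
                            tol = 1e-3)$root
  } else {
    stop("widen the tau grid: the upper CI endpoint lies beyond ",
         max(grid), " s")
  }

  structure(list(
    # lnL and the objective differ by a parameter-free constant, so the
    # profile log-likelihood is recovered by shifting the objective.
    profile = tibble::tibble(tau_kpr = grid,
                             loglik = fit$logLik + fit$objective - obj_grid,
                             delta2 = delta2),
    tau_hat = tau_hat, ci = c(lower = lower, upper = upper),
    threshold = threshold, conf_level = conf_level, fit = fit
  ), class = "kpr_profile")
}

#' @export
print.kpr_profile <- function(x, ...) {
  cat(sprintf("Profile likelihood of the KPR time: tau_hat = %.3g s, %d%% CI [%.3g, %.3g] s\n",
              x$tau_hat, round(100 * x$conf_level), x$ci[1], x$ci[2]))
  invisible(x)
}

# ---- identifiability -------------------------------------------------------

#' Structural identifiability of the KPR time from steady-state data alone
#'
#' Steady-state data constrain only the product `tau_kpr * k_off` (together
#' with `tau_kpr * k_c` and `k_c / k_off`), not the KPR time itself: the
#' transformation `(tau, k_off, k_c) -> (c tau, k_off/c, k_c/c)` leaves every
#' steady-state prediction unchanged. This check fits the model to
#' steady-state data, then walks the constant-product ridge
#' `k_off = product / tau` over `tau_range` (re-optimizing `k_c`, `K0`, `A`
#' at each point) and reports the objective change along the ridge (expected
#' flat) versus across it (holding `k_off` fixed while `tau` moves; expected
#' strongly curved). If `kinetics` is supplied, the same ridge is re-walked
#' on the augmented data, where the pulse-duration curves pin `k_c`
#' absolutely and break the ridge.
#'
#' Uses the fixed-sigma error model throughout, so it is well defined on
#' noiseless data; `delta2` values are `2 * (NLL - NLL_min)` i.e.
#' `Delta RSS / sigma^2`.
#'
#' @inheritParams fit_model
#' @param kinetics Optional pulse-kinetics tibble to augment the data.
#' @param tau_range Range of KPR times walked along the ridge (default one
#'   decade, 2 to 20 s).
#' @param n_grid Number of ridge points.
#' @return An object of class `identifiability_report`: list with
#'   `product`, `tau_grid`, `delta2_along`, `delta2_across`,
#'   `delta2_along_augmented` (NULL without kinetics), `fit_ss`, `fit_aug`.
#' @export
steady_state_identifiability_check <- function(data, kinetics = NULL,
                                               tau_range = c(2, 20),
                                               n_grid = 9, sigma = 0.1,
                                               n_starts = 20, seed = 1,
                                               bounds = kpr_bounds(),
                                               phi_eq = 0.8,
                                               control = list(maxit = 1000)) {
  data_ss <- .validate_bundle(data)
  data_ss$kinetics <- NULL
  fit_ss <- fit_model(data_ss, "kpr", n_starts = n_starts, seed = seed,
                      error_model = "fixed", sigma = sigma, bounds = bounds,
                      phi_eq = phi_eq, control = control)
  est <- fit_ss$estimates
  prod_hat <- est[["tau_kpr"]] * est[["k_off"]]
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid))

  lower_th <- .theta_of_p(bounds$lower)
  upper_th <- .theta_of_p(bounds$upper)
  free <- c(1, 3, 5) # k_c, K0, A re-optimized; tau, k_off pinned

  walk <- function(nll_obj, ref_value, ref_est, product, hold_koff) {
    vapply(taus, function(tau) {
      c_scale <- tau / ref_est[["tau_kpr"]]
      k_off_i <- if (hold_koff) ref_est[["k_off"]] else product / tau
      theta_fixed <- .theta_of_p(ref_est)
      theta_fixed[4] <- tau
      theta_fixed[2] <- log(k_off_i)
      warm_inv <- .theta_of_p(ref_est)[free]
      warm_inv[1] <- log(ref_est[["k_c"]] / c_scale) # exact ridge invariance
      sol <- .fit_sub(nll_obj$value, theta_fixed, free,
                      list(warm_inv, .theta_of_p(ref_est)[free]),
                      lower_th, upper_th, control)
      2 * (sol$value - ref_value)
    }, numeric(1))
  }

  nll_ss <- .make_model_nll(data_ss, phi_eq = phi_eq, error_model = "fixed",
                            sigma = sigma)
  delta2_along <- walk(nll_ss, fit_ss$objective, est, prod_hat,
                       hold_koff = FALSE)
  delta2_across <- walk(nll_ss, fit_ss$objective, est, prod_hat,
                        hold_koff = TRUE)

  fit_aug <- NULL
  delta2_aug <- NULL
  if (!is.null(kinetics)) {
    data_aug <- c(data_ss, list(kinetics = kinetics))
    fit_aug <- fit_model(data_aug, "kpr", n_starts = n_starts, seed = seed + 1,
                         error_model = "fixed", sigma = sigma, bounds = bounds,
                         phi_eq = phi_eq, control = control,
                         extra_starts = list(est))
    est_aug <- fit_aug$estimates
    prod_aug <- est_aug[["tau_kpr"]] * est_aug[["k_off"]]
    nll_aug <- .make_model_nll(data_aug, phi_eq = phi_eq,
                               error_model = "fixed", sigma = sigma)
    delta2_aug <- walk(nll_aug, fit_aug$objective, est_aug, prod_aug,
                       hold_koff = FALSE)
  }

  structure(list(product = prod_hat, tau_grid = taus,
                 delta2_along = delta2_along, delta2_across = delta2_across,
                 delta2_along_augmented = delta2_aug,
                 fit_ss = fit_ss, fit_aug = fit_aug),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf("Steady-state identifiability: tau*k_off = %.4g\n", x$product))
  cat(sprintf("  max |delta2| along constant-product ridge: %.3g\n",
              max(abs(x$delta2_along))))
  cat(sprintf("  min delta2 across the ridge (endpoints): %.3g\n",
              min(x$delta2_across[c(1, length(x$delta2_across))])))
  if (!is.null(x$delta2_along_augmented))
    cat(sprintf("  with kinetic data, min delta2 along the same path (endpoints): %.3g\n",
                min(x$delta2_along_augmented[c(1, length(x$delta2_along_augmented))])))
  invisible(x)
}
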