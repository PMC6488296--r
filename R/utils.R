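# Internal helpers shared across the fitting machinery.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# Parameter vector <-> optimizer coordinates. Order: k_c, k_off, K0, tau_kpr,
# A; all log-transformed except tau_kpr (which may sit on its 0 boundary).
.theta_of_p <- function(p) {
  th <- as.numeric(p)
  th[c(1, 2, 3, 5)] <- log(th[c(1, 2, 3, 5)])
  th
}

.p_of_theta <- function(th) {
  p <- as.numeric(th)
  p[c(1, 2, 3, 5)] <- exp(p[c(1, 2, 3, 5)])
  names(p) <- c("k_c", "k_off", "K0", "tau_kpr", "A")
  p
}

# Latin-hypercube starts in optimizer coordinates (uses the current RNG).
.lhs_starts <- function(n, lower, upper) {
  d <- length(lower)
  m <- vapply(seq_len(d), function(j) {
    u <- (sample.int(n) - stats::runif(n)) / n
    lower[j] + u * (upper[j] - lower[j])
  }, numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  lapply(seq_len(n), function(i) m[i, ])
}

# Minimize value_fn(p) over the free coordinates of theta, others fixed.
.fit_sub <- function(value_fn, theta_fixed, free, starts, lower_th, upper_th,
                     control = list(maxit = 500)) {
  obj <- function(th_free) {
    th <- theta_fixed
    th[free] <- th_free
    v <- value_fn(.p_of_theta(th))
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower_th[free]), upper_th[free])
    res <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = lower_th[free], upper = upper_th[free],
                   control = control),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-9 ||
        (abs(res$value - best$value) <= 1e-9 && 4 %in% free &&
         res$par[match(4, free)] < best$par[match(4, free)])) {
      best <- res
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  th <- theta_fixed
  th[free] <- best$par
  list(p = .p_of_theta(th), theta = th, value = best$value,
       convergence = best$convergence)
}
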