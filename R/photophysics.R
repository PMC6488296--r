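#' Illumination protocols
#'
#' A protocol is an ordered, contiguous sequence of light segments, each with
#' a wavelength (`"660"`, `"740"` or `"dark"`), a duration in seconds and —
#' for 660 nm segments — an intensity in percent of the maximal device
#' output. Intensity 0 is equivalent to darkness.
#'
#' @param wavelength Character or numeric vector; one of 660, 740, "dark"
#'   per segment.
#' @param duration_s Strictly positive segment durations, seconds.
#' @param intensity_percent Intensities in \[0, 100\]; recycled; ignored for
#'   740/dark segments.
#' @return A tibble of class `illumination_protocol` with columns
#'   `segment_index`, `wavelength`, `intensity_percent`, `duration_s`.
#' @examples
#' # 2 s full-intensity 660 nm pulse, then darkness
#' illumination_protocol(c("660", "dark"), c(2, 600), c(100, 0))
#' @export
illumination_protocol <- function(wavelength, duration_s,
                                  intensity_percent = 0) {
  wavelength <- as.character(wavelength)
  if (!all(wavelength %in% c("660", "740", "dark")))
    stop("'wavelength' must be one of 660, 740, 'dark'")
  n <- length(wavelength)
  duration_s <- rep_len(as.numeric(duration_s), n)
  intensity_percent <- rep_len(as.numeric(intensity_percent), n)
  if (any(!is.finite(duration_s)) || any(duration_s <= 0))
    stop("segment durations must be strictly positive")
  if (any(intensity_percent < 0) || any(intensity_percent > 100))
    stop("'intensity_percent' must lie in [0, 100]")
  intensity_percent[wavelength != "660"] <- 0
  out <- tibble::tibble(segment_index = seq_len(n), wavelength = wavelength,
                        intensity_percent = intensity_percent,
                        duration_s = duration_s)
  class(out) <- c("illumination_protocol", class(out))
  attr(out, "total_duration") <- sum(duration_s)
  out
}

#' @describeIn illumination_protocol Constant 660 nm illumination.
#' @param intensity Intensity in percent for the convenience constructors.
#' @param duration Total duration, seconds.
#' @export
protocol_constant_660 <- function(intensity, duration) {
  illumination_protocol("660", duration, intensity)
}

#' @describeIn illumination_protocol A 660 nm pulse of `pulse_s` seconds
#'   followed by darkness (the ON-state trapping protocol).
#' @param pulse_s Pulse duration, seconds.
#' @param dark_s Dark chase duration, seconds.
#' @export
protocol_pulse_trap <- function(intensity, pulse_s, dark_s = 600) {
  illumination_protocol(c("660", "dark"), c(pulse_s, dark_s), c(intensity, 0))
}

# Per-segment relaxation description: every segment drives the ON fraction
# toward a target at a first-order rate (rate 0 freezes the state).
.segment_kinetics <- function(photophys, wavelength, intensity) {
  if (wavelength == "660" && intensity > 0) {
    list(rate = photophys$k_c * intensity, target = photophys$phi_eq)
  } else if (wavelength == "740") {
    list(rate = photophys$k_740, target = 0)
  } else {
    list(rate = 0, target = 0) # dark: frozen, target irrelevant
  }
}

#' ON->OFF photoconversion rate under 660 nm light
#'
#' The rate `k_i` at which ON-state PhyB returns to the OFF state under
#' continuous 660 nm light of the given intensity:
#' `(1 - phi_eq) * k_c * intensity`. Linear through the origin, 0 in the
#' dark.
#'
#' @param photophys A [photophys_params()] object.
#' @param intensity Intensity in percent of maximal output, in \[0, 100\];
#'   vectorized.
#' @return Rate(s) in s^-1.
#' @export
rate_on_to_off <- function(photophys, intensity) {
  stopifnot(inherits(photophys, "photophys_params"))
  if (any(intensity < 0)) stop("'intensity' must be non-negative")
  if (any(intensity > 100)) stop("'intensity' must not exceed 100 percent")
  (1 - photophys$phi_eq) * photophys$k_c * intensity
}

#' @describeIn rate_on_to_off OFF->ON rate `phi_eq * k_c * intensity`.
#' @export
rate_off_to_on <- function(photophys, intensity) {
  stopifnot(inherits(photophys, "photophys_params"))
  if (any(intensity < 0)) stop("'intensity' must be non-negative")
  if (any(intensity > 100)) stop("'intensity' must not exceed 100 percent")
  photophys$phi_eq * photophys$k_c * intensity
}

#' Photoequilibrium ON fraction under continuous 660 nm light
#'
#' Equals `phi_eq` (default 0.8) for every positive intensity: the
#' ON:OFF ratio at photoequilibrium is intensity-independent; intensity sets
#' only the relaxation speed `k_c * intensity`.
#'
#' @inheritParams rate_on_to_off
#' @return The ON fraction (recycled to the length of `intensity`).
#' @export
on_fraction_steady_state <- function(photophys, intensity) {
  stopifnot(inherits(photophys, "photophys_params"))
  if (any(intensity <= 0))
    stop("no photoequilibrium in dark: the state is frozen, not relaxing")
  if (any(intensity > 100)) stop("'intensity' must not exceed 100 percent")
  rep_len(photophys$phi_eq, length(intensity))
}

#' Deterministic ON-fraction trajectory under an illumination protocol
#'
#' Piecewise closed-form solution of the two-state photocycle: within a
#' 660 nm segment of intensity I the ON fraction relaxes exponentially toward
#' `phi_eq` at rate `k_c * I`; dark segments hold it constant; 740 nm
#' segments relax toward 0 at rate `k_740`. The trajectory is continuous
#' across segment boundaries.
#'
#' @inheritParams rate_on_to_off
#' @param protocol An [illumination_protocol()].
#' @param f0 Initial ON fraction in \[0, 1\].
#' @param times Evaluation time points (s), within the protocol duration.
#' @return A tibble with columns `time_s`, `on_fraction`.
#' @examples
#' pp <- photophys_params(k_c = 0.05)
#' pr <- protocol_pulse_trap(100, pulse_s = 2)
#' simulate_on_fraction(pp, pr, f0 = 0, times = c(0, 1, 2, 10, 100))
#' @export
simulate_on_fraction <- function(photophys, protocol, f0, times) {
  stopifnot(inherits(photophys, "photophys_params"),
            inherits(protocol, "illumination_protocol"))
  if (length(f0) != 1 || !is.finite(f0) || f0 < 0 || f0 > 1)
    stop("'f0' must be a single value in [0, 1]")
  total <- sum(protocol$duration_s)
  if (any(times < 0) || any(times > total + 1e-9))
    stop("'times' must lie within the protocol duration")
  breaks <- c(0, cumsum(protocol$duration_s))
  n_seg <- nrow(protocol)
  kin <- lapply(seq_len(n_seg), function(i)
    .segment_kinetics(photophys, protocol$wavelength[i],
                      protocol$intensity_percent[i]))
  # ON fraction at the start of each segment
  f_start <- numeric(n_seg)
  f_start[1] <- f0
  for (i in seq_len(n_seg)) {
    k <- kin[[i]]
    f_end <- if (k$rate > 0)
      k$target + (f_start[i] - k$target) * exp(-k$rate * protocol$duration_s[i])
    else f_start[i]
    if (i < n_seg) f_start[i + 1] <- f_end
  }
  seg <- findInterval(times, breaks, all.inside = TRUE)
  f <- vapply(seq_along(times), function(j) {
    i <- seg[j]
    k <- kin[[i]]
    dt <- times[j] - breaks[i]
    if (k$rate > 0) k$target + (f_start[i] - k$target) * exp(-k$rate * dt)
    else f_start[i]
  }, numeric(1))
  tibble::tibble(time_s = as.numeric(times), on_fraction = pmin(1, pmax(0, f)))
}

#' ON fraction trapped by a 660 nm pulse from an all-OFF start
#'
#' Starting from all-OFF ligand, a 660 nm pulse of the given intensity and
#' duration followed by darkness traps the ON fraction
#' `phi_eq * (1 - exp(-k_c * intensity * duration))`: monotone increasing in
#' duration and saturating at the photoequilibrium fraction.
#'
#' @inheritParams rate_on_to_off
#' @param duration Pulse duration(s), seconds (vectorized, >= 0).
#' @return Trapped ON fraction(s).
#' @export
pulse_trapped_on_fraction <- function(photophys, intensity, duration) {
  stopifnot(inherits(photophys, "photophys_params"))
  if (any(intensity < 0) || any(intensity > 100))
    stop("'intensity' must lie in [0, 100]")
  if (any(duration < 0)) stop("'duration' must be non-negative")
  photophys$phi_eq * (1 - exp(-photophys$k_c * intensity * duration))
}

#' Per-molecule stochastic photoswitching oracle
#'
#' Brute-force validation oracle for the deterministic trajectories: each of
#' `n_molecules` molecules switches state with exponential waiting times at
#' the current segment's OFF->ON / ON->OFF rates. Returns the empirical ON
#' fraction at the requested times; reproducible for a fixed seed.
#'
#' @inheritParams simulate_on_fraction
#' @param n_molecules Number of simulated molecules (>= 1).
#' @param seed Integer seed for the simulation.
#' @return A tibble with columns `time_s`, `on_fraction` (empirical).
#' @export
stochastic_switch_oracle <- function(photophys, protocol, n_molecules, times,
                                     f0 = 0, seed = 1) {
  stopifnot(inherits(photophys, "photophys_params"),
            inherits(protocol, "illumination_protocol"))
  if (n_molecules < 1) stop("'n_molecules' must be at least 1")
  total <- sum(protocol$duration_s)
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0) || any(times > total + 1e-9))
    stop("'times' must lie within the protocol duration")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  breaks <- c(0, cumsum(protocol$duration_s))
  # Initial assignment: fixed count closest to f0 so the dark case is exact.
  n_on <- round(f0 * n_molecules)
  on <- c(rep(TRUE, n_on), rep(FALSE, n_molecules - n_on))

  grid <- sort(unique(c(times, breaks[breaks <= max(times, breaks[length(breaks)])])))
  grid <- grid[grid <= total + 1e-9]
  out_frac <- numeric(length(times))
  if (any(times == 0)) out_frac[times == 0] <- mean(on)

  for (g in seq_len(length(grid) - 1)) {
    t0 <- grid[g]; t1 <- grid[g + 1]
    dt <- t1 - t0
    if (dt <= 0) next
    i <- findInterval((t0 + t1) / 2, breaks, all.inside = TRUE)
    wl <- protocol$wavelength[i]
    int <- protocol$intensity_percent[i]
    if (wl == "660" && int > 0) {
      ka <- rate_off_to_on(photophys, int)
      ki <- rate_on_to_off(photophys, int)
    } else if (wl == "740") {
      ka <- 0; ki <- photophys$k_740
    } else {
      ka <- 0; ki <- 0
    }
    if (ka > 0 || ki > 0) {
      t_rem <- rep(dt, n_molecules)
      idx <- which((on & ki > 0) | (!on & ka > 0))
      while (length(idx) > 0) {
        r <- ifelse(on[idx], ki, ka)
        w <- stats::rexp(length(idx), rate = r)
        sw <- w < t_rem[idx]
        hit <- idx[sw]
        t_rem[hit] <- t_rem[hit] - w[sw]
        on[hit] <- !on[hit]
        idx <- hit[(on[hit] & ki > 0) | (!on[hit] & ka > 0)]
      }
    }
    sel <- which(abs(times - t1) < 1e-12)
    if (length(sel)) out_frac[sel] <- mean(on)
  }
  tibble::tibble(time_s = times, on_fraction = out_frac)
}

#' First-order association rate from a photoconversion time course
#'
#' Least-squares fit of `y(t) = y_max * (1 - exp(-k * t))` (optionally plus a
#' constant offset) to a spectroscopy or trapping time course, as used to
#' quantify absolute photoconversion rates. The amplitude (and offset) are
#' linear in the model for fixed `k` and are profiled out, so the search is a
#' robust one-dimensional optimization over `log k`, seeded from the fixed
#' multi-start grid `k` in \{1e-3, 1e-2, 1e-1, 1\} s^-1; ties are broken by
#' the lowest residual sum of squares.
#'
#' @param times Time points, seconds (>= 3 distinct values).
#' @param values Observed signal (e.g. delta-delta-absorbance).
#' @param offset Logical; fit an additive constant offset (default `FALSE`).
#' @param k_starts Multi-start rate grid, s^-1.
#' @return A list of class `first_order_fit` with elements `k`, `se_k`,
#'   `y_max`, `offset`, `rss`, `fitted`.
#' @examples
#' t <- seq(0, 300, by = 10)
#' y <- 2 * (1 - exp(-0.05 * t))
#' fit_first_order_rate(t, y)$k
#' @export
fit_first_order_rate <- function(times, values, offset = FALSE,
                                 k_starts = c(1e-3, 1e-2, 1e-1, 1)) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("'times' and 'values' lengths differ")
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  p <- if (offset) 3L else 2L
  if (length(unique(times)) < p + 1L)
    stop("need at least ", p + 1L, " distinct time points")
  if (stats::sd(values) == 0)
    stop("constant series: no identifiable rate")

  rss_at <- function(logk) {
    k <- exp(logk)
    x <- 1 - exp(-k * times)
    X <- if (offset) cbind(1, x) else cbind(x)
    cf <- tryCatch(qr.coef(qr(X), values), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(Inf)
    sum((values - X %*% cf)^2)
  }
  cand <- log(k_starts)
  vals <- vapply(cand, rss_at, numeric(1))
  best0 <- cand[which.min(vals)]
  opt <- stats::optimize(rss_at, interval = best0 + c(-log(40), log(40)))
  # Reject fits pinned to the search edge (no curvature in the data).
  if (min(abs(opt$minimum - (best0 + c(-log(40), log(40))))) < 1e-3 ||
      !is.finite(opt$objective))
    stop("first-order rate fit did not converge: no identifiable rate")
  k <- exp(opt$minimum)
  x <- 1 - exp(-k * times)
  X <- if (offset) cbind(1, x) else cbind(x)
  cf <- qr.coef(qr(X), values)
  y_max <- cf[length(cf)]
  y0 <- if (offset) cf[1] else 0
  fitted <- as.numeric(X %*% cf)
  rss <- sum((values - fitted)^2)
  # a fit no better than the constant mean carries no rate information
  if (rss >= sum((values - mean(values))^2))
    stop("first-order rate fit did not converge: no identifiable rate")
  # Asymptotic SE from the Gauss-Newton Jacobian of (y0, y_max, k).
  J <- cbind(X, y_max * times * exp(-k * times))
  dof <- max(length(values) - ncol(J), 1L)
  sigma2 <- rss / dof
  cov_k <- tryCatch(sigma2 * solve(crossprod(J))[ncol(J), ncol(J)],
                    error = function(e) NA_real_)
  structure(list(k = unname(k), se_k = sqrt(unname(cov_k)),
                 y_max = unname(y_max), offset = unname(y0),
                 rss = rss, fitted = fitted),
            class = "first_order_fit")
}
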