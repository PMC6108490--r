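#' Configuration for synthetic compression load curves
#'
#' Describes the physical test emulated by [generate_load_curve()]: a
#' standardized 10 mm x 5 mm cylinder compressed at a constant crosshead rate
#' after a standardizing preload, with force and displacement logged at a
#' fixed rate.
#'
#' @param E_true True elastic modulus, MPa.
#' @param F_peak_true True peak force, N (must exceed the preload).
#' @param yield_strain Strain at which the response departs from linearity.
#' @param noise_sd Gaussian force noise, N.
#' @param preload Standardizing initial load, N (default 10).
#' @param sample_rate Logging rate, Hz (default 4).
#' @param load_rate Crosshead speed, mm/min (default 0.6).
#' @param seed Integer seed.
#' @param duration_s Optional record duration, s; by default the record runs
#'   just past the post-peak decline.
#' @return A `load_curve_config`.
#' @export
load_curve_config <- function(E_true, F_peak_true, yield_strain = 0.04,
                              noise_sd = 0, preload = 10, sample_rate = 4,
                              load_rate = 0.6, seed = 1L, duration_s = NULL) {
  stopifnot(is.numeric(E_true), length(E_true) == 1)
  if (E_true <= 0) stop("E_true must be > 0")
  if (preload < 0) stop("preload must be >= 0")
  if (F_peak_true <= preload) stop("F_peak_true must exceed the preload")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  stopifnot(yield_strain > 0, noise_sd >= 0, load_rate > 0)
  A <- cylinder_contact_area()
  F_yield <- preload + E_true * A * yield_strain
  if (F_yield >= F_peak_true)
    stop(sprintf(
      "inconsistent curve shape: force at yield_strain (%.4g N) reaches the peak %.4g N; lower yield_strain",
      F_yield, F_peak_true))
  structure(list(E_true = E_true, F_peak_true = F_peak_true,
                 yield_strain = yield_strain, noise_sd = noise_sd,
                 preload = preload, sample_rate = sample_rate,
                 load_rate = load_rate, seed = as.integer(seed),
                 duration_s = duration_s),
            class = "load_curve_config")
}

#' Generate a synthetic near-linear-then-failure compression record
#'
#' The noiseless backbone is piecewise linear: an elastic rise at the slope
#' implied by `E_true` through the stress-strain geometry of the standardized
#' cylinder (stiffness `E A / h0` N/mm) up to `yield_strain`, a gentle
#' post-yield ramp (30% of the elastic stiffness) up to the peak force, then
#' a linear decline at half the elastic stiffness. Every segment is exactly
#' linear and the elastic one is the steepest, so the maximal-R^2 window
#' estimator recovers `E_true`. Seeded Gaussian noise is added
#' peak-preservingly: the designed peak sample is pinned at `F_peak_true`,
#' the first sample at the preload, and noisy samples are clipped to
#' `[0, F_peak_true]`, so the recorded maximum equals `F_peak_true` exactly.
#'
#' @param cfg A `load_curve_config`.
#' @return A `force_displacement_record`.
#' @export
generate_load_curve <- function(cfg) {
  stopifnot(inherits(cfg, "load_curve_config"))
  A <- cylinder_contact_area()
  h0 <- STD_CORE_HEIGHT
  k <- cfg$E_true * A / h0              # N per mm of displacement
  eps_y <- cfg$yield_strain
  F_y <- cfg$preload + k * eps_y * h0
  ramp_k <- 0.3 * k                     # N/mm, post-yield hardening ramp
  decline_k <- 0.5 * k                  # N/mm, post-peak softening
  eps_peak <- eps_y + (cfg$F_peak_true - F_y) / (ramp_k * h0)
  # observe the decline down to ~60% of the peak
  eps_end <- eps_peak + 0.4 * cfg$F_peak_true / (decline_k * h0)
  rate_mm_s <- cfg$load_rate / 60
  if (is.null(cfg$duration_s)) {
    n <- ceiling(eps_end * h0 / rate_mm_s * cfg$sample_rate) + 1L
  } else {
    n <- as.integer(round(cfg$duration_s * cfg$sample_rate))
  }
  tt <- (seq_len(n) - 1L) / cfg$sample_rate
  d <- rate_mm_s * tt
  eps <- d / h0
  f <- numeric(n)
  el <- eps <= eps_y
  f[el] <- cfg$preload + k * d[el]
  sh <- eps > eps_y & eps <= eps_peak
  f[sh] <- F_y + ramp_k * (eps[sh] - eps_y) * h0
  de <- eps > eps_peak
  f[de] <- cfg$F_peak_true - decline_k * (eps[de] - eps_peak) * h0
  f <- pmax(f, 0)
  peak_idx <- which.min(abs(eps - eps_peak))
  if (eps[n] < eps_peak) peak_idx <- 0L  # short record truncated before peak
  if (cfg$noise_sd > 0) {
    f <- f + with_seed(cfg$seed, stats::rnorm(n, 0, cfg$noise_sd))
    f[1] <- cfg$preload
    f <- pmin(pmax(f, 0), cfg$F_peak_true)
    if (peak_idx > 0) f[peak_idx] <- cfg$F_peak_true
  } else if (peak_idx > 0) {
    f[peak_idx] <- cfg$F_peak_true
  }
  force_displacement_record(tt, f, d, preload = cfg$preload,
                            sample_rate = cfg$sample_rate)
}
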