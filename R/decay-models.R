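#' Mono-exponential decay parameters
#'
#' Parameter container for a single-exponential fluorescence decay
#' \eqn{I(t) = A e^{-t/\tau} + B}. This is the model used for lifetime
#' calculation in single-labeling FLIM experiments, where the dye decay is
#' mono-exponential to good approximation.
#'
#' @param amplitude Photon flux amplitude at t = 0 (dimensionless, >= 0).
#' @param tau Fluorescence lifetime in ns (> 0).
#' @param background Constant background counts per time bin (>= 0).
#' @return An object of class `mono_params`.
#' @examples
#' p <- mono_params(amplitude = 100, tau = 2.46)
#' mono_decay(2.46, p) # amplitude / e
#' @export
mono_params <- function(amplitude, tau, background = 0) {
  stopifnot(is.numeric(amplitude), is.numeric(tau), is.numeric(background))
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, tau = tau, background = background),
            class = "mono_params")
}

#' Bi-exponential decay parameters
#'
#' Parameter container for the donor decay in a FRET experiment,
#' \eqn{f(t) = a_1 e^{-t/\tau_{fret}} + a_2 e^{-t/\tau_0} + B}.
#' The slow component `tau0` is the lifetime of the non-interacting donor;
#' the fast component `tau_fret` is the lifetime of donor molecules quenched
#' by a nearby acceptor. The convention `tau_fret <= tau0` is enforced.
#'
#' @param a1 Amplitude of the FRET (fast) component (>= 0).
#' @param a2 Amplitude of the non-interacting (slow) component (>= 0).
#' @param tau_fret Fast lifetime in ns (> 0).
#' @param tau0 Slow lifetime in ns (>= tau_fret).
#' @param background Constant background counts per time bin (>= 0).
#' @return An object of class `bi_params`.
#' @export
bi_params <- function(a1, a2, tau_fret, tau0, background = 0) {
  if (tau_fret <= 0 || tau0 <= 0) stop("lifetimes must be > 0", call. = FALSE)
  if (tau_fret > tau0)
    stop("tau_fret must be <= tau0 (fast/slow convention)", call. = FALSE)
  if (a1 < 0 || a2 < 0) stop("amplitudes must be >= 0", call. = FALSE)
  if (a1 + a2 <= 0) stop("a1 + a2 must be > 0", call. = FALSE)
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, tau_fret = tau_fret, tau0 = tau0,
                 background = background),
            class = "bi_params")
}

#' TCSPC acquisition configuration
#'
#' Time axis and pile-up budget of a TCSPC acquisition. The default emulates
#' an 80 MHz excitation source: a 12.5 ns repetition period histogrammed into
#' 256 bins of 12.5/256 ns (~48.8 ps).
#'
#' @param n_bins Number of histogram time bins.
#' @param bin_width Width of one time bin, ns.
#' @param period Laser repetition period, ns. Must satisfy
#'   `n_bins * bin_width <= period`.
#' @param pileup_budget Maximum allowed ratio of per-pixel peak count rate to
#'   excitation rate. Default 0.10, the standard recommendation for keeping
#'   classic pile-up distortion negligible.
#' @param n_excitations Nominal number of excitation cycles contributing to
#'   one pixel's histogram; used only for the pile-up budget check when
#'   simulating (12.5 ns period and a ~2.5 us pixel dwell repeated over a
#'   60 s frame gives on the order of 1e5-1e6 cycles; default 2e5).
#' @return An object of class `acq_config`.
#' @export
acq_config <- function(n_bins = 256L, bin_width = 12.5 / 256, period = 12.5,
                       pileup_budget = 0.10, n_excitations = 2e5) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins > 0, bin_width > 0, period > 0)
  if (n_bins * bin_width > period + 1e-9)
    stop("n_bins * bin_width must not exceed the repetition period",
         call. = FALSE)
  if (pileup_budget <= 0 || pileup_budget > 1)
    stop("pileup_budget must be in (0, 1]", call. = FALSE)
  structure(list(n_bins = n_bins, bin_width = bin_width, period = period,
                 pileup_budget = pileup_budget,
                 n_excitations = n_excitations),
            class = "acq_config")
}

#' Instrument response function (IRF)
#'
#' A discretized instrument response on the acquisition time axis. Weights
#' are non-negative and sum to one.
#'
#' @param weights Non-negative weights, one per time bin position.
#' @param bin_width Time bin width in ns; must match the acquisition config
#'   it is used with.
#' @return An object of class `irf`.
#' @seealso [irf_gaussian()], [irf_delta()]
#' @export
irf <- function(weights, bin_width) {
  if (any(weights < 0)) stop("IRF weights must be >= 0", call. = FALSE)
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) {
    if (s <= 0) stop("IRF weights must have positive sum", call. = FALSE)
    weights <- weights / s
  }
  structure(list(weights = as.numeric(weights), bin_width = bin_width),
            class = "irf")
}

#' Gaussian IRF
#'
#' Gaussian instrument response discretized on the acquisition time axis and
#' renormalized to sum one. The default FWHM of 0.2 ns is typical for hybrid
#' photodetectors.
#'
#' @param acq An [acq_config()].
#' @param fwhm_ns Full width at half maximum, ns.
#' @param center_ns Position of the IRF peak on the time axis, ns.
#' @return An [irf()] with `acq$n_bins` weights.
#' @export
irf_gaussian <- function(acq, fwhm_ns = 0.2, center_ns = 1.0) {
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  t <- (seq_len(acq$n_bins) - 0.5) * acq$bin_width
  w <- stats::dnorm(t, mean = center_ns, sd = sigma)
  irf(w / sum(w), acq$bin_width)
}

#' Delta-function IRF
#'
#' An idealized instantaneous instrument response: all weight in one bin.
#' Useful as an analytic reference, since convolution with it is the
#' identity.
#'
#' @param acq An [acq_config()].
#' @param bin Index of the bin carrying the unit weight (1-based).
#' @return An [irf()].
#' @export
irf_delta <- function(acq, bin = 1L) {
  w <- numeric(acq$n_bins)
  w[bin] <- 1
  irf(w, acq$bin_width)
}

#' Default donor photophysics
#'
#' Reference constants used by the synthetic-data generator and the FRET
#' defaults: donor reference lifetime 2.47 ns at reference refractive index
#' 1.38, and a default FRET mixture with equal amplitudes (a1 = a2) and
#' tau_fret = 2.01 ns, whose amplitude-weighted mean lifetime is 2.24 ns.
#'
#' @return A list with elements `tau_donor` (ns), `n_ref`, `fret_fraction`
#'   (a1 / (a1 + a2)), `tau_fret` (ns), and `fret_efficiency`
#'   (1 - tau_fret / tau_donor).
#' @export
default_photophysics <- function() {
  tau_donor <- 2.47
  tau_fret <- 2.01
  list(tau_donor = tau_donor,
       n_ref = 1.38,
       fret_fraction = 0.5,
       tau_fret = tau_fret,
       fret_efficiency = 1 - tau_fret / tau_donor)
}

#' Evaluate a mono-exponential decay
#'
#' @param t Time(s) since excitation, ns (>= 0). Vectorized.
#' @param p A [mono_params()].
#' @return Expected intensity `amplitude * exp(-t / tau) + background`.
#' @export
mono_decay <- function(t, p) {
  stopifnot(inherits(p, "mono_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p$amplitude * exp(-t / p$tau) + p$background
}

#' Evaluate a bi-exponential decay
#'
#' @param t Time(s) since excitation, ns (>= 0). Vectorized.
#' @param p A [bi_params()].
#' @return Expected intensity
#'   `a1 * exp(-t / tau_fret) + a2 * exp(-t / tau0) + background`.
#' @export
bi_decay <- function(t, p) {
  stopifnot(inherits(p, "bi_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p$a1 * exp(-t / p$tau_fret) + p$a2 * exp(-t / p$tau0) + p$background
}

#' FRET efficiency from donor lifetimes
#'
#' Fractional quenching of the donor, `E = 1 - tau_fret / tau0`. It is 0 when
#' the two lifetimes are equal (no energy transfer) and approaches 1 as the
#' quenched lifetime approaches zero.
#'
#' @param tau_fret Quenched donor lifetime, ns.
#' @param tau0 Unquenched donor lifetime, ns. Must satisfy
#'   `0 < tau_fret <= tau0` elementwise.
#' @return Efficiency value(s) in `[0, 1]`.
#' @export
fret_efficiency <- function(tau_fret, tau0) {
  if (any(tau_fret <= 0) || any(tau0 <= 0))
    stop("lifetimes must be > 0", call. = FALSE)
  if (any(tau_fret > tau0 + 1e-12))
    stop("tau_fret must be <= tau0 (efficiency would be negative)",
         call. = FALSE)
  pmax(0, 1 - tau_fret / tau0)
}

#' Lifetime from local refractive index (Strickler-Berg)
#'
#' Reduced (radiative-rate-dominated) form of the Strickler-Berg relation:
#' the radiative rate scales with the square of the local refractive index,
#' so the lifetime follows the inverse-quadratic law
#' \eqn{\tau(n) = \tau_{ref} (n_{ref}/n)^2}. The full spectral integral is
#' deliberately not modeled; only the inverse-quadratic dependence is used.
#'
#' @param n Local refractive index (> 0). Vectorized.
#' @param tau_ref Reference lifetime in ns at refractive index `n_ref`.
#' @param n_ref Reference refractive index (> 0).
#' @return Lifetime(s) in ns, strictly decreasing in `n`.
#' @export
strickler_berg_lifetime <- function(n, tau_ref, n_ref) {
  if (any(n <= 0) || tau_ref <= 0 || n_ref <= 0)
    stop("n, tau_ref and n_ref must all be > 0", call. = FALSE)
  tau_ref * (n_ref / n)^2
}

#' Refractive index giving a target lifetime (inverse Strickler-Berg)
#'
#' Inverse of [strickler_berg_lifetime()]: the refractive index at which a
#' fluorophore with reference lifetime `tau_ref` at `n_ref` has lifetime
#' `tau`.
#'
#' @param tau Target lifetime, ns (> 0). Vectorized.
#' @param tau_ref Reference lifetime, ns.
#' @param n_ref Reference refractive index.
#' @return Refractive index value(s).
#' @export
strickler_berg_ri <- function(tau, tau_ref, n_ref) {
  if (any(tau <= 0) || tau_ref <= 0 || n_ref <= 0)
    stop("tau, tau_ref and n_ref must all be > 0", call. = FALSE)
  n_ref * sqrt(tau_ref / tau)
}

#' Mean lifetime of a bi-exponential decay
#'
#' Amplitude-weighted mean \eqn{(a_1\tau_{fret} + a_2\tau_0)/(a_1 + a_2)} or
#' intensity-weighted mean
#' \eqn{(a_1\tau_{fret}^2 + a_2\tau_0^2)/(a_1\tau_{fret} + a_2\tau_0)}.
#'
#' @param p A [bi_params()].
#' @param mode `"amplitude_weighted"` or `"intensity_weighted"`.
#' @return Mean lifetime in ns.
#' @export
mean_lifetime <- function(p, mode = c("amplitude_weighted",
                                      "intensity_weighted")) {
  stopifnot(inherits(p, "bi_params"))
  mode <- match.arg(mode)
  if (p$a1 + p$a2 <= 0) stop("a1 + a2 must be > 0", call. = FALSE)
  if (mode == "amplitude_weighted") {
    (p$a1 * p$tau_fret + p$a2 * p$tau0) / (p$a1 + p$a2)
  } else {
    (p$a1 * p$tau_fret^2 + p$a2 * p$tau0^2) /
      (p$a1 * p$tau_fret + p$a2 * p$tau0)
  }
}

# Bin-integrated, periodically wrapped exponential component without IRF:
# counts in bin k for unit amplitude are
#   tau * (exp(-t_k/tau) - exp(-t_{k+1}/tau)) / (1 - exp(-T/tau)),
# the geometric sum over all previous excitation pulses a repetition period
# T apart. Vector over the acquisition's n_bins bins.
wrapped_binned_exp <- function(tau, acq) {
  edges <- (0:acq$n_bins) * acq$bin_width
  raw <- tau * (exp(-edges[-(acq$n_bins + 1)] / tau) -
                exp(-edges[-1] / tau))
  raw / (1 - exp(-acq$period / tau))
}

#' Expected TCSPC histogram: decay convolved with the IRF
#'
#' Forward model of a TCSPC measurement: the ideal exponential decay
#' (integrated over each time bin and wrapped over the laser repetition
#' period, so incomplete decays from previous pulses fold into the early
#' bins) circularly convolved with the instrument response; the constant
#' background is added after convolution. With a delta IRF and a period much
#' longer than the lifetime this reduces to the analytically binned decay.
#'
#' @param params A [mono_params()] or [bi_params()].
#' @param irf An [irf()] whose `bin_width` matches `acq$bin_width`.
#' @param acq An [acq_config()].
#' @return Numeric vector of expected counts per time bin
#'   (length `acq$n_bins`).
#' @export
convolve_with_irf <- function(params, irf, acq) {
  stopifnot(inherits(irf, "irf"), inherits(acq, "acq_config"))
  if (abs(irf$bin_width - acq$bin_width) > 1e-12)
    stop("IRF bin width does not match acquisition bin width", call. = FALSE)
  w <- irf$weights
  if (length(w) < acq$n_bins) w <- c(w, numeric(acq$n_bins - length(w)))
  if (length(w) > acq$n_bins)
    stop("IRF longer than the acquisition window", call. = FALSE)
  fw <- stats::fft(w)
  if (inherits(params, "mono_params")) {
    ideal <- params$amplitude * wrapped_binned_exp(params$tau, acq)
    bg <- params$background
  } else if (inherits(params, "bi_params")) {
    ideal <- params$a1 * wrapped_binned_exp(params$tau_fret, acq) +
      params$a2 * wrapped_binned_exp(params$tau0, acq)
    bg <- params$background
  } else {
    stop("params must be mono_params or bi_params", call. = FALSE)
  }
  out <- Re(stats::fft(stats::fft(ideal) * fw, inverse = TRUE)) / acq$n_bins
  pmax(out, 0) + bg
}

# d/d tau of wrapped_binned_exp: analytic gradient used by the fitters.
# b_k = tau * D_k * g with D_k = e^{-t_k/tau} - e^{-t_{k+1}/tau} and
# g = 1 / (1 - e^{-T/tau}).
wrapped_binned_exp_grad <- function(tau, acq) {
  edges <- (0:acq$n_bins) * acq$bin_width
  t0 <- edges[-(acq$n_bins + 1)]
  t1 <- edges[-1]
  e0 <- exp(-t0 / tau)
  e1 <- exp(-t1 / tau)
  D <- e0 - e1
  E <- exp(-acq$period / tau)
  g <- 1 / (1 - E)
  dD <- (t0 * e0 - t1 * e1) / tau^2
  dg <- E * acq$period / tau^2 * g^2
  D * g + tau * dD * g + tau * D * dg
}

# Circular convolution of an arbitrary per-bin shape with a cached IRF
# spectrum; used by the fitting hot loop to avoid re-transforming the IRF.
conv_shape <- function(shape, fw) {
  n <- length(shape)
  pmax(Re(stats::fft(stats::fft(shape) * fw, inverse = TRUE)) / n, 0)
}
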