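# Shared small-scale fixtures. Sizes are deliberately reduced from the
# 256 x 256 defaults so the whole suite stays fast; the quantities under
# test (per-pixel estimates, class assignments, means) do not depend on
# frame size or focus counts.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(image_size = 96L, n_foci = c(early = 40L, mid = 12L, late = 8L)),
    list(...))
  do.call(phantom_config, args)
}

default_acq <- acq_config()
delta_irf <- irf_delta(default_acq)
gauss_irf <- irf_gaussian(default_acq)

# Analytic bin-integrated mono decay with periodic wrap (independent oracle
# for the forward model): amplitude A, lifetime tau on the acq time axis.
oracle_binned_mono <- function(A, tau, acq) {
  edges <- (0:acq$n_bins) * acq$bin_width
  A * tau * (exp(-edges[-(acq$n_bins + 1)] / tau) - exp(-edges[-1] / tau)) /
    (1 - exp(-acq$period / tau))
}

# Expected counts for a Poisson pixel at a given photon budget.
pixel_mu <- function(tau, photons, irf_use = gauss_irf, acq = default_acq,
                     bg = 0.05) {
  s <- convolve_with_irf(mono_params(1, tau), irf_use, acq)
  s * (photons / sum(s)) + bg
}
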