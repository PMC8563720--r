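test_that("mono_decay matches direct arithmetic and enforces its domain", {
  expect_equal(mono_decay(0, mono_params(100, 2.46)), 100)
  expect_equal(mono_decay(2.46, mono_params(100, 2.46)), 100 / exp(1))
  expect_equal(mono_decay(1.0, mono_params(50, 2.0, background = 5)),
               50 * exp(-0.5) + 5)
  # strictly decreasing without background
  t <- seq(0, 10, by = 0.1)
  expect_true(all(diff(mono_decay(t, mono_params(3, 1.7))) < 0))
  expect_error(mono_params(10, tau = -1), "tau")
  expect_error(mono_params(-1, tau = 2), "amplitude")
})

test_that("bi_decay matches arithmetic, reduces to mono, rejects tau_fret > tau0", {
  p <- bi_params(a1 = 50, a2 = 50, tau_fret = 1.0, tau0 = 2.0)
  expect_equal(bi_decay(2.0, p), 50 * exp(-2) + 50 * exp(-1))
  expect_equal(bi_decay(0, p), 100)
  # single-component limit equals mono_decay
  lim <- bi_params(a1 = 0, a2 = 100, tau_fret = 1, tau0 = 2.47)
  t <- seq(0, 12, by = 0.25)
  expect_equal(bi_decay(t, lim), mono_decay(t, mono_params(100, 2.47)))
  expect_error(bi_params(1, 1, tau_fret = 3, tau0 = 2), "convention")
  expect_error(bi_params(0, 0, 1, 2), "a1 \\+ a2")
})

test_that("fret_efficiency identities hold and domain is enforced", {
  expect_equal(fret_efficiency(2.47, 2.47), 0)
  expect_equal(fret_efficiency(1.0, 2.0), 0.5)
  expect_equal(fret_efficiency(0.741, 2.47), 1 - 0.741 / 2.47) # = 0.70
  expect_error(fret_efficiency(2.5, 2.0), "tau_fret")
  expect_error(fret_efficiency(-1, 2), "lifetimes")
})

test_that("fret_efficiency stays in [0,1] and is monotone in tau_fret", {
  set.seed(42)
  for (i in 1:200) {
    tau0 <- runif(1, 0.5, 6)
    tf <- runif(1, 1e-3, tau0)
    e <- fret_efficiency(tf, tau0)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
  tau0 <- 2.47
  tfs <- seq(0.1, tau0, length.out = 50)
  expect_true(all(diff(fret_efficiency(tfs, tau0)) < 0))
})

test_that("strickler_berg_lifetime is inverse-quadratic and scale-invariant", {
  expect_equal(strickler_berg_lifetime(1.38, 2.46, 1.38), 2.46)
  expect_equal(strickler_berg_lifetime(2 * 1.38, 2.46, 1.38), 2.46 / 4)
  expect_equal(strickler_berg_lifetime(1.38, 2.46, 1.33),
               2.46 * (1.33 / 1.38)^2)
  # scale invariance: doubling both n and n_ref changes nothing
  set.seed(7)
  n <- runif(20, 1.1, 1.6)
  expect_equal(strickler_berg_lifetime(2 * n, 2.46, 2 * 1.38),
               strickler_berg_lifetime(n, 2.46, 1.38))
  # strictly decreasing in n
  expect_true(all(diff(strickler_berg_lifetime(seq(1.2, 1.6, 0.01),
                                               2.46, 1.38)) < 0))
  expect_error(strickler_berg_lifetime(-1, 2, 1.3), "> 0")
  # inverse round-trips
  expect_equal(strickler_berg_ri(
    strickler_berg_lifetime(1.41, 2.47, 1.38), 2.47, 1.38), 1.41)
})

test_that("mean_lifetime modes match their closed forms", {
  lim <- bi_params(0, 5, 1, 2.47)
  expect_equal(mean_lifetime(lim, "amplitude_weighted"), 2.47)
  expect_equal(mean_lifetime(lim, "intensity_weighted"), 2.47)
  eq <- bi_params(2, 2, 1, 3)
  expect_equal(mean_lifetime(eq, "amplitude_weighted"), 2.0)
  expect_equal(mean_lifetime(eq, "intensity_weighted"),
               (1 + 9) / (1 + 3))
  # the default FRET mixture has amplitude-weighted mean 2.24 ns
  pp <- default_photophysics()
  mix <- bi_params(pp$fret_fraction, 1 - pp$fret_fraction,
                   pp$tau_fret, pp$tau_donor)
  expect_equal(mean_lifetime(mix, "amplitude_weighted"), 2.24)
})

test_that("delta-IRF convolution equals the analytic binned wrapped decay", {
  # period chosen >> tau so the wrap factor is ~1
  acq <- acq_config(n_bins = 256L, bin_width = 12.5 / 256, period = 12.5)
  p <- mono_params(80, 0.25)
  out <- convolve_with_irf(p, irf_delta(acq), acq)
  expect_equal(out, oracle_binned_mono(80, 0.25, acq), tolerance = 1e-6)
  # and the closed-form geometric wrap factor at tau = 2.5, period = 12.5:
  tau <- 2.5
  out2 <- convolve_with_irf(mono_params(1, tau), irf_delta(acq), acq)
  nowrap_bin0 <- tau * (1 - exp(-acq$bin_width / tau))
  expect_equal(out2[1], nowrap_bin0 / (1 - exp(-acq$period / tau)),
               tolerance = 1e-9)
})

test_that("convolution conserves counts and is linear in amplitudes", {
  acq <- default_acq
  p <- mono_params(40, 2.3, background = 0.2)
  p0 <- mono_params(40, 2.3)
  for (ir in list(delta_irf, gauss_irf)) {
    out <- convolve_with_irf(p, ir, acq)
    out0 <- convolve_with_irf(p0, ir, acq)
    # background added after convolution, n_bins * background extra counts
    expect_equal(sum(out) - sum(out0), acq$n_bins * 0.2, tolerance = 1e-9)
    # normalized IRF preserves the total
    expect_equal(sum(out0),
                 sum(convolve_with_irf(p0, delta_irf, acq)),
                 tolerance = 1e-9)
  }
  # linearity: bi output = sum of its two mono components
  b <- bi_params(a1 = 30, a2 = 70, tau_fret = 1.2, tau0 = 2.47,
                 background = 0.1)
  s <- convolve_with_irf(mono_params(30, 1.2), gauss_irf, acq) +
    convolve_with_irf(mono_params(70, 2.47), gauss_irf, acq) + 0.1
  expect_equal(convolve_with_irf(b, gauss_irf, acq), s, tolerance = 1e-12)
})

test_that("periodic convolution converges to ordinary convolution", {
  tau <- 1.0
  acq <- acq_config(n_bins = 512L, bin_width = 100 * tau / 512,
                    period = 100 * tau)
  w <- numeric(512); w[1:6] <- c(1, 4, 8, 4, 1, 0.5); w <- w / sum(w)
  ir <- irf(w, acq$bin_width)
  out <- convolve_with_irf(mono_params(10, tau), ir, acq)
  # brute-force ordinary (zero-padded) convolution of the unwrapped decay
  edges <- (0:512) * acq$bin_width
  unwrapped <- 10 * tau * (exp(-edges[-513] / tau) - exp(-edges[-1] / tau))
  lin <- numeric(512)
  for (k in 1:512) {
    j <- 1:k
    lin[k] <- sum(unwrapped[j] * w[k - j + 1])
  }
  sig <- out > max(out) * 1e-12
  expect_equal(out[sig], lin[sig], tolerance = 1e-9)
})

test_that("convolution rejects mismatched bin widths and bad IRFs", {
  acq <- default_acq
  bad <- irf(rep(1 / 10, 10), bin_width = acq$bin_width * 2)
  expect_error(convolve_with_irf(mono_params(1, 2), bad, acq), "bin width")
  expect_error(irf(c(-0.1, 1.1), 0.05), ">= 0")
})

test_that("acq_config validates the time axis and pile-up budget", {
  expect_error(acq_config(n_bins = 300, bin_width = 0.05, period = 12.5),
               "period")
  expect_error(acq_config(pileup_budget = 0), "pileup")
  expect_silent(acq_config())
})
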