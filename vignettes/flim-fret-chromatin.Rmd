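---
title: "Measuring chromatin compaction by FLIM and FLIM-FRET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromatin compaction by FLIM and FLIM-FRET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimfret)
```

## The measurement problem

DNA packing density in the interphase nucleus varies over an order of
magnitude between relaxed euchromatin and dense heterochromatin. Because DNA
and nuclear proteins have similar refractive increments, local chromatin
compaction translates directly into local refractive index (RI), and the
excited-state lifetime of a fluorophore senses that RI: in the
radiative-rate-dominated regime the Strickler–Berg relation reduces to an
inverse-quadratic law,

$$\tau(n) = \tau_{\mathrm{ref}} \left(\frac{n_{\mathrm{ref}}}{n}\right)^2 .$$

Labeling replicating DNA with a fluorophore and imaging its lifetime
(FLIM) therefore reads out compaction: chromatin replicating in early
S-phase (loose, gene-rich) shows longer lifetimes than late-replicating
heterochromatin. A second, independent readout is FLIM-FRET: when two
nucleotide pulses label neighbouring chromatin with a donor and an acceptor
fluorophore, donor molecules within Förster range (< ~10 nm) of an acceptor
are quenched, and the donor decay becomes bi-exponential,

$$f(t) = a_1 e^{-t/\tau_{\mathrm{fret}}} + a_2 e^{-t/\tau_0},$$

with the slow component $\tau_0$ belonging to non-interacting donors. The
per-pixel FRET efficiency is

$$E = 1 - \tau_{\mathrm{fret}}/\tau_0 .$$

This package implements the complete computational chain for both assays —
TCSPC forward model, per-pixel decay fitting, lifetime/FRET maps, discrete
segmentation, histograms and summaries — together with a synthetic
nucleus generator that stands in for raw FLIM data, which are not publicly
available for this kind of experiment.

## Forward model of a TCSPC pixel

A TCSPC histogram accumulates photon arrival times relative to the laser
pulse in `n_bins` bins of width `bin_width` over the repetition period
(defaults: 256 bins × 12.5/256 ns ≈ 48.8 ps, 12.5 ns period, i.e. an 80 MHz
source). The expected bin content for a decay component with lifetime $\tau$
is the *bin-integrated* exponential multiplied by the geometric wrap factor
$1/(1-e^{-T/\tau})$, which folds incomplete decays from all previous pulses
into the window — essential here, since $\tau/T \approx 0.2$ makes the
wrapped tail several percent of the peak. The result is circularly convolved
with the instrument response function (IRF) and the constant background is
added afterwards (`convolve_with_irf()`).

Numerical notes:

* The circular convolution runs on the bin grid, so the wrap of the IRF tail
  assumes the bins tile the period; the default configuration satisfies
  `n_bins * bin_width == period` exactly.
* The default IRF is a Gaussian of FWHM 0.2 ns centred at 1.0 ns (typical
  hybrid-detector response), discretized and renormalized; a delta IRF is
  available as the analytic reference, for which convolution is the
  identity.

## Per-pixel estimation

`fit_mono()`/`fit_bi()` estimate decay parameters per pixel by maximizing
the Poisson likelihood of the forward model (default), or by model-weighted
(Pearson) least squares. Data-weighted (Neyman, $1/y$) least squares was
deliberately rejected: at the ~20 counts/bin typical of these budgets it
biases lifetimes low by several percent because downward-fluctuating bins
receive inflated weight, and it would break the required agreement between
the two objectives (they agree within 1% at a few times $10^4$ photons; at
exactly 5 × 10³ photons individual draws can still differ by ~1.3%, which is
why the cross-check test runs at 2 × 10⁴).

The optimizer is L-BFGS-B with analytic gradients, run in log-parameter
coordinates so lifetimes (~1 ns), amplitudes (~10³) and backgrounds (~10⁻²)
are comparably scaled; the solution is re-polished and restarted once from a
perturbed start on abnormal termination, with no RNG involved, so fits are
deterministic. On noiseless input the fitted lifetime matches a brute-force
grid search to the grid resolution.

SPCImage-style analysis settings are reproduced as configuration:
a signal **threshold of 30 counts** (applied to the spatially binned decay;
`threshold_on = "peak"` gives the peak-bin alternative) and a **binning
factor of 1**, meaning each pixel's decay is aggregated over its 3 × 3
neighbourhood before fitting. Goodness of fit is the Pearson reduced
$\chi^2$ over bins with expected counts ≥ 1 (the floor avoids division
blow-ups in empty tail bins), with 3 parameters for mono fits and 5 (or 4
with fixed $\tau_0$) for bi fits; on correctly specified simulations its
median is ~1.

**Identifiability caveats, stated rather than hidden.**

* With a free constant offset on a 12.5 ns window the wrapped decay never
  reaches the background floor, so the background is weakly identified; its
  estimate (bounded at 0) is biased high, which pulls the lifetime down by
  ~0.01–0.03 ns regardless of photon budget. We keep the free offset (it
  mirrors standard practice); the residual bias is an order of magnitude
  below the ±0.05 ns recovery tolerances used throughout. The same weak
  identifiability makes the small-N → large-N SD scaling deviate from the
  ideal $1/\sqrt{N}$ near the `bg = 0` boundary, which the property test
  acknowledges by requiring a factor > 4 (not 10) over two decades.
* Two-component fits with $\tau_{\mathrm{fret}}/\tau_0 \to 1$ are
  fundamentally degenerate. Fits landing at a ratio > 0.95 carry a
  *collapse* flag and are excluded from FRET maps; pixels whose fitted FRET
  amplitude fraction is below 5% are reported through the donor-only path
  ($E = 0$, class low) because $\tau_{\mathrm{fret}}$ is unidentifiable when
  $a_1 \approx 0$. Individual parameters ($a_1/a_2$ vs
  $\tau_{\mathrm{fret}}$) trade off strongly near the default operating
  point ($\tau_{\mathrm{fret}}/\tau_0 \approx 0.81$); the amplitude-weighted
  mean lifetime, which is what the FRET experiment summarizes, is
  well-determined.
* For bi-exponential analysis $\tau_0$ may be fitted freely per pixel or
  fixed from a donor-only control (`fix_tau0`,
  `estimate_tau0_donor_only()`). The original analysis does not say which
  was used; the default is free, and the acceptance experiments use the
  fixed mode, which is the better-conditioned choice at these budgets.
* Reported "averaged lifetimes" of multi-exponential decays are ambiguous in
  the field; both `amplitude_weighted` and `intensity_weighted` means are
  implemented (`mean_lifetime()`), and the FRET summary pins
  amplitude-weighted, under which the default mixture
  ($a_1 = a_2$, $\tau_{\mathrm{fret}} = 2.01$ ns, $\tau_0 = 2.47$ ns)
  averages to 2.24 ns.

## The synthetic nucleus generator

`generate_phantom()` emulates the three S-phase replication-labeling
patterns on a 256 × 256 frame: an elliptical nucleus with low-frequency
boundary jitter and 2–3 nucleoli; **early** — many (300) small foci
scattered uniformly through the nucleoplasm; **mid/late** — fewer (60/40),
larger foci, 70% of them placed in a 5-px rim band along the nuclear and
nucleolar boundaries and the rest in interior clusters. Counts, radii and
the rim width are config defaults chosen to match published images
qualitatively; none of them influence the acceptance quantities, which are
parameter-recovery means.

The ground truth is compaction: each stage has a reference lifetime
(defaults 2.46 / 2.37 / 2.23 ns for early / mid / late — the published
per-stage means), converted to a per-pixel RI map through the inverse
Strickler–Berg law at the reference point ($\tau_{\mathrm{ref}} = 2.47$ ns
at $n_{\mathrm{ref}} = 1.38$), plus N(0, 0.003) RI jitter for local
heterogeneity. Per-pixel true lifetimes are then recomputed from the RI map
through the forward law, making RI, not lifetime, the primitive quantity.
(The derived stage RIs are ~1.383/1.409/1.452; the late value sits slightly
above the commonly quoted ~1.33–1.42 physiological range — accepting that
is the price of pinning the ground truth to the printed lifetimes, and is
recorded as a design decision.)

`generate_fret_phantom()` reuses the geometry and pins donor focus RI at the
reference, so the unquenched donor lifetime is 2.47 ns: the FRET assay reads
proximity, not compaction. In *simultaneous* labeling mode every donor focus
carries the two-component mixture ($a_1/(a_1+a_2) = 0.5$, ground-truth
$E = 1 - 2.01/2.47 \approx 0.186$); in *sequential* mode each focus is
within acceptor proximity with probability 0.3 (a Bernoulli abstraction of
the acceptor field — the package does not model acceptor photophysics, since
the readout is donor-side).

`simulate_cube()` renders a phantom to photon counts: per-pixel expected
decay from the forward model, scaled to the photon budget (default 2000
photons per focus pixel; 10⁴ for bi-exponential work), a background of
0.005 counts/bin inside the nucleus, then independent Poisson sampling. The
background default is deliberately small so that *unlabeled* nucleoplasm
stays below the 30-count threshold even after 3 × 3 binning, matching the
control observation that autofluorescence never exceeded the threshold.
Pile-up is handled as in the experiment — avoided, not corrected: the cube
records whether expected photons per pixel per excitation cycle
(`n_excitations` defaults to 2 × 10⁵ cycles/pixel) stay within the 10%
budget, and exceeding it is a warning, not an error.

One master seed drives geometry; photon noise takes its own seed, so a fixed
nucleus can be resampled. Identical seeds and configs give bit-identical
phantoms, cubes, and (the fitters being RNG-free) results.

**What a green test does not establish.** The generator makes no attempt at
optical realism: no PSF blur (foci have hard edges), no detector
afterpulsing or IRF drift, no spectral bleed-through, no acceptor channel,
no chromosome-scale spatial correlation of compaction beyond the
stage-level RI classes. Recovery tests therefore validate the estimation
chain against its own forward model at realistic budgets — exactly what a
reanalysis of unavailable raw data can validate — not the microscope.

## Maps, classes and summaries

`segment_map()` discretizes scalar maps with half-open `[low, high)`
intervals: the lifetime scheme is short 2.1–2.35 ns (red) / intermediate
2.35–2.55 ns (green) / long 2.55–2.75 ns (blue); the FRET scheme is low
< 50% (blue) / intermediate 50–70% (green) / high ≥ 70% (red). The prose
ranges leave the boundaries ambiguous; one documented convention is used
everywhere, so τ = 2.35 ns is "intermediate" and E = 0.70 is "high".
Out-of-range values land in explicit `under`/`over` overflow classes rather
than being clipped. Histograms (`map_histogram()`) use 0.02-wide bins
aligned to multiples of the width; group summaries
(`summarize_by_group()`) default to intensity-weighted means (per-pixel
photon counts as weights — photon-rich pixels carry more information), with
pairwise group differences reported in ps.

## Files and the command line

Cubes travel as multi-page TIFF (one 16-bit page per time bin, promoted to
32-bit when counts overflow) plus a JSON sidecar with acquisition metadata,
provenance and the pile-up check; maps as 32-bit float TIFF; class maps as
plain-text PPM with a JSON legend; tables as CSV. The TIFF codec is
implemented in-package (baseline little-endian subset) because no TIFF
library is available in the supported dependency set; PPM replaces paletted
PNG for the same reason. Vendor TCSPC formats (.sdt/.ptu) are out of scope.
`cli_main()` provides `simulate`, `fit`, `fret`, `segment` and `report`
subcommands with uniform `--config/--seed/--outdir/--verbose` flags and
0/1/2 exit codes (success / runtime / config error); any output is
reproducible from the config digest and seed that every run logs.

## Known limitations

* Per-pixel fitting only; no global or phasor analysis.
* Donor-side modeling only; acceptor decays and spectral overlap are not
  simulated.
* The FRET-population histogram is reported as-is; no mixture-model
  decomposition is attempted.
* The free-background lifetime bias (~0.5%) discussed above is inherent to
  the 80 MHz window; fixing the background from dark regions would remove it
  at the cost of a per-image preprocessing convention.
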