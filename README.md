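# flimfret

Fluorescence lifetime imaging (FLIM) and FLIM-FRET analysis of chromatin
compaction in the cell nucleus, for microscopists and image analysts who
want a scriptable, testable replacement for point-and-click TCSPC analysis.

## What it computes

Chromatin packing density sets the local refractive index *n*, and a
fluorophore's lifetime senses it through the reduced Strickler–Berg law

    tau(n) = tau_ref * (n_ref / n)^2

so replication-labeled DNA reads out compaction per pixel: early-S-phase
(loose) chromatin shows longer lifetimes than late-S-phase heterochromatin.
Independently, dual-pulse labeling with a donor/acceptor pair turns donor
quenching into a proximity assay: the donor decay becomes

    f(t) = a1 * exp(-t / tau_fret) + a2 * exp(-t / tau0)

and the per-pixel FRET efficiency is `E = 1 - tau_fret / tau0`.

The package provides:

* **decay models** — exponential decays, periodic (wrap-around) IRF
  convolution for 80 MHz-style TCSPC, Strickler–Berg conversions, FRET
  efficiency, amplitude/intensity-weighted mean lifetimes;
* **synthetic data** — nucleus phantoms with early/mid/late S-phase
  replication-labeling geometry, RI ground truth, donor-only and FRET
  variants, Poisson photon simulation with a pile-up budget check
  (`generate_phantom()`, `generate_fret_phantom()`, `simulate_cube()`);
* **fitting** — per-pixel mono/bi-exponential Poisson-MLE fits with
  SPCImage-style threshold (30 counts) and 3×3 binning, reduced chi-square,
  donor-only tau0 reference (`fit_mono()`, `fit_bi()`, `fit_image()`,
  `estimate_tau0_donor_only()`);
* **mapping** — color-coded lifetime classes (short 2.1–2.35 ns,
  intermediate 2.35–2.55 ns, long 2.55–2.75 ns), FRET maps with
  low/intermediate/high classes (<50%, 50–70%, ≥70%), histograms, per-group
  summaries (`segment_map()`, `compute_fret_map()`, `map_histogram()`,
  `summarize_by_group()`, `render_class_map()`);
* **I/O + CLI** — multi-page TIFF cubes with JSON sidecars, float map TIFFs,
  PPM class maps, CSV tables, and a `simulate / fit / fret / segment /
  report` command line (`cli_main()`, wrapper in `inst/scripts/flimfret`).

## Worked example

Recover the early-vs-late S-phase compaction difference from synthetic
nuclei (128 px frame to keep it quick; defaults are 256 px):

```r
library(flimfret)

cfg <- phantom_config(image_size = 128L,
                      n_foci = c(early = 80L, mid = 18L, late = 12L))
acq <- acq_config()            # 256 bins x 48.8 ps, 12.5 ns period
ir  <- irf_gaussian(acq)       # 0.2 ns FWHM instrument response

fit_one <- function(stage) {
  ph   <- generate_phantom(stage, cfg, seed = 1)
  cube <- simulate_cube(ph, ir, acq, seed = 2)
  lm   <- fit_image(cube, ir, fit_config())   # mono MLE, threshold 30, binning 1
  g <- matrix(NA_character_, 128, 128)
  g[ph$labels == 3L & lm$mask] <- stage       # labeled replication foci
  list(map = lm, summary = summarize_by_group(lm, g))
}
early <- fit_one("early"); late <- fit_one("late")
rbind(early$summary, late$summary)
#>   group n_pixels mean_tau_ns sd_tau_ns mean_E
#> 1 early      517        2.45   0.03378     NA
#> 2  late      501        2.23   0.02500     NA
```

The intensity-weighted mean fitted lifetime of the labeled foci is ~2.45 ns
in the early-S phantom and ~2.23 ns in the late-S phantom — a ~220 ps
shortening, reflecting the higher refractive index (denser packing) of
late-replicating heterochromatin that the generator encodes as ground
truth. Segmenting the late map with the lifetime color scheme puts
essentially all foci in the "short" (2.1–2.35 ns, red) class:

```r
class_counts(segment_map(late$map$tau_map, lifetime_scheme(), late$map$mask))
#>          class n_pixels
#> 1        under        3
#> 2        short      884
#> 3 intermediate        8
#> 4         long        0
#> 5         over        0
```

(The count exceeds the summary's `n_pixels` because fitted halo pixels
around each focus are classified too.)

For the FRET assay, `generate_fret_phantom()` + `fit_image(model = "bi",
fix_tau0 = ...)` + `compute_fret_map()` produce per-pixel efficiency maps
and low/intermediate/high class images; see the methods vignette
(`vignettes/flim-fret-chromatin.Rmd`) for the model, parameter and
identifiability discussion.

## Command line

```sh
Rscript inst/scripts/flimfret simulate --config=default --seed=1 --outdir=run
Rscript inst/scripts/flimfret fit      --cube=run/cube.tif --outdir=run
Rscript inst/scripts/flimfret segment  --map=run/tau.tif   --outdir=run
Rscript inst/scripts/flimfret report   --map=run/tau.tif   --outdir=run
```

Exit codes: 0 success, 1 runtime failure, 2 configuration error. Every run
logs its config digest and seed; outputs are reproducible from those alone.

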