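Package: flimfret
Title: FLIM and FLIM-FRET Analysis of Chromatin Compaction
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-pixel analysis of time-correlated single photon counting
    (TCSPC) fluorescence lifetime imaging (FLIM) data: mono- and
    bi-exponential decay fitting with periodic instrument-response
    convolution, Strickler-Berg refractive-index to lifetime sensing,
    FRET efficiency mapping (E = 1 - tau_fret/tau0), discrete lifetime and
    FRET segmentation schemes, and a synthetic nucleus phantom generator
    that emulates early-, mid-, and late-S-phase replication labeling
    patterns with Poisson photon statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
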