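{
  "stage": "late",
  "phantom": {
    "image_size": 128,
    "n_foci": {"early": 80, "mid": 18, "late": 12},
    "photons_per_pixel": 2000
  },
  "fit": {"model": "mono", "threshold_counts": 30, "binning_factor": 1},
  "scheme": "lifetime"
}
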