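{
  "seed": 1,
  "dissociation": {
    "label": "WT",
    "populations": [
      {
        "label": "fast",
        "k_off": 0.909090909090909,
        "diffusion_coeff": 0.31,
        "fraction": 0.76
      },
      {
        "label": "slow",
        "k_off": 0.32258064516129,
        "diffusion_coeff": 0.02,
        "fraction": 0.24
      }
    ],
    "k_bleach": 3,
    "tau_int": 0.02,
    "tau_TL": [0.02, 0.12, 0.22],
    "n_events": 60000,
    "n_replicates": 30,
    "model": "biexp",
    "track_mode": "truth",
    "radius_um": 0.32,
    "min_track_len": 2
  },
  "diffusion": {
    "D": 0.31,
    "n_tracks": 1000,
    "n_frames": 100,
    "tau_TL": 0.02,
    "loc_error_sd": 0.025,
    "fit_fraction": 0.25,
    "thresholds": [0.1, 0.01],
    "bin_um": 0.5
  },
  "gradient": {
    "n_cells": 240,
    "profile_length": 4.5,
    "step": 0.05,
    "amplitude_median": 100,
    "amplitude_gsd": 1.6,
    "lambda0": 1.5,
    "beta": 0.5,
    "background": 0,
    "noise_frac_sd": 0.05,
    "smooth_sigma_um": 0.2,
    "drop_head": 0.5,
    "bin_fraction": 0.05,
    "window_mid": 1.5,
    "window_pole": 0.83
  }
}
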