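{
  "k_on": 10000,
  "k_off": 0.001,
  "R_max_deg": 0.6,
  "noise_sd_deg": 0.002,
  "bulk_shift_deg": 0.05,
  "dt_s": 1,
  "seed": 42,
  "schedule": {
    "start_s": 60,
    "association_s": 720,
    "dissociation_s": 180,
    "concentration_uM": 100
  }
}
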