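{
  "n_subjects": 6,
  "n_blocks": 5,
  "trials_per_block": 7,
  "native_rate": 30000,
  "effect_mean": 0,
  "effect_trial": {"mcn_to_vlpag": -0.4, "vlpag_to_mcn": 0},
  "effect_freeze": {"mcn_to_vlpag": -0.05, "vlpag_to_mcn": 0},
  "subject_sd": 0.1,
  "noise_snr_db": 10,
  "freeze_start": 80,
  "freeze_end": 10,
  "freeze_noise_sd": 10,
  "freeze_subject_sd": 10,
  "seed": 1
}
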