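{
  "seed": 42,
  "stages": {"wsbm": true, "boundary": true, "genes": false, "hopf": false},
  "cohort": {"parcellation_scale": "small", "n_subjects": 15, "n_timepoints": 120},
  "wsbm": {"restarts": 8, "n_boot": 300},
  "boundary": {"n_perm": 2000}
}
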