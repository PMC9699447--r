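{
  "units": ["H3N1P1", "H4N1P1", "H4N2P2"],
  "lengths": [50, 120],
  "Tstar_grid": [0.4, 0.8, 1.2],
  "seeds": [1, 2, 3],
  "steps_per_leg": 100000,
  "equilibration_steps": 25000,
  "snapshot_stride": 1000,
  "sample_stride": 100
}
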