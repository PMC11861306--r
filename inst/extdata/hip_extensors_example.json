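{
  "muscle_group": "hip extensors",
  "FC0": 0.00912,
  "RC0": 0.00094,
  "r": 7.5,
  "L": 20,
  "k": 0.0319,
  "RP0": 3.2e-05,
  "FP0_over_RP0": 552,
  "provenance": "k, RP0, FP0_over_RP0: hip-extensor calibration of the velocity-dependent model against an alternating isometric/isokinetic dynamometer protocol (see muscle_group_parameters()). FC0, RC0, r: generalized three-compartment fatigue/recovery constants from the model's lineage; supply joint-specific values where available. L: conventional controller gain."
}
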