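# Example porolung run configuration.  Unset keys take the package defaults
# (nu = 0.4, tissue density 700 kg/m3, breathing period 4 s, stiffness
# statistics 10-500 Pa with volume-weighted mean 178 Pa).
phantom:
  target_edge_length: [0.015, 0.020, 0.025]
material:
  correlation_length: 0.08
  axis_contrast: [1.25, 1.0, 0.8]
waveform:
  amplitude: 300
solver:
  dt: 0.02
  n_cycles: 3
output_dir: porolung-out
seed: 1
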