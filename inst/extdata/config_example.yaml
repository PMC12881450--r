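params_file: params_calibrated.yaml
protocol:
  kind: bolus
  dose: 1.0
  window: [-24, 0]
integrator:
  rtol: 1.0e-8
  atol: 1.0e-10
  grid_dt: 0.1
t_end: 24
seed: 1
outdir: mirseize_out
scan:
  kind: bolus
  ladder: [0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.1, 1.2]
sensitivity:
  arm: control
  N: 1000
  M: 4
  NR: 5
synth:
  noise_sd: 0.1
  replicates: 4
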