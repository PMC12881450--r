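model:
  lam_R1: 0.35
  lam_R2: 0.35
  lam_R3: 0.35
  lam_T: 0.02
  lam_S: 0.01
  k1: 0.25
  k2: 1.0
  k3: 0.25
  k4: 1.0
  k5: 0.25
  k6: 1.0
  k7: 0.82
  k8: 1.0
  k9: 0.536
  k10: 1.0
  alpha: 60.0
  beta: 60.0
  gamma: 60.0
  delta: 1.2
  eps: 0.9
  zeta: 2.4
  eta: 0.9
  theta: 0.6
  kappa: 2.0
  lam: 0.03
  mu_A1: 0.0577623
  mu_A2: 0.0577623
  mu_A3: 0.0577623
  mu_R1: 0.5
  mu_R2: 0.5
  mu_R3: 0.5
  mu_T: 0.12
  mu_S: 0.12
  se_source_multiplier: 1.5
thresholds:
  th_T: 0.935
  th_S: 0.993
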