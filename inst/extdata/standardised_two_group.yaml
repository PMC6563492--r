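# Two-group study on the standardised time region [-1, 1], four
# occasions with fixed endpoints, polynomial retention functions
# (group 1 quadratic, group 2 linear), flexible scheduling condition.
seed: 1
model:
  model: Mg
  groups: 2
  random_class: RIRS
  d11: 1
  d22: 3
  sigma2: 1
  corr_kind: ar1
  rho: 0.5
dropout:
  - family: quadratic
    coefficients: [0.5, -0.35, 0.15]
  - family: linear
    coefficients: [0.65, -0.35]
problem:
  time_region: [-1, 1]
  times: [-1, null, null, 1]
  condition: flexible
  n_total: 100
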