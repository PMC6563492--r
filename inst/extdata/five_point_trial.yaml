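# One-year two-arm dementia trial: five-occasion D-optimal design problem.
# Random-intercept model with AR(1) day-scale errors; logistic dropout in
# dose and time. Baseline and first follow-up (day 42) and end of study
# (day 364) are fixed; the two middle occasions, the lower dose level and
# the allocation weight are optimized.
seed: 1
model:
  model: Md
  groups: 2
  beta: [8.939, -0.0866, 0.01458]
  random_class: RI
  d11: 7.080921        # 2.661^2
  sigma2: 6.827769     # 2.613^2
  corr_kind: ar1
  rho: 0.3326
dropout:
  family: logistic
  coefficients: [-2.2332, -0.0131, 0.0100]
  baseline_certain: true
problem:
  time_region: [0, 364]
  times: [0, 42, null, null, 364]
  condition: restricted
  doses: [null, 100]
  dose_region: [0, 100]
  n_total: 144
cost:
  recruit_cost: 2
  visit_cost: 1
  budget: 864          # 144 * (2 + 4): the five-occasion reference trial
  q_values: [5, 4]
simulation:
  reps: 20000
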