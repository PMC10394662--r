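# Default pipeline configuration: published rate constants (min^-1),
# 10 sampling times on 0-360 min, pure reactant charge, 2% multiplicative
# measurement noise, bound-constrained least squares with Laplace
# uncertainty.
k:
  - 0.000821
  - 0.003175
  - 0.001472
  - 0.002501
  - 0.000199
  - 0.001776
  - 0.002285
  - 0.0
  - 0.0
  - 0.000241
  - 0.000359
  - 0.000617
design:
  times: [0, 40, 80, 120, 160, 200, 240, 280, 320, 360]
  c0: [1, 0, 0, 0, 0, 0, 0, 0, 0]
noise:
  kind: multiplicative_gaussian
  sigma: 0.02
  clip_negative: true
fit:
  initial_guess: 0.01
  lower_bound: 0.0
  uncertainty: laplace
  weighting: uniform
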