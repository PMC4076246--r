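'n': 2519
confounder_spec:
  age:
    dist: uniform_int
    min: 18.0
    max: 49.0
  education:
    dist: categorical
    prob:
    - 0.15
    - 0.45
    - 0.3
    - 0.1
  marital:
    dist: bernoulli
    prob: 0.6
  gravidity:
    dist: truncated_poisson
    lambda: 3.0
    max: 12.0
  cd4_nadir:
    dist: lognormal
    meanlog: 5.521460917862246
    sdlog: 0.8
beta_A:
  intercept: -0.91
  age: -0.02
  education: 0.25
  marital: 0.35
  gravidity: 0.04
  cd4_nadir: 0.0008
beta_Y:
  intercept: -2.54
  age: 0.015
  education: -0.12
  marital: -0.08
  gravidity: 0.04
  cd4_nadir: -0.0012
  A: 0.35
visit_spec:
  months:
    shape: 2.0
    scale: 12.0
  frac:
    shape1: 2.0
    shape2: 2.0
miss_spec:
  cd4_nadir:
    intercept: -2.0
    'Y': 0.5
    A: 0.3
  education:
    intercept: -2.8
    'Y': 0.4
misclass:
  sensitivity: 1.0
  specificity: 1.0
seed: 1
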