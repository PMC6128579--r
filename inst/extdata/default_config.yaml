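# Default pipeline configuration.
# Geometry: the 25 x 13 m studied area, sensor 1 at the origin, six
# location sensors on the boundary, headlocks along the y = 0 wall.
geometry:
  length_m: 25
  width_m: 13
  S: 14
  sensors: ~        # 6 x 2 list of [x, y]; ~ = default boundary layout
  reference: ~      # [x, y]; ~ = area center
  headlock: ~       # two endpoints; ~ = the y = 0 wall

# Lognormal shadowing channel. sigma is the simulated shadowing noise (dB);
# ranging always inverts the noise-free curve. reference_measured, if set,
# gives the six RSSI-measured reference-to-sensor distances (m) used to
# compute the ranging correction coefficient.
shadowing:
  P0: -40
  d0: 1
  exponent: 2.5
  sigma: 1
  reference_measured: ~

ensemble:
  L: 10
  weak_learner: nnet
  hidden_units: 10
  maxit: 200
  feature_mode: raw

fusion:
  eps1: 0.2
  eps2: 0.03
  body_length: 1.5
  error_max: 1.30

synthetic:
  n_per_class: 100
  feeding_overlap_amp: 0.05
  n_tags: 5

split:
  train_frac: 0.6

evaluation:
  bootstrap_B: 1000
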