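# Starting values for the kittiwake HMM state-dependent distributions.
# Two colony states (quiet and active nest attendance) are merged to
# "colony" after decoding. Log-normal locations are natural-scale medians.
# The flying WBF location starts at the center of the kittiwake flight
# band (3-6 Hz); starting it near the murre wing-beat frequency hands the
# flight observations to the swimming state before EM can correct it.
states: [colony1, colony2, flying, swimming]
behavior_map:
  colony1: colony
  colony2: colony
  flying: flying
  swimming: swimming
bin: 10
forbidden:
  - [colony1, swimming]
  - [swimming, colony1]
  - [colony2, swimming]
  - [swimming, colony2]
pitch:
  family: normal
  mean: [35, 10, 0, 5]
  sd: [10, 10, 5, 5]
activity:
  family: zero-inflated log-normal
  location: [0.05, 0.05, 0.6, 0.15]
  scale: [0.5, 0.5, 0.5, 0.5]
  zero_mass: [0.9, 0.9, 0.1, 0.1]
wbf:
  family: zero-inflated log-normal
  location: [0.5, 2, 4.5, 2]
  scale: [0.5, 0.5, 0.2, 0.5]
  zero_mass: [0.9, 0.9, 0.1, 0.9]
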