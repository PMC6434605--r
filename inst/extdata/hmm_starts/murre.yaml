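# Starting values for the murre HMM state-dependent distributions.
# Log-normal locations are natural-scale medians (exp(meanlog)).
# Bernoulli depth probabilities are held fixed through fitting.
states: [colony, diving, flying, swimming]
behavior_map:
  colony: colony
  diving: diving
  flying: flying
  swimming: swimming
bin: 5
forbidden:
  - [colony, swimming]
  - [swimming, colony]
  - [colony, diving]
  - [diving, colony]
  - [diving, flying]
  - [flying, diving]
pitch:
  family: normal
  mean: [30, -5, 0, -5]
  sd: [20, 50, 5, 10]
activity:
  family: exponential
  rate: [25, 5, 2.5, 5]
wbf:
  family: zero-inflated log-normal
  location: [0.5, 2, 9, 2]
  scale: [0.5, 0.5, 0.2, 0.5]
  zero_mass: [0.9, 0.9, 0.1, 0.9]
depth:
  family: bernoulli
  prob: [1.0e-12, 0.999999999999, 1.0e-12, 1.0e-12]
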