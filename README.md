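# ethogramr

Behavioral classification of seabird biologger data.

Time-activity budgets — hours per day spent at the colony, flying,
swimming, and (for divers) underwater — underpin much of seabird
behavioral ecology and energetics, but wide-ranging species cannot be
observed directly. `ethogramr` builds these budgets from back-mounted
biologgers (tri-axial acceleration at 25 Hz, depth at 1 Hz, GPS fixes at
30–60 s) for two study systems, thick-billed murres (*Uria lomvia*) and
black-legged kittiwakes (*Rissa tridactyla*), and asks the practical
question: does the choice of classification method matter?

The pipeline:

1. **Metrics** — static acceleration `S` (2-s moving mean), pitch
   `atan(S_X / sqrt(S_Y^2 + S_Z^2))`, dynamic acceleration
   `D = raw − S`, ODBA `|D_X| + |D_Y| + |D_Z|`, 2-s moving SDs
   (`SD_ODBA` for murres, `SD_Z` for kittiwakes), and wing-beat
   frequency (WBF): the dominant 5-s FFT frequency of the heave axis
   with sub-bin peak interpolation and a spectral noise floor. Pitch is
   standardised to 0° over presumed flight (WBF in 6–9 Hz for murres,
   3–6 Hz for kittiwakes) to remove tag-mounting offsets.
2. **Segmentation** — per-second diving/flying labels, a 3-s minimum
   bout rule, and segments capped at 120 s with per-segment mean
   metrics.
3. **Six classifiers** — histogram segregation (HS), k-means (KM),
   Gaussian-mixture EM, a 5-node neural network (NN) and a 500-tree
   random forest (RF) trained on HS labels, and a constrained hidden
   Markov model (HMM) with the six impossible transitions (colony↔water
   without flight, diving↔flying) pinned to zero and Viterbi decoding.
4. **Validation** — GPS ground-speed rules (flying > 2 m/s murre /
   3 m/s kittiwake; colony within 250 m of the nest; speed errors
   > 30 / 20 m/s excluded; transition windows of 60 / 30 s excluded)
   provide independent reference labels; accuracy comes from confusion
   matrices at the fix resolution.
5. **Energetics** — daily energy expenditure from behavior-specific
   coefficients, e.g. murres: `DEE = 32.0·t_c + 532.8·t_f + 100.8·t_s +
   97.2·t_d` kJ/day.
6. **Variable selection** — forward selection with random forests over
   an extended 42-metric library (plus depth for murres).

A semi-Markov simulator generates full synthetic deployments
(acceleration, depth, GPS) with the documented class-conditional
structure, so the whole pipeline runs and is tested without any field
data.

## Worked example

```r
library(ethogramr)

cfg <- species_config("murre", "chick")
dep <- simulate_deployment(cfg, hours = 12, seed = 1, bird_id = "demo")

f <- calibrate_pitch(compute_features(dep$trace, cfg), cfg)
eth <- classify_hs(f, cfg)[["demo"]]

fi  <- round(dep$gps$t * 25) + 1
lab <- label_gps_murre(dep$gps, dep$trace$depth[fi], nest = c(0, 0), cfg)
lab <- mark_transitions(lab, cfg$transition_window)
score_ethogram(eth, lab, cfg)
```

```
Overall accuracy: 1.000 (684 fixes used, 36 excluded)
          predicted
reference  colony diving flying swimming
  colony      329      0      0        0
  diving        0     13      0        0
  flying        0      0     62        0
  swimming      0      0      0      280
Balanced accuracy:
  colony   diving   flying swimming
       1        1        1        1
```

684 GPS fixes overlap the 12-h deployment after dropping the 36 within
a transition window; the histogram-segregation ethogram agrees with the
GPS reference at every one of them.
`daily_energy(activity_budget(eth, cfg), cfg)` converts the budget to
energy — 1,351 kJ for these 12 hours, the 1.2 hours of flight costing
more than three times the 5.6 hours at the colony.

The `analysis/` scripts run the same workflow as a narrative sequence
(simulate → features → classify → validate → energetics → variable
selection), writing tables under `results/`.

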