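test_that("state sequences honor the adjacency constraints", {
  cfg <- species_config("murre")
  st <- simulate_states(cfg, hours = 24, seed = 1)
  expect_setequal(unique(st$states),
                  c("colony", "flying", "swimming", "diving"))
  pairs <- cbind(st$bout_table$behavior[-nrow(st$bout_table)],
                 st$bout_table$behavior[-1])
  forbidden <- rbind(c("colony", "swimming"), c("swimming", "colony"),
                     c("colony", "diving"), c("diving", "colony"),
                     c("diving", "flying"), c("flying", "diving"))
  for (r in seq_len(nrow(forbidden))) {
    expect_false(any(pairs[, 1] == forbidden[r, 1] &
                       pairs[, 2] == forbidden[r, 2]))
  }
  # dives only inside swimming bouts: every dive is preceded and followed
  # by swimming
  dv <- which(st$bout_table$behavior == "diving")
  dv <- dv[dv > 1 & dv < nrow(st$bout_table)]
  expect_true(all(st$bout_table$behavior[dv - 1] == "swimming"))
  expect_true(all(st$bout_table$behavior[dv + 1] == "swimming"))
  expect_equal(st$bout_table$behavior[1], "colony")
})

test_that("state simulation is deterministic, respects the label set, \
and never emits bouts under 10 s", {
  cfgk <- species_config("kittiwake")
  s1 <- simulate_states(cfgk, hours = 12, seed = 9)
  s2 <- simulate_states(cfgk, hours = 12, seed = 9)
  expect_identical(s1$states, s2$states)
  expect_false("diving" %in% s1$states)
  interior <- s1$bout_table[-nrow(s1$bout_table), ]
  expect_true(all(interior$end - interior$start >= 10))
  expect_error(simulate_states(cfgk, hours = 0), "positive")
})

test_that("simulated acceleration realises the configured class structure", {
  cfg <- species_config("murre")
  par <- behavior_params("murre")

  # colony-only hour: recomputed mean pitch matches the configured mean
  # once the known mounting offset is removed
  st <- as_state_sequence(rep("colony", 3600), "c")
  agg_pitch <- sapply(1:6, function(s) {
    tr <- simulate_accel(st, par, cfg, seed = s, mounting_offset = 4)
    f <- compute_features(tr, cfg)
    mean(f$pitch) - 4
  })
  expect_equal(mean(agg_pitch), par$colony$pitch_mean,
               tolerance = 2 * par$colony$pitch_sd / sqrt(6) + 0.5)

  # flight-only: dominant 5-s frequency inside the murre band for >99%
  # of windows
  stf <- as_state_sequence(rep("flying", 3600), "f")
  trf <- simulate_accel(stf, par, cfg, seed = 2, mounting_offset = 0)
  ff <- compute_features(trf, cfg)
  expect_gt(mean(ff$WBF >= 6 & ff$WBF <= 9), 0.99)

  # dives descend below -1 m in every dive bout
  std <- simulate_states(cfg, hours = 24, seed = 3)
  trd <- simulate_accel(std, par, cfg, seed = 3)
  bt <- std$bout_table
  for (i in which(bt$behavior == "diving")) {
    d <- trd$depth[(bt$start[i] * 25 + 1):(bt$end[i] * 25)]
    expect_lt(min(d), -1)
  }
  # determinism
  tr_a <- simulate_accel(st, par, cfg, seed = 11)
  tr_b <- simulate_accel(st, par, cfg, seed = 11)
  expect_identical(tr_a$Z, tr_b$Z)
})

test_that("simulated GPS kinematics satisfy the labelling rules", {
  coh <- murre_cohort()
  cfg <- species_config("murre")
  for (b in names(coh$gps)) {
    gps <- coh$gps[[b]]
    truth <- attr(gps, "true_behavior")
    speed <- ground_speed(gps)
    dist <- sqrt(gps$x^2 + gps$y^2)
    colony_fix <- truth == "colony"
    expect_gt(mean(dist[colony_fix] <= cfg$colony_radius), 0.98)
    # interior flight fixes move faster than the flight-speed rule
    fly <- which(truth == "flying")
    fly <- fly[fly > 1 & (fly - 1) %in% fly]  # consecutive flight fixes
    if (length(fly) > 3) {
      expect_gt(mean(speed[fly] > cfg$gps_flight_speed), 0.95)
    }
  }
  kcoh <- kittiwake_cohort()
  kcfg <- species_config("kittiwake")
  for (b in names(kcoh$gps)) {
    gps <- kcoh$gps[[b]]
    truth <- attr(gps, "true_behavior")
    speed <- ground_speed(gps)
    swim <- which(truth == "swimming")
    swim <- swim[swim > 1 & (swim - 1) %in% swim]
    if (length(swim) > 3) {
      expect_gt(mean(speed[swim] < kcfg$gps_flight_speed), 0.95)
    }
  }
})
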