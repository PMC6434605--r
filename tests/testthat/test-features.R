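test_that("static acceleration is an identity on constant traces and \
averages out a fast sine", {
  tr <- toy_trace(secs = 20)
  S <- static_acceleration(tr)
  expect_equal(S$S_X, rep(0, nrow(tr)))
  expect_equal(S$S_Z, rep(1, nrow(tr)))

  tr2 <- toy_trace(secs = 20, tone_hz = 8, tone_amp = 1)
  S2 <- static_acceleration(tr2)
  interior <- 100:(nrow(tr2) - 100)
  expect_lt(max(abs(S2$S_Z[interior] - 1)), 0.05)

  expect_error(static_acceleration(tr, window = 0.01), "two samples")
})

test_that("pitch reproduces worked angles and is scale invariant", {
  expect_equal(pitch_angle(0, 0, 1), 0)
  expect_equal(pitch_angle(1, 0, 0), 90)
  expect_equal(pitch_angle(1, 0, 1), 45)
  expect_equal(pitch_angle(0.4, 0.1, 0.9),
               pitch_angle(4, 1, 9))
  expect_true(is.na(pitch_angle(0, 0, 0)))
  s <- runif(50, -1, 1)
  expect_true(all(abs(pitch_angle(s, runif(50), runif(50))) <= 90))
})

test_that("raw = static + dynamic exactly, and ODBA is the absolute sum", {
  tr <- toy_trace(secs = 30, tone_hz = 5, tone_amp = 0.8, noise_sd = 0.2)
  S <- static_acceleration(tr)
  D <- dynamic_and_odba(tr, S)
  expect_equal(S$S_X + D$D_X, tr$X)
  expect_equal(S$S_Y + D$D_Y, tr$Y)
  expect_equal(S$S_Z + D$D_Z, tr$Z)
  expect_equal(D$ODBA, abs(D$D_X) + abs(D$D_Y) + abs(D$D_Z))
  expect_true(all(D$ODBA >= 0))
  expect_true(all(D$SD_Z >= 0 & D$SD_ODBA >= 0))

  # worked value: |0.1| + |-0.2| + |0.3| = 0.6
  expect_equal(abs(0.1) + abs(-0.2) + abs(0.3), 0.6)
  const <- toy_trace(secs = 10)
  Dc <- dynamic_and_odba(const, static_acceleration(const))
  expect_equal(Dc$ODBA, rep(0, nrow(const)))
  expect_equal(Dc$SD_ODBA, rep(0, nrow(const)))
})

test_that("moving SD of i.i.d. Gaussian dynamic noise approaches the \
population SD", {
  set.seed(42)
  n <- 25 * 600
  z <- rnorm(n, 0, 0.2)
  tr <- as_accel_trace(data.frame(t = (0:(n - 1)) / 25,
                                  X = 0, Y = 0, Z = 1 + z))
  D <- dynamic_and_odba(tr, static_acceleration(tr))
  # windowed SD has a small negative bias (N denominator, 50 samples)
  expect_equal(mean(D$SD_Z), 0.2, tolerance = 0.02)
})

test_that("WBF recovers pure-tone frequencies to sub-bin accuracy", {
  fs <- 25
  t <- (0:(fs * 30 - 1)) / fs
  # exact-bin tone: 8.0 Hz is the 40th bin of a 125-sample window
  z8 <- sin(2 * pi * 8 * t)
  expect_equal(wbf(z8, fs, at = 300), 8, tolerance = 1e-6)
  expect_equal(wbf(rep(1, fs * 30), fs, at = 300), 0)

  # off-bin tone with quadratic interpolation, checked against a dense
  # zero-padded DFT oracle
  dense_peak <- function(z) {
    zp <- c(z - mean(z), rep(0, 8067))  # 8192-point zero-padded DFT
    P <- Mod(stats::fft(zp))^2
    k <- which.max(P[2:4096])
    k * fs / 8192
  }
  for (f0 in c(8.1, 4.16, 2.3, 6.93)) {
    zf <- sin(2 * pi * f0 * t + 0.7)
    win <- zf[(300 - 62):(300 + 62)]
    expect_equal(wbf(zf, fs, at = 300), dense_peak(win), tolerance = 0.05)
    expect_equal(wbf(zf, fs, at = 300), f0, tolerance = 0.05)
  }
  expect_error(wbf(z8[1:50], fs), "exceeds the trace length")
})

test_that("WBF property sweep: any frequency in (0.5, Nyquist-0.5) is \
recovered within half a refined bin", {
  fs <- 25
  t <- (0:(fs * 20 - 1)) / fs
  set.seed(3)
  for (f0 in runif(12, 0.6, 11.9)) {
    z <- sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
    est <- wbf(z, fs, at = 250)
    expect_lt(abs(est - f0), 0.1)
  }
})

test_that("pitch calibration recovers a simulated mounting offset", {
  cfg <- species_config("murre")
  par <- behavior_params("murre")
  st <- as_state_sequence(rep(rep(c("colony", "flying"), 8), each = 300),
                          "cal")
  tr <- simulate_accel(st, par, cfg, seed = 5, mounting_offset = 9)
  f <- compute_features(tr, cfg)
  cal <- calibrate_pitch(f, cfg)
  expect_equal(attr(cal, "pitch_offset"), 9, tolerance = 1)
  band <- cfg$flight_wbf_band
  in_band <- cal$WBF >= band[1] & cal$WBF <= band[2]
  expect_lt(abs(mean(cal$pitch[in_band])), 1e-9)

  # no presumed flight: warning, unchanged
  st2 <- as_state_sequence(rep("colony", 600), "nofly")
  tr2 <- simulate_accel(st2, par, cfg, seed = 6, mounting_offset = 9)
  f2 <- compute_features(tr2, cfg)
  expect_warning(cal2 <- calibrate_pitch(f2, cfg), "uncalibrated")
  expect_equal(cal2$pitch, f2$pitch)
})

test_that("extended metrics: 42 accelerometer columns plus murre depth, \
with correct windowed statistics", {
  expect_length(extended_metric_names(FALSE), 42)
  expect_length(extended_metric_names(TRUE), 43)

  fs <- 25
  n <- fs * 30
  t <- (0:(n - 1)) / fs
  set.seed(9)
  tr <- as_accel_trace(data.frame(t = t, X = rnorm(n, 0, 0.1),
                                  Y = rnorm(n, 0, 0.1), Z = t))
  m <- extended_metrics(tr, at = 10:20)
  expect_true(all(extended_metric_names(FALSE) %in% names(m)))
  # Z ramps at 1 g/s: windowed trend is the slope, acf1 near 1
  expect_equal(m$trend_Z, rep(1, nrow(m)), tolerance = 1e-6)
  expect_true(all(m$acf1_Z > 0.95))
  expect_true(all(m$range_X >= 0))
  expect_true(all(abs(m$acf1_X) <= 1, na.rm = TRUE))

  # white-noise acf1 is small; skew of symmetric values is 0
  expect_lt(median(abs(m$acf1_X)), 0.3)
  sym <- c(-2, -1, 0, 1, 2)
  d <- sym - mean(sym)
  expect_equal(mean(d^3) / mean(d^2)^1.5, 0)

  # zero-variance windows yield NA for the moment statistics
  tc <- toy_trace(secs = 10)
  mc <- extended_metrics(tc, at = 5)
  expect_true(is.na(mc$skew_X))
  expect_true(is.na(mc$acf1_X))
})

test_that("per-behavior feature means recover the generator parameters", {
  coh <- murre_cohort()
  cfg <- species_config("murre")
  par <- behavior_params("murre")
  pooled <- do.call(rbind, lapply(names(coh$features), function(b) {
    f <- coh$features[[b]]
    data.frame(behavior = coh$states[[b]]$states, pitch = f$pitch,
               act = f$SD_ODBA, wbf = f$WBF)
  }))
  n_bouts <- table(unlist(lapply(coh$states, function(s)
    s$bout_table$behavior)))
  for (beh in c("colony", "swimming")) {
    rows <- pooled[pooled$behavior == beh, ]
    # bout-level draws dominate the sampling error; duration weighting
    # roughly halves the effective bout count
    n_eff <- max(n_bouts[[beh]] / 2, 1)
    expect_lt(abs(mean(rows$pitch) - par[[beh]]$pitch_mean),
              3 * par[[beh]]$pitch_sd / sqrt(n_eff) + 0.5)
    expect_lt(abs(mean(rows$act) - par[[beh]]$act_mean),
              3 * par[[beh]]$act_sd / sqrt(n_eff) +
                0.05 * par[[beh]]$act_mean)
  }
  fly <- pooled[pooled$behavior == "flying", ]
  expect_equal(mean(fly$wbf[fly$wbf > 6]), 8.1, tolerance = 0.1)
})
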