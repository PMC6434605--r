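# Shared fixtures, built once per test run. Sizes are kept small: the
# behaviors separate at any scale, so a few hours of simulated data per
# bird exercise every code path.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

murre_cohort <- function() {
  fixture("murre_cohort", function() {
    cfg <- species_config("murre")
    simulate_cohort(cfg, n_birds = 4, hours = 6, seeds = 1:4)
  })
}

kittiwake_cohort <- function() {
  fixture("kittiwake_cohort", function() {
    cfg <- species_config("kittiwake", "chick")
    simulate_cohort(cfg, n_birds = 4, hours = 6, seeds = 1:4)
  })
}

# A toy trace with known geometry: constant orientation plus a pure tone.
toy_trace <- function(secs = 60, fs = 25, pitch_deg = 0, tone_hz = 0,
                      tone_amp = 0, noise_sd = 0, seed = 1, depth = NULL) {
  set.seed(seed)
  n <- secs * fs
  t <- (0:(n - 1)) / fs
  theta <- pitch_deg * pi / 180
  z <- cos(theta) + tone_amp * sin(2 * pi * tone_hz * t) +
    stats::rnorm(n, 0, noise_sd)
  x <- sin(theta) + stats::rnorm(n, 0, noise_sd)
  y <- stats::rnorm(n, 0, noise_sd)
  df <- data.frame(t = t, X = x, Y = y, Z = z)
  if (!is.null(depth)) df$depth <- rep(depth, length.out = n)
  as_accel_trace(df, bird_id = "toy")
}
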