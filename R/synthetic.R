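# Synthetic biologger deployments.
#
# The generator emulates the class-conditional signal structure of the two
# study species: colony time shows high pitch and low dynamic
# acceleration, swimming low pitch and high dynamic acceleration, flight a
# dominant heave-axis frequency in the species wing-beat band, and murre
# dives a depth profile below -1 m. Behavior sequences are semi-Markov
# (explicit log-normal bout durations) because the real behaviors are long
# bouts; a per-second Markov chain would fragment them.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Behavior parameter presets for the simulator
#'
#' Per-behavior distributions used by [simulate_accel()] and
#' [simulate_gps()]: bout-level pitch (degrees, mean and SD across bouts),
#' bout-level activity (g, on the species activity metric), the flapping
#' frequency and its slow jitter for periodic behaviors, the AR(1)
#' coefficient of the dynamic noise, log-normal bout-duration parameters
#' (seconds), GPS speeds (m/s), and the murre dive-depth distribution (m).
#'
#' Defaults reproduce the field class statistics: murre colony pitch
#' 37.6 +/- 6.1 deg with `SD_ODBA` 0.05 +/- 0.02 g, swimming -7.4 +/- 2.5 deg with
#' 0.28 +/- 0.08 g, flight WBF 8.1 Hz, dives to -20.5 +/- 9.0 m; kittiwake colony
#' 29.9 +/- 11.7 deg with `SD_Z` 0.04 +/- 0.02 g, swimming 5.7 +/- 2.9 deg with
#' 0.18 +/- 0.04 g, flight WBF 4.16 Hz. Incubation (egg) presets differ from
#' chick rearing only in bout durations and colony activity (incubating
#' birds sit longer but shift position on the nest).
#'
#' @param species `"murre"` or `"kittiwake"`.
#' @param stage `"chick"` or `"egg"`.
#' @return list of class `"behavior_params"`, one element per behavior.
#' @export
behavior_params <- function(species = c("murre", "kittiwake"),
                            stage = c("chick", "egg")) {
  species <- match.arg(species)
  stage <- match.arg(stage)
  if (species == "murre") {
    p <- list(
      colony = list(pitch_mean = 37.6, pitch_sd = 6.1,
                    act_mean = 0.05, act_sd = 0.02,
                    periodic_hz = 0, periodic_jitter = 0, periodic_weight = 0,
                    ar_phi = 0.7,
                    bout_meanlog = log(5400), bout_sdlog = 0.6,
                    speed_mean = 0, speed_sd = 0),
      flying = list(pitch_mean = 0, pitch_sd = 2,
                    act_mean = 0.40, act_sd = 0.06,
                    periodic_hz = 8.1, periodic_jitter = 0.12,
                    periodic_weight = 0.9, ar_phi = 0.4,
                    bout_meanlog = log(480), bout_sdlog = 0.5,
                    speed_mean = 12, speed_sd = 1),
      swimming = list(pitch_mean = -7.4, pitch_sd = 2.5,
                      act_mean = 0.28, act_sd = 0.08,
                      periodic_hz = 0.25, periodic_jitter = 0.03,
                      periodic_weight = 0.25, ar_phi = 0.8,
                      bout_meanlog = log(1200), bout_sdlog = 0.6,
                      speed_mean = 0.5, speed_sd = 0.2),
      diving = list(pitch_mean = -5, pitch_sd = 5,
                    act_mean = 0.20, act_sd = 0.05,
                    periodic_hz = 2.2, periodic_jitter = 0.1,
                    periodic_weight = 0.7, ar_phi = 0.5,
                    bout_meanlog = log(90), bout_sdlog = 0.35,
                    speed_mean = 0.4, speed_sd = 0.15,
                    depth_mean = 20.5, depth_sd = 9)
    )
    if (stage == "egg") {
      p$colony$bout_meanlog <- log(9000)
    }
    trans <- list(colony = c(flying = 1),
                  flying = c(colony = 0.5, swimming = 0.5),
                  swimming = c(flying = 0.35, diving = 0.65),
                  diving = c(swimming = 1))
  } else {
    p <- list(
      colony = list(pitch_mean = 29.9, pitch_sd = 11.7,
                    act_mean = 0.04, act_sd = 0.02,
                    periodic_hz = 0, periodic_jitter = 0, periodic_weight = 0,
                    ar_phi = 0.7,
                    bout_meanlog = log(4200), bout_sdlog = 0.6,
                    speed_mean = 0, speed_sd = 0),
      flying = list(pitch_mean = 0, pitch_sd = 2,
                    act_mean = 0.60, act_sd = 0.08,
                    periodic_hz = 4.16, periodic_jitter = 0.10,
                    periodic_weight = 0.95, ar_phi = 0.4,
                    bout_meanlog = log(600), bout_sdlog = 0.5,
                    speed_mean = 8, speed_sd = 0.8),
      swimming = list(pitch_mean = 5.7, pitch_sd = 2.9,
                      act_mean = 0.18, act_sd = 0.04,
                      periodic_hz = 0.25, periodic_jitter = 0.03,
                      periodic_weight = 0.25, ar_phi = 0.8,
                      bout_meanlog = log(1500), bout_sdlog = 0.6,
                      speed_mean = 0.6, speed_sd = 0.2)
    )
    if (stage == "egg") {
      p$colony$bout_meanlog <- log(7200)
      p$colony$act_mean <- 0.07
      p$colony$act_sd <- 0.03
    }
    trans <- list(colony = c(flying = 1),
                  flying = c(colony = 0.5, swimming = 0.5),
                  swimming = c(flying = 1))
  }
  attr(p, "transitions") <- trans
  attr(p, "species") <- species
  attr(p, "stage") <- stage
  class(p) <- "behavior_params"
  p
}

#' Construct a state sequence from per-second labels
#'
#' @param labels character vector of per-second behavior labels.
#' @param bird_id deployment identifier.
#' @return a `state_sequence` list with per-second `states` and a
#'   `bout_table` of (behavior, start, end) with half-open seconds.
#' @export
as_state_sequence <- function(labels, bird_id = "bird") {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  out <- list(bird_id = bird_id,
              states = labels,
              bout_table = data.frame(behavior = r$values,
                                      start = starts, end = ends))
  class(out) <- "state_sequence"
  out
}

#' Simulate a behavioral state sequence
#'
#' Semi-Markov generator: bouts alternate according to the species
#' adjacency constraints (colony never abuts swimming or diving; diving
#' never abuts flying; murre dives occur only within swimming bouts; every
#' colony-water change passes through flying), with durations drawn from
#' per-behavior log-normal distributions, truncated below at 10 s. The
#' sequence starts at the colony.
#'
#' @param config a [species_config()].
#' @param params a [behavior_params()] preset.
#' @param hours deployment duration.
#' @param seed integer seed; identical seeds give identical sequences.
#' @param bird_id deployment identifier.
#' @return a `state_sequence`.
#' @export
simulate_states <- function(config, params = behavior_params(config$species, config$stage),
                            hours = 48, seed = 1, bird_id = "bird") {
  if (hours <= 0) stop("duration must be positive")
  n_sec <- round(hours * 3600)
  trans <- attr(params, "transitions")
  with_seed(seed, {
    labels <- character(0)
    beh <- "colony"
    total <- 0
    parts <- list()
    i <- 1
    while (total < n_sec) {
      pb <- params[[beh]]
      d <- max(10, round(stats::rlnorm(1, pb$bout_meanlog, pb$bout_sdlog)))
      d <- min(d, n_sec - total)
      parts[[i]] <- rep(beh, d)
      i <- i + 1
      total <- total + d
      nxt <- trans[[beh]]
      beh <- if (length(nxt) == 1) names(nxt) else
        sample(names(nxt), 1, prob = nxt)
    }
    as_state_sequence(unlist(parts), bird_id = bird_id)
  })
}

# AR(1) noise with unit marginal variance.
ar1_unit <- function(n, phi) {
  e <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

# Dynamic (zero-mean) tri-axial signal for one bout, scaled so that the
# species activity metric, recomputed the way the features module computes
# it (2-s moving-mean static removal, 2-s moving SD), matches `act`.
bout_dynamic <- function(beh_params, n, fs, act, metric) {
  w <- beh_params$periodic_weight
  phi <- beh_params$ar_phi
  z <- sqrt(1 - w) * ar1_unit(n, phi)
  if (w > 0 && beh_params$periodic_hz > 0) {
    f_inst <- beh_params$periodic_hz +
      beh_params$periodic_jitter * ar1_unit(n, 0.999)
    phase <- cumsum(2 * pi * f_inst / fs) + stats::runif(1, 0, 2 * pi)
    z <- z + sqrt(w) * sqrt(2) * sin(phase)
  }
  x <- 0.6 * ar1_unit(n, phi)
  y <- 0.6 * ar1_unit(n, phi)
  half <- max(1L, round(fs))
  dz <- z - moving_mean(z, half)
  if (metric == "SD_Z") {
    realized <- mean(moving_sd_pop(dz, half))
  } else {
    dx <- x - moving_mean(x, half)
    dy <- y - moving_mean(y, half)
    odba <- abs(dx) + abs(dy) + abs(dz)
    realized <- mean(moving_sd_pop(odba, half))
  }
  s <- act / max(realized, 1e-9)
  cbind(X = x * s, Y = y * s, Z = z * s)
}

#' Simulate a 25 Hz acceleration trace for a state sequence
#'
#' Static orientation realises each bout's pitch (the gravity vector
#' rotated by pitch, unit magnitude), dynamic noise is AR(1) scaled so the
#' recomputed activity metric matches the bout's draw from the behavior's
#' activity distribution, and flight (plus murre underwater strokes)
#' carries a heave-axis sinusoid at the behavior's flapping frequency with
#' slow jitter. A per-deployment mounting-pitch offset, uniform on
#' +/-15 deg, is added to every bout to exercise pitch calibration. Murre
#' dives get a 1 Hz V-shaped depth profile (1 m/s descent and ascent with
#' a bottom phase) to a depth drawn from the dive-depth distribution,
#' step-filled onto the 25 Hz base.
#'
#' @param states a `state_sequence`.
#' @param params a [behavior_params()] preset.
#' @param config a [species_config()].
#' @param seed integer seed.
#' @param mounting_offset fixed offset in degrees, or `NULL` to draw one.
#' @return an `accel_trace` with attributes `mounting_offset` and
#'   `true_states`.
#' @export
simulate_accel <- function(states, params, config, seed = 1,
                           mounting_offset = NULL) {
  fs <- config$sampling_rate
  n_sec <- length(states$states)
  n <- n_sec * fs
  bouts <- states$bout_table
  metric <- config$activity_metric
  with_seed(seed + 1L, {
    if (is.null(mounting_offset)) mounting_offset <- stats::runif(1, -15, 15)
    X <- Y <- Z <- numeric(n)
    depth_sec <- numeric(n_sec)
    for (i in seq_len(nrow(bouts))) {
      beh <- bouts$behavior[i]
      pb <- params[[beh]]
      a <- bouts$start[i] * fs + 1L
      b <- bouts$end[i] * fs
      len <- b - a + 1L
      # bout-level draws plus slow within-bout drift (correlation time of
      # minutes), so segment-level densities are smooth, not spiky; the
      # split 0.8/0.6 keeps the segment-mean SD near the nominal class SD
      sec_len <- bouts$end[i] - bouts$start[i]
      pitch_b <- stats::rnorm(1, pb$pitch_mean, 0.8 * pb$pitch_sd)
      pitch_sec <- pitch_b + 0.6 * pb$pitch_sd * ar1_unit(sec_len, 0.99)
      theta <- rep((pitch_sec + mounting_offset) * pi / 180, each = fs)
      act_b <- max(stats::rnorm(1, pb$act_mean, 0.8 * pb$act_sd),
                   0.2 * pb$act_mean)
      act_mod <- rep(exp(0.25 * ar1_unit(sec_len, 0.99) - 0.25^2 / 2),
                     each = fs)
      dyn <- bout_dynamic(pb, len, fs, act_b, metric) * act_mod
      X[a:b] <- sin(theta) + dyn[, "X"]
      Y[a:b] <- dyn[, "Y"]
      Z[a:b] <- cos(theta) + dyn[, "Z"]
      if (beh == "diving") {
        dur <- bouts$end[i] - bouts$start[i]
        target <- max(2, stats::rnorm(1, pb$depth_mean, pb$depth_sd))
        target <- min(target, dur / 2 * 0.9)  # descent + ascent at 1 m/s
        tt <- seq_len(dur)
        prof <- pmin(tt, dur - tt + 1, target)
        depth_sec[(bouts$start[i] + 1):bouts$end[i]] <- -prof
      }
    }
    trace <- data.frame(t = (seq_len(n) - 1) / fs, X = X, Y = Y, Z = Z)
    if (config$species == "murre") {
      trace$depth <- rep(depth_sec, each = fs)
    }
    trace <- as_accel_trace(trace, bird_id = states$bird_id, config = config)
    attr(trace, "mounting_offset") <- mounting_offset
    attr(trace, "true_states") <- states$states
    trace
  })
}

#' Simulate a GPS track consistent with a state sequence
#'
#' Positions live in a planar nest-centered frame (meters). Colony time is
#' an Ornstein-Uhlenbeck wobble around the nest; swimming drifts with a
#' persistent slow heading; flight moves at cruising speed with a
#' persistent heading, is nudged back inside an 8 km range cap, and the
#' final leg of each trip steers to the nest at the speed needed to arrive
#' on time (bounded to stay above the flight-speed rule and below the
#' speed-error cutoff). Positions are continuous; fixes are the per-second
#' positions at the fix interval plus 3 m GPS noise, with a rare
#' large-error fix (rate 5e-4) to exercise the speed-error exclusion.
#'
#' @param states a `state_sequence`.
#' @param config a [species_config()].
#' @param params a [behavior_params()] preset.
#' @param seed integer seed.
#' @return a `gps_track` with attribute `true_behavior` (per-fix truth).
#' @export
simulate_gps <- function(states, config, params, seed = 1) {
  n_sec <- length(states$states)
  bouts <- states$bout_table
  with_seed(seed + 2L, {
    px <- py <- numeric(n_sec + 1)
    px[1] <- 20; py[1] <- 5
    nb <- nrow(bouts)
    inbound <- logical(nb)
    for (i in seq_len(nb)) {
      if (bouts$behavior[i] == "flying") {
        nxt <- if (i < nb) bouts$behavior[i + 1] else "colony"
        inbound[i] <- nxt == "colony"
      }
    }
    heading <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(nb)) {
      beh <- bouts$behavior[i]
      pb <- params[[beh]]
      for (s in (bouts$start[i] + 1):bouts$end[i]) {
        x <- px[s]; y <- py[s]
        if (beh == "colony") {
          r <- sqrt(x^2 + y^2)
          if (r > 300) {  # arrived late: finish the approach
            vx <- -x / r * 15; vy <- -y / r * 15
          } else {
            vx <- -0.05 * x + stats::rnorm(1, 0, 0.3)
            vy <- -0.05 * y + stats::rnorm(1, 0, 0.3)
          }
        } else if (beh == "flying") {
          r <- sqrt(x^2 + y^2)
          if (inbound[i]) {
            remaining <- bouts$end[i] - s + 1
            if (r < 200) {  # early arrival: orbit the colony
              ang <- atan2(y, x) + 8 / max(r, 50)
              tx <- 150 * cos(ang); ty <- 150 * sin(ang)
              d <- sqrt((tx - x)^2 + (ty - y)^2)
              vx <- (tx - x) / max(d, 1) * 8; vy <- (ty - y) / max(d, 1) * 8
            } else {
              v <- min(max(r / remaining, config$gps_flight_speed + 2), 28)
              vx <- -x / r * v; vy <- -y / r * v
            }
          } else {
            heading <- heading + stats::rnorm(1, 0, 0.05)
            if (r > 8000) {  # range cap: blend heading back toward the nest
              home <- atan2(-y, -x)
              heading <- heading + 0.2 * sin(home - heading)
            }
            v <- max(stats::rnorm(1, pb$speed_mean, 0.5),
                     config$gps_flight_speed + 2)
            vx <- v * cos(heading); vy <- v * sin(heading)
          }
        } else {  # swimming / diving drift
          heading <- heading + stats::rnorm(1, 0, 0.1)
          v <- max(stats::rnorm(1, pb$speed_mean, pb$speed_sd), 0)
          vx <- v * cos(heading); vy <- v * sin(heading)
        }
        px[s + 1] <- x + vx
        py[s + 1] <- y + vy
      }
    }
    fix_t <- seq(0, n_sec - 1, by = config$fix_interval)
    fi <- fix_t + 1L
    gx <- px[fi] + stats::rnorm(length(fi), 0, 3)
    gy <- py[fi] + stats::rnorm(length(fi), 0, 3)
    bad <- stats::runif(length(fi)) < 5e-4
    if (any(bad)) {
      gx[bad] <- gx[bad] + stats::rnorm(sum(bad), 0, 2500)
      gy[bad] <- gy[bad] + stats::rnorm(sum(bad), 0, 2500)
    }
    track <- data.frame(t = fix_t, x = gx, y = gy)
    attr(track, "bird_id") <- states$bird_id
    attr(track, "coord_type") <- "planar"
    attr(track, "true_behavior") <- states$states[fi]
    class(track) <- c("gps_track", "data.frame")
    track
  })
}

#' Simulate a complete deployment
#'
#' Convenience wrapper bundling [simulate_states()], [simulate_accel()]
#' and [simulate_gps()] for one bird.
#'
#' @inheritParams simulate_states
#' @return list with `states`, `trace`, `gps`.
#' @export
simulate_deployment <- function(config,
                                params = behavior_params(config$species, config$stage),
                                hours = 48, seed = 1,
                                bird_id = sprintf("%s_%02d", config$species, seed)) {
  states <- simulate_states(config, params, hours = hours, seed = seed,
                            bird_id = bird_id)
  trace <- simulate_accel(states, params, config, seed = seed)
  gps <- simulate_gps(states, config, params, seed = seed)
  list(states = states, trace = trace, gps = gps)
}
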