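# Accelerometer-derived metrics.
#
# All moving windows are centered, with truncated windows at the track
# edges. Standard deviations use the population denominator N. The heavy
# lifting is done with cumulative sums (O(n)) so a 48 h deployment at
# 25 Hz stays cheap.

moving_mean <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  a <- pmax(seq_len(n) - half, 1L)
  b <- pmin(seq_len(n) + half, n)
  (cs[b + 1] - cs[a]) / (b - a + 1)
}

moving_sd_pop <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  a <- pmax(seq_len(n) - half, 1L)
  b <- pmin(seq_len(n) + half, n)
  m <- b - a + 1
  mu <- (cs[b + 1] - cs[a]) / m
  v <- (cs2[b + 1] - cs2[a]) / m - mu^2
  sqrt(pmax(v, 0))
}

#' Static (gravitational) acceleration
#'
#' Centered moving mean of each axis over `window` seconds (default 2 s);
#' encodes posture.
#'
#' @param trace an `accel_trace`.
#' @param window window length in seconds.
#' @return data frame with columns `S_X`, `S_Y`, `S_Z`, one row per sample.
#' @export
static_acceleration <- function(trace, window = 2) {
  if (!nrow(trace)) stop("empty acceleration trace")
  fs <- sampling_rate(trace)
  if (window < 2 / fs) stop("window must span at least two samples")
  half <- max(1L, round(window * fs / 2))
  data.frame(S_X = moving_mean(trace$X, half),
             S_Y = moving_mean(trace$Y, half),
             S_Z = moving_mean(trace$Z, half))
}

#' Pitch angle from static acceleration
#'
#' Vertical body angle in degrees: the arctangent of the surge (X)
#' component over the root-sum-square of the other two, so a level bird
#' reads 0 deg and a vertical bird 90 deg. An all-zero static vector has no
#' defined orientation and yields `NA`.
#'
#' @param S_X,S_Y,S_Z static acceleration components (g).
#' @return pitch in degrees, in `[-90, 90]`.
#' @export
pitch_angle <- function(S_X, S_Y, S_Z) {
  denom <- sqrt(S_Y^2 + S_Z^2)
  out <- atan2(S_X, denom) * 180 / pi
  out[S_X == 0 & denom == 0] <- NA_real_
  out
}

#' Dynamic acceleration, ODBA, and activity metrics
#'
#' Dynamic acceleration is the residual after removing the static
#' component (`raw = static + dynamic` exactly, by construction). ODBA is
#' the absolute dynamic acceleration summed over the three axes. `SD_Z`
#' and `SD_ODBA` are centered 2-s moving standard deviations (denominator
#' N) of `D_Z` and ODBA.
#'
#' @param trace an `accel_trace`.
#' @param S static acceleration from [static_acceleration()], on the same
#'   sample grid.
#' @param window window for the SD metrics, seconds.
#' @return data frame with `D_X`, `D_Y`, `D_Z`, `ODBA`, `SD_Z`, `SD_ODBA`.
#' @export
dynamic_and_odba <- function(trace, S, window = 2) {
  if (nrow(S) != nrow(trace)) stop("static grid does not match the trace")
  fs <- sampling_rate(trace)
  half <- max(1L, round(window * fs / 2))
  D_X <- trace$X - S$S_X
  D_Y <- trace$Y - S$S_Y
  D_Z <- trace$Z - S$S_Z
  ODBA <- abs(D_X) + abs(D_Y) + abs(D_Z)
  data.frame(D_X = D_X, D_Y = D_Y, D_Z = D_Z, ODBA = ODBA,
             SD_Z = moving_sd_pop(D_Z, half),
             SD_ODBA = moving_sd_pop(ODBA, half))
}

# Dominant frequency of one window: periodogram argmax with the DC bin
# excluded, a noise floor (peak power must exceed `floor_factor` times the
# window's median spectral power, else 0 Hz), and quadratic interpolation
# of log-power around the peak for sub-bin resolution.
dominant_freq_window <- function(x, fs, floor_factor = 3,
                                 concentration = 0.5) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2
  nb <- floor(n / 2)
  if (nb < 2) return(0)
  P <- P[2:(nb + 1)]
  k <- which.max(P)
  peak3 <- sum(P[max(1, k - 1):min(nb, k + 1)])
  if (P[k] <= 0 || P[k] < floor_factor * stats::median(P) ||
      peak3 < concentration * sum(P)) return(0)
  delta <- 0
  if (k > 1 && k < nb && max(P[k - 1], P[k + 1]) > 1e-9 * P[k]) {
    lp <- log(pmax(P[(k - 1):(k + 1)], 1e-300))
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (den < 0) delta <- 0.5 * (lp[1] - lp[3]) / den
    if (!is.finite(delta) || abs(delta) > 0.5) delta <- 0
  }
  (k + delta) * fs / n
}

# Vectorised dominant frequency for all full windows centered at the given
# sample indices; truncated edge windows fall back to the scalar path.
dominant_freq_at <- function(z, centers, fs, window = 5, floor_factor = 3,
                             concentration = 0.5, chunk = 20000L) {
  half <- floor(window * fs / 2)
  n <- length(z)
  wlen <- 2L * half + 1L
  nb <- floor(wlen / 2)
  freq_bin <- fs / wlen
  out <- numeric(length(centers))
  full <- centers - half >= 1 & centers + half <= n
  # edges: truncated windows, needing at least 2 s of data
  for (j in which(!full)) {
    a <- max(1L, centers[j] - half)
    b <- min(n, centers[j] + half)
    if (b - a + 1 >= 2 * fs) {
      out[j] <- dominant_freq_window(z[a:b], fs, floor_factor)
    } else {
      out[j] <- 0
    }
  }
  idx_full <- which(full)
  off <- -half:half
  for (start in seq(1, length(idx_full), by = chunk)) {
    cols <- idx_full[start:min(start + chunk - 1L, length(idx_full))]
    m <- length(cols)
    X <- z[rep(centers[cols], each = wlen) + off]
    dim(X) <- c(wlen, m)
    X <- X - rep(colMeans(X), each = wlen)
    P <- Mod(stats::mvfft(X))^2
    P <- P[2:(nb + 1), , drop = FALSE]
    k <- max.col(t(P), ties.method = "first")
    pk <- P[cbind(k, seq_len(m))]
    # column medians via one order() pass (P is column-major), much
    # cheaper than apply() over 1e5 windows
    srt <- matrix(P[order(rep(seq_len(m), each = nb), P)], nrow = nb)
    med <- if (nb %% 2 == 0) {
      (srt[nb / 2, ] + srt[nb / 2 + 1, ]) / 2
    } else {
      srt[(nb + 1) / 2, ]
    }
    tot <- colSums(P)
    peak3 <- pk + P[cbind(pmax(k - 1L, 1L), seq_len(m))] +
      P[cbind(pmin(k + 1L, nb), seq_len(m))]
    # correct the double count when the peak sits at a boundary bin
    at_lo <- k == 1L; at_hi <- k == nb
    peak3[at_lo] <- peak3[at_lo] - pk[at_lo]
    peak3[at_hi] <- peak3[at_hi] - pk[at_hi]
    ok <- pk > 0 & pk >= 3e-300 & pk > floor_factor * med &
      peak3 >= concentration * tot
    delta <- numeric(m)
    nbr <- pmax(P[cbind(pmax(k - 1L, 1L), seq_len(m))],
                P[cbind(pmin(k + 1L, nb), seq_len(m))])
    interior <- ok & k > 1 & k < nb & nbr > 1e-9 * pk
    if (any(interior)) {
      ii <- which(interior)
      la <- log(pmax(P[cbind(k[ii] - 1L, ii)], 1e-300))
      lb <- log(pmax(P[cbind(k[ii], ii)], 1e-300))
      lc <- log(pmax(P[cbind(k[ii] + 1L, ii)], 1e-300))
      den <- la - 2 * lb + lc
      d <- ifelse(den < 0, 0.5 * (la - lc) / den, 0)
      d[!is.finite(d) | abs(d) > 0.5] <- 0
      delta[ii] <- d
    }
    f <- (k + delta) * freq_bin
    f[!ok] <- 0
    out[cols] <- f
  }
  out
}

#' Dominant wing-beat frequency series
#'
#' Dominant frequency of the heave (Z) axis from the periodogram of a
#' centered `window`-second moving window (default 5 s), the DC bin
#' excluded and the window mean removed. The peak is refined by quadratic
#' interpolation of log-power around the maximum bin, giving sub-bin
#' resolution (a 5 s window at 25 Hz has 0.2 Hz bins). Windows without a
#' meaningful periodicity return 0 Hz: the peak must exceed three times
#' the window's median spectral power and, with its two neighboring bins,
#' carry at least half the window's non-DC power. Broad-band noise fails
#' the concentration check, so non-locomotor windows read 0 Hz the way
#' field wing-beat traces do, while flapping, underwater strokes, and
#' surface-wave peaks pass.
#'
#' @param z heave-axis acceleration samples (g).
#' @param fs sampling rate, Hz.
#' @param at sample indices of the window centers (default: every sample).
#' @param window window length, seconds; `window * fs` must be at least 8
#'   samples.
#' @return frequency in Hz per requested center, 0 where below the floor.
#' @export
wbf <- function(z, fs, at = seq_along(z), window = 5) {
  if (window * fs < 8) stop("WBF window must cover at least 8 samples")
  if (window * fs > length(z)) stop("WBF window exceeds the trace length")
  dominant_freq_at(z, as.integer(at), fs, window = window)
}

sampling_rate <- function(trace) {
  if (nrow(trace) < 2) return(NA_real_)
  round(1 / stats::median(diff(trace$t)), 3)
}

#' Compute the per-second feature frame
#'
#' Computes the classification metrics on the 1-s grid: static
#' acceleration and pitch (2-s windows), dynamic acceleration and ODBA,
#' the 2-s moving standard deviations `SD_Z` and `SD_ODBA`, the 5-s
#' dominant frequency `WBF`, and depth where present. Window statistics
#' are computed at the full 25 Hz resolution and sampled at the grid
#' points, so values match a compute-then-subsample pipeline exactly.
#'
#' @param trace an `accel_trace`.
#' @param config a [species_config()].
#' @param interval output grid spacing, seconds.
#' @return a `feature_frame` data frame (attributes `bird_id`, `species`).
#' @export
compute_features <- function(trace, config, interval = 1) {
  fs <- sampling_rate(trace)
  S <- static_acceleration(trace, window = 2)
  D <- dynamic_and_odba(trace, S, window = 2)
  n <- nrow(trace)
  t0 <- trace$t[1]
  grid_t <- seq(0, trace$t[n] - t0, by = interval)
  gi <- as.integer(round(grid_t * fs)) + 1L
  gi <- gi[gi >= 1 & gi <= n]
  out <- data.frame(
    t = trace$t[gi],
    S_X = S$S_X[gi], S_Y = S$S_Y[gi], S_Z = S$S_Z[gi],
    pitch = pitch_angle(S$S_X[gi], S$S_Y[gi], S$S_Z[gi]),
    D_X = D$D_X[gi], D_Y = D$D_Y[gi], D_Z = D$D_Z[gi],
    ODBA = D$ODBA[gi], SD_Z = D$SD_Z[gi], SD_ODBA = D$SD_ODBA[gi],
    WBF = dominant_freq_at(trace$Z, gi, fs, window = 5)
  )
  if (!is.null(trace$depth)) out$depth <- trace$depth[gi]
  attr(out, "bird_id") <- attr(trace, "bird_id")
  attr(out, "species") <- config$species
  attr(out, "activity_metric") <- config$activity_metric
  class(out) <- c("feature_frame", "data.frame")
  out
}

#' Activity metric column of a feature frame
#'
#' `SD_ODBA` for murres, `SD_Z` for kittiwakes.
#' @param features a `feature_frame`.
#' @param config a [species_config()].
#' @return numeric vector.
#' @export
activity_metric <- function(features, config) {
  features[[config$activity_metric]]
}

#' Calibrate pitch to presumed flight
#'
#' Tag mounting varies between deployments, offsetting the pitch channel.
#' During flapping flight all birds hold a consistent body orientation, so
#' pitch is standardised to 0 deg over presumed flight: the offset is the
#' mean pitch of all timestamps whose WBF falls inside the species flight
#' band, and is subtracted from the whole deployment. With less than 60 s
#' of presumed flight the offset cannot be estimated and the features are
#' returned unchanged with a warning.
#'
#' @param features a `feature_frame`.
#' @param config a [species_config()].
#' @return the feature frame with calibrated `pitch` and attribute
#'   `pitch_offset`.
#' @export
calibrate_pitch <- function(features, config) {
  band <- config$flight_wbf_band
  in_band <- !is.na(features$WBF) &
    features$WBF >= band[1] & features$WBF <= band[2]
  step <- stats::median(diff(features$t))
  if (sum(in_band) * step < 60) {
    warning("less than 60 s of presumed flight; pitch left uncalibrated")
    attr(features, "pitch_offset") <- 0
    return(features)
  }
  offset <- mean(features$pitch[in_band], na.rm = TRUE)
  features$pitch <- features$pitch - offset
  attr(features, "pitch_offset") <- offset
  features
}
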