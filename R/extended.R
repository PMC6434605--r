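#' Extended 42-metric library
#'
#' The variable-selection analysis draws on a wider library of 42
#' accelerometer statistics than the four a priori classification
#' variables. Per axis (X, Y, Z): the raw value, static (2-s moving mean)
#' and dynamic (residual) components, and the windowed minimum, maximum,
#' range, skewness, kurtosis, trend (least-squares slope of value against
#' time), and lag-1 autocorrelation, all over centered 2-s windows, plus
#' the dominant frequency over a 5-s window (33 columns). Nine composite
#' metrics complete the library: pitch, roll, ODBA, the 2-s moving mean
#' and range of ODBA, `SD_X`, `SD_Y`, `SD_Z`, and `SD_ODBA`. For murres,
#' depth is appended as an additional candidate (43 columns), since the
#' pressure channel is part of that species' classification data.
#'
#' Skewness and kurtosis are the sample moment estimators
#' `m3 / m2^(3/2)` and `m4 / m2^2 - 3` (excess); zero-variance windows
#' yield `NA` for skew, kurtosis, and acf1.
#'
#' @param trace an `accel_trace`.
#' @param at seconds (relative to the first sample) at which to evaluate;
#'   defaults to the full 1-s grid. Restricting to the validation fix
#'   times keeps the variable-selection pipeline cheap.
#' @return a data frame with a `t` column plus the metric columns.
#' @export
extended_metrics <- function(trace, at = NULL) {
  fs <- sampling_rate(trace)
  n <- nrow(trace)
  if (trace$t[n] - trace$t[1] < 5) stop("trace must span at least 5 s")
  t0 <- trace$t[1]
  if (is.null(at)) at <- seq(0, trace$t[n] - t0, by = 1)
  gi <- as.integer(round(at * fs)) + 1L
  keep <- gi >= 1 & gi <= n
  gi <- gi[keep]
  at <- at[keep]

  S <- static_acceleration(trace, window = 2)
  D <- dynamic_and_odba(trace, S, window = 2)
  half2 <- max(1L, round(2 * fs / 2))

  axes <- list(X = trace$X, Y = trace$Y, Z = trace$Z)
  out <- list(t = trace$t[gi])
  win_stats <- function(v) {
    mn <- mx <- sk <- ku <- tr <- ac <- numeric(length(gi))
    for (j in seq_along(gi)) {
      a <- max(1L, gi[j] - half2)
      b <- min(n, gi[j] + half2)
      w <- v[a:b]
      m <- length(w)
      mn[j] <- min(w); mx[j] <- max(w)
      mu <- mean(w)
      d <- w - mu
      m2 <- mean(d^2)
      if (m2 < 1e-20) {
        sk[j] <- NA_real_; ku[j] <- NA_real_; ac[j] <- NA_real_
      } else {
        sk[j] <- mean(d^3) / m2^1.5
        ku[j] <- mean(d^4) / m2^2 - 3
        ac[j] <- suppressWarnings(stats::cor(w[-1], w[-m]))
      }
      tt <- seq_len(m) / fs
      tr[j] <- sum((tt - mean(tt)) * d) / sum((tt - mean(tt))^2)
    }
    list(min = mn, max = mx, range = mx - mn, skew = sk, kurt = ku,
         trend = tr, acf1 = ac)
  }
  for (ax in names(axes)) {
    v <- axes[[ax]]
    out[[paste0("raw_", ax)]] <- v[gi]
    out[[paste0("static_", ax)]] <- S[[paste0("S_", ax)]][gi]
    out[[paste0("dynamic_", ax)]] <- D[[paste0("D_", ax)]][gi]
    ws <- win_stats(v)
    out[[paste0("min_", ax)]] <- ws$min
    out[[paste0("max_", ax)]] <- ws$max
    out[[paste0("range_", ax)]] <- ws$range
    out[[paste0("skew_", ax)]] <- ws$skew
    out[[paste0("kurt_", ax)]] <- ws$kurt
    out[[paste0("trend_", ax)]] <- ws$trend
    out[[paste0("acf1_", ax)]] <- ws$acf1
    out[[paste0("freq_", ax)]] <- dominant_freq_at(v, gi, fs, window = 5)
  }
  out$pitch <- pitch_angle(S$S_X[gi], S$S_Y[gi], S$S_Z[gi])
  out$roll <- atan2(S$S_Y[gi], S$S_Z[gi]) * 180 / pi
  out$ODBA <- D$ODBA[gi]
  out$mean_ODBA <- moving_mean(D$ODBA, half2)[gi]
  rng_odba <- win_stats(D$ODBA)
  out$range_ODBA <- rng_odba$range
  out$SD_X <- moving_sd_pop(D$D_X, half2)[gi]
  out$SD_Y <- moving_sd_pop(D$D_Y, half2)[gi]
  out$SD_Z <- D$SD_Z[gi]
  out$SD_ODBA <- D$SD_ODBA[gi]
  if (!is.null(trace$depth)) out$depth <- trace$depth[gi]
  res <- as.data.frame(out)
  attr(res, "bird_id") <- attr(trace, "bird_id")
  res
}

#' Names of the extended metric columns
#'
#' @param murre include depth (43 candidates) or not (42).
#' @return character vector of metric names.
#' @export
extended_metric_names <- function(murre = FALSE) {
  per_axis <- c("raw", "static", "dynamic", "min", "max", "range",
                "skew", "kurt", "trend", "acf1", "freq")
  nm <- c(as.vector(outer(per_axis, c("X", "Y", "Z"), paste, sep = "_")),
          "pitch", "roll", "ODBA", "mean_ODBA", "range_ODBA",
          "SD_X", "SD_Y", "SD_Z", "SD_ODBA")
  if (murre) nm <- c(nm, "depth")
  nm
}
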