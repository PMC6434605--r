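# Constrained hidden Markov model classification.
#
# Observations are bin means (5 s murre, 10 s kittiwake) of pitch, the
# activity metric, and WBF, plus a binary below--1 m depth indicator for
# murres. Emissions follow the bundled starting-value tables: normal
# pitch; exponential SD_ODBA (murre); zero-inflated log-normal SD_Z
# (kittiwake) and WBF; fixed Bernoulli depth. Six transitions are pinned
# at zero so a bird cannot move between the colony and the water without
# flying, nor between diving and anything but swimming. Fitting is EM
# (forward-backward with per-step scaling, closed-form M-steps); decoding
# is Viterbi in log space. EM preserves structural zeros, so the
# forbidden transitions remain exactly zero through fitting.

#' HMM specification with field-calibrated starting values
#'
#' Murres use four states (colony, diving, flying, swimming); kittiwakes
#' four (two colony states, flying, swimming) merged to colony after
#' decoding. Log-normal locations in the shipped tables are natural-scale
#' medians (`exp(meanlog)`). The Bernoulli depth probabilities (1e-12 and
#' 1 - 1e-12) are held fixed through fitting to keep diving anchored to
#' the pressure channel.
#'
#' @param species `"murre"` or `"kittiwake"`.
#' @param path optional YAML file overriding the bundled starting values.
#' @return list of class `"hmm_spec"`.
#' @export
hmm_spec <- function(species = c("murre", "kittiwake"), path = NULL) {
  species <- match.arg(species)
  if (is.null(path)) {
    path <- system.file("extdata", "hmm_starts",
                        paste0(species, ".yaml"), package = "ethogramr")
  }
  raw <- yaml::read_yaml(path)
  spec <- list(
    species = species,
    states = raw$states,
    behavior_map = unlist(raw$behavior_map),
    bin = raw$bin,
    forbidden = do.call(rbind, lapply(raw$forbidden, unlist)),
    pitch = list(mean = unlist(raw$pitch$mean), sd = unlist(raw$pitch$sd)),
    activity = raw$activity,
    wbf = raw$wbf,
    depth = if (!is.null(raw$depth)) unlist(raw$depth$prob)
  )
  spec$activity$location <- unlist(spec$activity$location)
  if (!is.null(spec$activity$scale)) spec$activity$scale <- unlist(spec$activity$scale)
  if (!is.null(spec$activity$zero_mass)) spec$activity$zero_mass <- unlist(spec$activity$zero_mass)
  spec$wbf$location <- unlist(spec$wbf$location)
  spec$wbf$scale <- unlist(spec$wbf$scale)
  spec$wbf$zero_mass <- unlist(spec$wbf$zero_mass)
  class(spec) <- "hmm_spec"
  spec
}

# Bin 1-s features to the HMM interval: means of pitch/activity/WBF, and
# for murres an any-below-threshold depth indicator per bin.
bin_features <- function(features, config, bin = config$hmm_bin) {
  n <- nrow(features)
  nb <- floor(n / bin)
  if (nb < 2) stop("track too short for HMM binning")
  idx <- rep(seq_len(nb), each = bin)
  used <- seq_len(nb * bin)
  bmean <- function(v) as.numeric(tapply(v[used], idx, mean, na.rm = TRUE))
  out <- data.frame(
    bin = seq_len(nb),
    pitch = bmean(features$pitch),
    activity = bmean(activity_metric(features, config)),
    WBF = bmean(features$WBF)
  )
  if (config$species == "murre") {
    dv <- features$depth[used] < config$dive_depth_threshold
    out$depth_ind <- as.numeric(tapply(dv, idx, any))
  }
  out
}

dzilnorm_log <- function(x, zero_mass, meanlog, sdlog) {
  iszero <- x < 1e-12
  out <- numeric(length(x))
  out[iszero] <- log(zero_mass)
  out[!iszero] <- log1p(-zero_mass) +
    stats::dlnorm(x[!iszero], meanlog, sdlog, log = TRUE)
  out
}

# K x T matrix of log emission densities.
hmm_log_emissions <- function(obs, par, spec, config) {
  K <- length(spec$states)
  T_ <- nrow(obs)
  L <- matrix(0, K, T_)
  for (k in seq_len(K)) {
    l <- stats::dnorm(obs$pitch, par$pitch_mean[k], par$pitch_sd[k],
                      log = TRUE)
    if (spec$activity$family == "exponential") {
      l <- l + stats::dexp(pmax(obs$activity, 1e-8), par$act_rate[k],
                           log = TRUE)
    } else {
      l <- l + dzilnorm_log(obs$activity, par$act_zero[k],
                            par$act_meanlog[k], par$act_sdlog[k])
    }
    l <- l + dzilnorm_log(obs$WBF, par$wbf_zero[k],
                          par$wbf_meanlog[k], par$wbf_sdlog[k])
    if (!is.null(spec$depth)) {
      p <- par$depth_prob[k]
      l <- l + ifelse(obs$depth_ind > 0, log(p), log1p(-p))
    }
    L[k, ] <- l
  }
  L
}

hmm_start_par <- function(spec) {
  par <- list(
    pitch_mean = spec$pitch$mean,
    pitch_sd = spec$pitch$sd,
    wbf_zero = spec$wbf$zero_mass,
    wbf_meanlog = log(spec$wbf$location),
    wbf_sdlog = spec$wbf$scale
  )
  if (spec$activity$family == "exponential") {
    par$act_rate <- spec$activity$rate <- unlist(spec$activity$rate)
  } else {
    par$act_zero <- spec$activity$zero_mass
    par$act_meanlog <- log(spec$activity$location)
    par$act_sdlog <- spec$activity$scale
  }
  if (!is.null(spec$depth)) par$depth_prob <- spec$depth
  par
}

hmm_start_transition <- function(spec) {
  K <- length(spec$states)
  A <- matrix(1, K, K)
  if (!is.null(spec$forbidden)) {
    for (r in seq_len(nrow(spec$forbidden))) {
      i <- match(spec$forbidden[r, 1], spec$states)
      j <- match(spec$forbidden[r, 2], spec$states)
      A[i, j] <- 0
    }
  }
  for (i in seq_len(K)) {
    allowed <- which(A[i, ] > 0 & seq_len(K) != i)
    A[i, ] <- 0
    A[i, i] <- 0.99
    A[i, allowed] <- 0.01 / length(allowed)
  }
  A
}

# Scaled forward-backward; returns state posteriors, expected transition
# counts, and the log-likelihood.
hmm_forward_backward <- function(logB, A, delta) {
  K <- nrow(logB)
  T_ <- ncol(logB)
  cmax <- apply(logB, 2, max)
  B <- exp(sweep(logB, 2, cmax))
  alpha <- matrix(0, K, T_)
  cscale <- numeric(T_)
  a <- delta * B[, 1]
  cscale[1] <- sum(a)
  alpha[, 1] <- a / cscale[1]
  tA <- t(A)
  for (t in 2:T_) {
    a <- (tA %*% alpha[, t - 1]) * B[, t]
    cscale[t] <- sum(a)
    alpha[, t] <- a / cscale[t]
  }
  beta <- matrix(0, K, T_)
  beta[, T_] <- 1
  for (t in (T_ - 1):1) {
    b <- A %*% (B[, t + 1] * beta[, t + 1])
    beta[, t] <- b / cscale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  xi_sum <- matrix(0, K, K)
  for (t in 1:(T_ - 1)) {
    m <- (alpha[, t] %o% (B[, t + 1] * beta[, t + 1])) * A / cscale[t + 1]
    xi_sum <- xi_sum + m
  }
  list(gamma = gamma, xi_sum = xi_sum,
       loglik = sum(log(cscale)) + sum(cmax))
}

hmm_m_step <- function(obs, gamma, spec, par) {
  K <- nrow(gamma)
  for (k in seq_len(K)) {
    w <- gamma[k, ]
    sw <- sum(w)
    if (sw < 1e-6) next  # state unused in this track; keep its start values
    mu <- sum(w * obs$pitch) / sw
    par$pitch_mean[k] <- mu
    par$pitch_sd[k] <- max(sqrt(sum(w * (obs$pitch - mu)^2) / sw), 0.5)
    if (spec$activity$family == "exponential") {
      par$act_rate[k] <- sw / max(sum(w * obs$activity), 1e-6)
    } else {
      z <- obs$activity < 1e-12
      par$act_zero[k] <- min(max(sum(w[z]) / sw, 1e-6), 1 - 1e-6)
      wp <- w[!z]
      if (sum(wp) > 1e-8) {
        lx <- log(obs$activity[!z])
        m <- sum(wp * lx) / sum(wp)
        par$act_meanlog[k] <- m
        par$act_sdlog[k] <- max(sqrt(sum(wp * (lx - m)^2) / sum(wp)), 0.05)
      }
    }
    z <- obs$WBF < 1e-12
    par$wbf_zero[k] <- min(max(sum(w[z]) / sw, 1e-6), 1 - 1e-6)
    wp <- w[!z]
    if (sum(wp) > 1e-8) {
      lx <- log(obs$WBF[!z])
      m <- sum(wp * lx) / sum(wp)
      par$wbf_meanlog[k] <- m
      par$wbf_sdlog[k] <- max(sqrt(sum(wp * (lx - m)^2) / sum(wp)), 0.05)
    }
    # depth Bernoulli probabilities are fixed, not re-estimated
  }
  par
}

hmm_viterbi <- function(logB, A, delta) {
  K <- nrow(logB)
  T_ <- ncol(logB)
  logA <- log(A)
  phi <- log(delta) + logB[, 1]
  back <- matrix(0L, K, T_)
  for (t in 2:T_) {
    m <- phi + logA  # K x K: row = from, col = to
    back[, t] <- max.col(t(m), ties.method = "first")
    phi <- m[cbind(back[, t], seq_len(K))] + logB[, t]
  }
  states <- integer(T_)
  states[T_] <- which.max(phi)
  for (t in T_:2) states[t - 1] <- back[states[t], t]
  states
}

#' Hidden Markov model classification
#'
#' Fits the constrained HMM per track by EM from the bundled starting
#' values and decodes with Viterbi; bin states are expanded back to the
#' 1-s grid by repetition (a trailing partial bin takes the last state).
#'
#' @param features a `feature_frame` or named list of them (calibrated).
#' @param config a [species_config()].
#' @param spec an [hmm_spec()].
#' @param max_iter maximum EM iterations (the likelihood is essentially
#'   flat well before 30 on these well-separated emissions).
#' @param tol relative log-likelihood convergence tolerance.
#' @return named list of ethograms.
#' @export
classify_hmm <- function(features, config, spec = hmm_spec(config$species),
                         max_iter = 30, tol = 1e-5) {
  features <- as_feature_list(features)
  out <- lapply(names(features), function(b) {
    f <- features[[b]]
    obs <- bin_features(f, config, spec$bin)
    if (anyNA(obs)) {
      bad <- names(obs)[vapply(obs, anyNA, TRUE)]
      stop("non-finite HMM input in variable(s): ",
           paste(bad, collapse = ", "))
    }
    K <- length(spec$states)
    par <- hmm_start_par(spec)
    A <- hmm_start_transition(spec)
    delta <- rep(1 / K, K)
    last_ll <- -Inf
    for (iter in seq_len(max_iter)) {
      logB <- hmm_log_emissions(obs, par, spec, config)
      if (!all(is.finite(logB))) {
        stop("non-finite HMM emission density; check input variables")
      }
      fb <- hmm_forward_backward(logB, A, delta)
      par <- hmm_m_step(obs, fb$gamma, spec, par)
      rs <- rowSums(fb$xi_sum)
      Anew <- fb$xi_sum / ifelse(rs > 0, rs, 1)
      keep <- rs > 0
      A[keep, ] <- Anew[keep, ]
      delta <- fb$gamma[, 1]
      delta <- pmax(delta, 1e-12)
      delta <- delta / sum(delta)
      if (is.finite(last_ll) &&
          abs(fb$loglik - last_ll) < tol * (abs(last_ll) + 1)) break
      last_ll <- fb$loglik
    }
    logB <- hmm_log_emissions(obs, par, spec, config)
    path <- hmm_viterbi(logB, A, pmax(delta, 1e-12))
    beh_bin <- spec$behavior_map[spec$states[path]]
    n_sec <- nrow(f)
    sec <- rep(beh_bin, each = spec$bin)
    if (length(sec) < n_sec) {
      sec <- c(sec, rep(sec[length(sec)], n_sec - length(sec)))
    }
    ethogram_df(f$t, sec[seq_len(n_sec)], b, "HMM")
  })
  stats::setNames(out, names(features))
}
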