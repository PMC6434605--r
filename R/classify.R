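# The six behavioral classification methods. All consume a named list of
# calibrated feature frames (one per bird, 1-s grid) and emit a named list
# of ethograms: data frames of (t, behavior) covering the full track.

ethogram_df <- function(t, behavior, bird_id, method) {
  out <- data.frame(t = t, behavior = behavior)
  attr(out, "bird_id") <- bird_id
  attr(out, "method") <- method
  class(out) <- c("ethogram", "data.frame")
  out
}

as_feature_list <- function(features) {
  if (is.data.frame(features)) {
    nm <- attr(features, "bird_id") %||% "bird"
    features <- stats::setNames(list(features), nm)
  }
  features
}

#' Histogram-segregation breakpoint of a 1-D sample
#'
#' Gaussian kernel density estimate (Silverman's bandwidth); the
#' breakpoint is the minimum-density location between the two highest
#' density peaks. Used to automate the visual peak-and-valley reading of
#' stacked histograms: depth and WBF first at the 1-s level, then activity
#' and pitch on segment means.
#'
#' @param values numeric sample (at least 100 values recommended).
#' @param n_classes number of classes the valley separates (2 supported).
#' @param min_depth a candidate valley is only accepted if its density is
#'   below this fraction of the lower of the two peaks, so small ripples
#'   within a single mode are not mistaken for class boundaries.
#' @return the breakpoint (scalar).
#' @export
hs_breakpoints <- function(values, n_classes = 2, min_depth = 0.5) {
  values <- values[is.finite(values)]
  if (n_classes != 2) stop("only two-class breakpoints are supported")
  if (length(unique(values)) < 2) {
    stop("constant sample has no density valley")
  }
  d <- stats::density(values, bw = "nrd0", n = 512)
  y <- d$y
  k <- length(y)
  is_peak <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
               FALSE)
  peaks <- which(is_peak)
  if (length(peaks) < 2) {
    stop("density is unimodal; no interior valley to use as a breakpoint")
  }
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  main <- peaks[1]
  for (other in peaks[-1]) {
    pair <- sort(c(main, other))
    between <- seq(pair[1], pair[2])
    vi <- between[which.min(y[between])]
    if (y[vi] < min_depth * min(y[pair])) {
      return(d$x[vi])
    }
  }
  stop("no sufficiently deep density valley between modes")
}

try_breakpoint <- function(values) {
  tryCatch(hs_breakpoints(values), error = function(e) NULL)
}

# Reference class centroids (the field class statistics) used as a
# last-resort assignment when no density valley exists anywhere (e.g. a
# track containing one behavior).
water_land_centroids <- function(config) {
  if (config$species == "murre") {
    list(colony = c(pitch = 37.6, act = 0.05),
         swimming = c(pitch = -7.4, act = 0.28))
  } else {
    list(colony = c(pitch = 29.9, act = 0.04),
         swimming = c(pitch = 5.7, act = 0.18))
  }
}

# Nearest-centroid assignment in (pitch, log activity) with fixed scales
# comparable to the class separations (15 deg, 0.5 log-g).
assign_by_centroid <- function(pitch, activity, config) {
  cen <- water_land_centroids(config)
  act <- log(pmax(activity, 1e-4))
  d_col <- ((pitch - cen$colony["pitch"]) / 15)^2 +
    ((act - log(cen$colony["act"])) / 0.5)^2
  d_swm <- ((pitch - cen$swimming["pitch"]) / 15)^2 +
    ((act - log(cen$swimming["act"])) / 0.5)^2
  ifelse(d_col <= d_swm, "colony", "swimming")
}

#' Histogram segregation (HS) classification
#'
#' The stepwise density-valley method. Murres: diving by the depth rule,
#' flying by a per-track WBF breakpoint, then remaining segments split
#' into colony and swimming by breakpoints on log mean activity and mean
#' pitch. Kittiwakes: flying by WBF, colony by low `SD_Z`, remaining
#' segments to swimming (a pitch breakpoint reclaims high-pitch active
#' colony segments). Each track is classified individually; when a track's
#' own density is unimodal the pooled-population breakpoint is used, and
#' for WBF the lower edge of the species flight band.
#'
#' @param features a `feature_frame` or named list of them (calibrated).
#' @param config a [species_config()].
#' @return named list of ethograms.
#' @export
classify_hs <- function(features, config) {
  features <- as_feature_list(features)
  per_bird <- lapply(features, function(f) {
    # the valley is sought among windows with a detected periodicity; the
    # zero-frequency mass (non-locomotor windows) sits below any positive
    # threshold either way
    thr <- try_breakpoint(f$WBF[f$WBF > 0])
    if (is.null(thr) || thr >= config$flight_wbf_band[2]) {
      thr <- config$flight_wbf_band[1]
    }
    labels <- first_pass(f, config, function(ff) ff$WBF > thr)
    labels <- enforce_min_bout(labels)
    segs <- build_segments(labels, f, config)
    list(f = f, labels = labels, segs = segs)
  })
  all_unknown <- do.call(rbind, lapply(per_bird, function(p)
    p$segs[p$segs$behavior_hint == "unknown", ]))
  pooled_act <- try_breakpoint(log(pmax(all_unknown$mean_activity, 1e-4)))
  pooled_pitch <- try_breakpoint(all_unknown$mean_pitch)

  out <- lapply(names(per_bird), function(b) {
    p <- per_bird[[b]]
    segs <- p$segs
    beh <- segs$behavior_hint
    unk <- which(beh == "unknown")
    if (length(unk)) {
      su <- segs[unk, ]
      act_thr <- try_breakpoint(log(pmax(su$mean_activity, 1e-4)))
      if (is.null(act_thr)) act_thr <- pooled_act
      pitch_thr <- try_breakpoint(su$mean_pitch)
      if (is.null(pitch_thr)) pitch_thr <- pooled_pitch
      lab <- rep(NA_character_, length(unk))
      if (config$species == "murre") {
        if (!is.null(act_thr)) {
          lab <- ifelse(log(pmax(su$mean_activity, 1e-4)) < act_thr,
                        "colony", "swimming")
          if (!is.null(pitch_thr)) {
            lab[lab == "colony" & su$mean_pitch < pitch_thr] <- "swimming"
            lab[lab == "swimming" & su$mean_pitch > pitch_thr] <- "colony"
          }
        } else if (!is.null(pitch_thr)) {
          lab <- ifelse(su$mean_pitch > pitch_thr, "colony", "swimming")
        } else {
          lab <- assign_by_centroid(su$mean_pitch, su$mean_activity, config)
        }
      } else {
        if (!is.null(act_thr)) {
          lab <- ifelse(log(pmax(su$mean_activity, 1e-4)) < act_thr,
                        "colony", "swimming")
          if (!is.null(pitch_thr)) {
            lab[lab == "swimming" & su$mean_pitch > pitch_thr] <- "colony"
          }
        } else if (!is.null(pitch_thr)) {
          lab <- ifelse(su$mean_pitch > pitch_thr, "colony", "swimming")
        } else {
          lab <- assign_by_centroid(su$mean_pitch, su$mean_activity, config)
        }
      }
      beh[unk] <- lab
    }
    sec <- segments_to_seconds(segs, beh, nrow(p$f))
    ethogram_df(p$f$t, sec, b, "HS")
  })
  stats::setNames(out, names(per_bird))
}

# Map water/land clusters to behaviors from their feature means alone
# (high pitch and low activity read as colony), via the nearest reference
# class centroid. Pure function of the cluster feature means, never of
# cluster index, and robust to a behavior being absent from the data.
map_step2_clusters <- function(cluster, segments, config) {
  cl_pitch <- tapply(segments$mean_pitch, cluster, mean)
  cl_act <- tapply(segments$mean_activity, cluster, mean)
  lab <- assign_by_centroid(cl_pitch, cl_act, config)
  unname(lab[match(as.character(cluster), names(cl_pitch))])
}

two_step_cluster_classify <- function(features, config, method,
                                      step1_rule, step2_assign) {
  features <- as_feature_list(features)
  per_bird <- lapply(features, function(f) {
    labels <- first_pass(f, config, step1_rule)
    labels <- enforce_min_bout(labels)
    segs <- build_segments(labels, f, config)
    list(f = f, segs = segs)
  })
  pooled <- do.call(rbind, lapply(per_bird, function(p)
    cbind(p$segs, row_bird = attr(p$f, "bird_id") %||% "bird")))
  unk <- pooled[pooled$behavior_hint == "unknown", ]
  assign <- if (nrow(unk)) step2_assign(unk) else character(0)
  unk$assigned <- assign
  out <- lapply(names(per_bird), function(b) {
    p <- per_bird[[b]]
    beh <- p$segs$behavior_hint
    rows <- unk[unk$row_bird == (attr(p$f, "bird_id") %||% "bird"), ]
    beh[match(rows$segment_id, p$segs$segment_id)] <- rows$assigned
    sec <- segments_to_seconds(p$segs, beh, nrow(p$f))
    ethogram_df(p$f$t, sec, b, method)
  })
  stats::setNames(out, names(per_bird))
}

# Min-max scaling to [0, 1], the preprocessing used before the step-2
# clustering of segment means.
scale_to_range <- function(x) {
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

step2_matrix <- function(segments) {
  cbind(pitch = scale_to_range(segments$mean_pitch),
        lnact = scale_to_range(log(pmax(segments$mean_activity, 1e-4))))
}

#' k-Means (KM) classification
#'
#' Two steps on all tracks pooled: a 1-D 2-means on WBF whose
#' higher-center class is flying (murre diving fixed first by the depth
#' rule), then, after segmentation, k-means on segment-mean pitch and log
#' activity (both min-max scaled) with two colony classes and one
#' swimming class; clusters map to behaviors by their mean pitch.
#'
#' @inheritParams classify_hs
#' @param seed integer seed for the k-means starts.
#' @return named list of ethograms.
#' @export
classify_km <- function(features, config, seed = 1) {
  features <- as_feature_list(features)
  wbf_all <- unlist(lapply(features, function(f) {
    keep <- if (config$species == "murre" && !is.null(f$depth))
      !(f$depth < config$dive_depth_threshold) else TRUE
    f$WBF[keep]
  }), use.names = FALSE)
  thr <- with_seed(seed, {
    km1 <- stats::kmeans(wbf_all, centers = 2, nstart = 5, iter.max = 50)
    mean(range(km1$centers))  # 1-D k-means boundary = midpoint of centers
  })
  step2 <- function(unk) {
    with_seed(seed + 1L, {
      km2 <- stats::kmeans(step2_matrix(unk), centers = 3, nstart = 10,
                           iter.max = 100)
      map_step2_clusters(km2$cluster, unk, config)
    })
  }
  two_step_cluster_classify(features, config, "KM",
                            function(ff) ff$WBF > thr, step2)
}

#' Gaussian-mixture EM classification
#'
#' Identical two-step structure to [classify_km()] but each clustering is
#' a Gaussian mixture with free proportions fitted by EM: two components
#' on WBF (higher mean is flying), then 3-6 full-covariance components on
#' scaled segment pitch and log activity with the count chosen by BIC,
#' merged to behaviors by cluster mean pitch. Degenerate fits fall back to
#' the KM labels.
#'
#' @inheritParams classify_km
#' @param max_fit_n mixtures are fitted on at most this many points (the
#'   full data are then classified from the fitted model).
#' @return named list of ethograms.
#' @importFrom mclust Mclust mclustBIC predict.Mclust
#' @export
classify_em <- function(features, config, seed = 1, max_fit_n = 50000) {
  features <- as_feature_list(features)
  wbf_all <- unlist(lapply(features, function(f) {
    keep <- if (config$species == "murre" && !is.null(f$depth))
      !(f$depth < config$dive_depth_threshold) else TRUE
    f$WBF[keep]
  }), use.names = FALSE)
  # WBF carries a point mass at the first spectral bin (sub-bin
  # refinement needs an interior peak), which makes a Gaussian mixture
  # singular; a dither far below the bin width breaks the atom without
  # moving the class boundary. Degenerate fits are re-initialised on
  # fresh subsamples before falling back to k-means.
  fit1 <- with_seed(seed, {
    fit <- NULL
    for (attempt in 1:5) {
      idx <- if (length(wbf_all) > max_fit_n)
        sample.int(length(wbf_all), max_fit_n) else seq_along(wbf_all)
      x <- wbf_all[idx] + stats::runif(length(idx), -0.05, 0.05)
      fit <- tryCatch(
        mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    fit
  })
  if (is.null(fit1)) {
    warning("WBF mixture degenerate after 5 starts; using k-means step 1")
    return(classify_km(features, config, seed = seed))
  }
  # the zero atom gives the low component a near-degenerate variance, so
  # the posterior boundary collapses toward it; the midpoint between the
  # component means is the stable decision rule (as in 1-D k-means)
  mu <- fit1$parameters$mean
  thr_em <- mean(range(mu))
  flight_rule <- function(ff) ff$WBF > thr_em
  step2 <- function(unk) {
    X <- step2_matrix(unk)
    fit2 <- with_seed(seed + 1L, {
      init <- if (nrow(X) > 5000)
        list(subset = sample.int(nrow(X), 5000)) else NULL
      tryCatch(
        mclust::Mclust(X, G = 3:6, modelNames = "VVV",
                       initialization = init, verbose = FALSE),
        error = function(e) NULL)
    })
    if (is.null(fit2)) {
      return(with_seed(seed + 2L, {
        km <- stats::kmeans(X, centers = 3, nstart = 10, iter.max = 100)
        map_step2_clusters(km$cluster, unk, config)
      }))
    }
    map_step2_clusters(fit2$classification, unk, config)
  }
  two_step_cluster_classify(features, config, "EM", flight_rule, step2)
}

# The per-second feature columns used by the supervised NN/RF models:
# the a priori classification variables (pitch, activity metric, WBF,
# plus depth for murres).
clf_feature_frame <- function(features, config) {
  out <- data.frame(pitch = features$pitch,
                    activity = activity_metric(features, config),
                    WBF = features$WBF)
  if (config$species == "murre") out$depth <- features$depth
  out
}

#' Build a supervised training set from HS classifications
#'
#' Training data come from the HS ethograms, not from GPS, so the
#' supervised methods remain usable when GPS is absent: a random subset of
#' `n_tracks` tracks, then at most `per_class` rows per behavior per track
#' sampled without replacement.
#'
#' @param ethograms named list of ethograms (typically from
#'   [classify_hs()]).
#' @param features matching named list of feature frames.
#' @param config a [species_config()].
#' @param n_tracks number of tracks to draw (error if fewer available).
#' @param per_class maximum rows per behavior per track.
#' @param seed integer seed.
#' @return a `training_set` data frame of feature columns plus `behavior`
#'   and `bird_id`; attribute `tracks` records the provenance.
#' @export
build_training_set <- function(ethograms, features, config,
                               n_tracks = 10, per_class = 1000, seed = 1) {
  if (length(ethograms) < n_tracks) {
    stop(sprintf("need at least %d labelled tracks, have %d",
                 n_tracks, length(ethograms)))
  }
  with_seed(seed, {
    tracks <- sample(names(ethograms), n_tracks)
    rows <- lapply(tracks, function(b) {
      lab <- ethograms[[b]]$behavior
      X <- clf_feature_frame(features[[b]], config)
      picks <- unlist(lapply(split(seq_along(lab), lab), function(ii) {
        if (length(ii) > per_class) sample(ii, per_class) else ii
      }), use.names = FALSE)
      cbind(X[picks, , drop = FALSE],
            behavior = lab[picks], bird_id = b)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out <- out[stats::complete.cases(out), ]
    attr(out, "tracks") <- tracks
    attr(out, "seed") <- seed
    class(out) <- c("training_set", "data.frame")
    out
  })
}

apply_depth_override <- function(behavior, features, config) {
  if (config$species == "murre" && !is.null(features$depth)) {
    behavior[features$depth < config$dive_depth_threshold] <- "diving"
  }
  behavior
}

#' Neural-network classification
#'
#' Single-hidden-layer feed-forward network with five hidden nodes and a
#' softmax output over the behavior classes, trained on the HS-derived
#' training set with inputs standardised by the training means and SDs.
#' Every 1-s row of every track is predicted; the murre depth rule is
#' applied as an override after prediction. Non-converged fits are
#' retried with a new initialisation (up to five times).
#'
#' @param training a `training_set` from [build_training_set()].
#' @param features a `feature_frame` or named list of them.
#' @param config a [species_config()].
#' @param seed integer seed.
#' @return named list of ethograms.
#' @export
classify_nn <- function(training, features, config, seed = 1) {
  features <- as_feature_list(features)
  xcols <- setdiff(names(training), c("behavior", "bird_id"))
  mu <- vapply(training[xcols], mean, 0)
  sigma <- pmax(vapply(training[xcols], stats::sd, 0), 1e-8)
  X <- scale(as.matrix(training[xcols]), center = mu, scale = sigma)
  yf <- factor(training$behavior)
  if (nlevels(yf) == 1) {
    only <- levels(yf)
    out <- lapply(names(features), function(b) {
      f <- features[[b]]
      pred <- apply_depth_override(rep(only, nrow(f)), f, config)
      ethogram_df(f$t, pred, b, "NN")
    })
    return(stats::setNames(out, names(features)))
  }
  fit <- NULL
  with_seed(seed, {
    for (attempt in 1:5) {
      cand <- nnet::nnet(X, nnet::class.ind(yf), size = 5, softmax = TRUE,
                         maxit = 300, trace = FALSE, MaxNWts = 5000)
      train_acc <- mean(
        levels(yf)[max.col(cand$fitted.values)] == as.character(yf))
      fit <- cand
      if (cand$convergence == 0 || train_acc > 0.9) break
    }
  })
  out <- lapply(names(features), function(b) {
    f <- features[[b]]
    Xb <- scale(as.matrix(clf_feature_frame(f, config)),
                center = mu, scale = sigma)
    Xb[!is.finite(Xb)] <- 0
    pred <- levels(yf)[max.col(predict(fit, Xb))]
    pred <- apply_depth_override(pred, f, config)
    ethogram_df(f$t, pred, b, "NN")
  })
  stats::setNames(out, names(features))
}

#' Random-forest classification
#'
#' Random forest (500 trees, `floor(sqrt(p))` variables per split,
#' seeded, single-threaded for reproducibility) trained on the same
#' HS-derived training set as the NN, predicting every 1-s row with the
#' murre depth override.
#'
#' @inheritParams classify_nn
#' @param num_trees number of trees.
#' @param importance importance mode passed to the forest (default
#'   permutation, retrievable from the `forest` attribute of the result).
#' @return named list of ethograms; attribute `forest` holds the fit.
#' @export
classify_rf <- function(training, features, config, seed = 1,
                        num_trees = 500, importance = "permutation") {
  features <- as_feature_list(features)
  xcols <- setdiff(names(training), c("behavior", "bird_id"))
  df <- data.frame(behavior = factor(training$behavior), training[xcols])
  fit <- ranger::ranger(behavior ~ ., data = df, num.trees = num_trees,
                        mtry = floor(sqrt(length(xcols))),
                        min.node.size = 50, importance = importance,
                        seed = seed, num.threads = 1)
  out <- lapply(names(features), function(b) {
    f <- features[[b]]
    Xb <- clf_feature_frame(f, config)
    ok <- stats::complete.cases(Xb)
    pred <- rep(levels(df$behavior)[1], nrow(Xb))
    if (any(ok)) {
      pr <- predict(fit, data = Xb[ok, , drop = FALSE], num.threads = 1)
      pred[ok] <- as.character(pr$predictions)
    }
    pred <- apply_depth_override(pred, f, config)
    ethogram_df(f$t, pred, b, "RF")
  })
  attr(out, "forest") <- fit
  stats::setNames(out, names(features))
}
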