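# End-to-end pipeline drivers: simulate a cohort, extract features, run
# the six classifiers, and score against GPS-rule reference labels.

#' Simulate a cohort and compute calibrated features
#'
#' @param config a [species_config()].
#' @param params a [behavior_params()] preset.
#' @param n_birds number of deployments.
#' @param hours deployment length.
#' @param seeds integer seeds, one per bird.
#' @param extended_at_fixes if `TRUE`, also evaluate the extended metric
#'   library at the usable GPS fix times while the raw trace is in hand
#'   (the variable-selection input), so the trace need not be kept or
#'   regenerated.
#' @return list with per-bird `features`, `gps_labels` (transition
#'   exclusion applied), `states`, `gps`, and optionally
#'   `extended`/`extended_labels`.
#' @export
simulate_cohort <- function(config,
                            params = behavior_params(config$species, config$stage),
                            n_birds = 10, hours = 48,
                            seeds = seq_len(n_birds),
                            extended_at_fixes = FALSE) {
  stopifnot(length(seeds) == n_birds)
  birds <- sprintf("%s_%02d", config$species, seq_len(n_birds))
  features <- list(); gps_labels <- list(); states <- list(); gps <- list()
  depth_fix <- list(); extended <- list(); extended_labels <- list()
  for (i in seq_len(n_birds)) {
    dep <- simulate_deployment(config, params, hours = hours,
                               seed = seeds[i], bird_id = birds[i])
    f <- compute_features(dep$trace, config)
    f <- calibrate_pitch(f, config)
    fi <- round(dep$gps$t / stats::median(diff(dep$trace$t))) + 1
    if (config$species == "murre") {
      dfix <- dep$trace$depth[fi]
      lab <- label_gps_murre(dep$gps, dfix, nest = c(0, 0), config)
    } else {
      dfix <- NULL
      lab <- label_gps_kittiwake(dep$gps, island = c(0, 0), config)
    }
    lab <- mark_transitions(lab, config$transition_window)
    if (extended_at_fixes) {
      keep <- lab$behavior != "excluded"
      extended[[birds[i]]] <- extended_metrics(dep$trace, at = lab$t[keep])
      extended_labels[[birds[i]]] <- lab$behavior[keep]
    }
    features[[birds[i]]] <- f
    gps_labels[[birds[i]]] <- lab
    states[[birds[i]]] <- dep$states
    gps[[birds[i]]] <- dep$gps
    depth_fix[[birds[i]]] <- dfix
  }
  out <- list(features = features, gps_labels = gps_labels, states = states,
              gps = gps, depth_fix = depth_fix, config = config,
              params = params)
  if (extended_at_fixes) {
    out$extended <- extended
    out$extended_labels <- extended_labels
  }
  out
}

#' Run the six classification methods on a cohort
#'
#' @param cohort result of [simulate_cohort()] (or a compatible list with
#'   `features` and `config`).
#' @param methods subset of `c("HS","KM","EM","NN","RF","HMM")`.
#' @param seed integer seed for the stochastic methods.
#' @param n_tracks,per_class training-set parameters for NN/RF.
#' @return named list (method) of named lists (bird) of ethograms.
#' @export
run_classifiers <- function(cohort, methods = c("HS", "KM", "EM", "NN",
                                                "RF", "HMM"),
                            seed = 1, n_tracks = min(10, length(cohort$features)),
                            per_class = 1000) {
  config <- cohort$config
  features <- cohort$features
  out <- list()
  hs <- NULL
  if (any(c("HS", "NN", "RF") %in% methods)) {
    hs <- classify_hs(features, config)
  }
  if ("HS" %in% methods) out$HS <- hs
  if ("KM" %in% methods) out$KM <- classify_km(features, config, seed = seed)
  if ("EM" %in% methods) out$EM <- classify_em(features, config, seed = seed)
  if (any(c("NN", "RF") %in% methods)) {
    training <- build_training_set(hs, features, config,
                                   n_tracks = n_tracks,
                                   per_class = per_class, seed = seed)
    if ("NN" %in% methods) {
      out$NN <- classify_nn(training, features, config, seed = seed)
    }
    if ("RF" %in% methods) {
      out$RF <- classify_rf(training, features, config, seed = seed)
    }
  }
  if ("HMM" %in% methods) out$HMM <- classify_hmm(features, config)
  out[intersect(methods, names(out))]
}

#' Score classifier outputs against the GPS reference
#'
#' @param ethograms output of [run_classifiers()].
#' @param cohort the cohort the ethograms were computed on.
#' @return data frame with one row per (method, bird): overall accuracy
#'   and fix counts.
#' @export
score_cohort <- function(ethograms, cohort) {
  config <- cohort$config
  rows <- list()
  for (m in names(ethograms)) {
    for (b in names(ethograms[[m]])) {
      cs <- score_ethogram(ethograms[[m]][[b]], cohort$gps_labels[[b]],
                           config)
      rows[[length(rows) + 1]] <- data.frame(
        method = m, bird_id = b,
        overall_accuracy = cs$overall_accuracy,
        n_used = cs$n_used, n_excluded = cs$n_excluded)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate, classify, and score a full benchmark cohort
#'
#' Convenience wrapper for the whole pipeline at study scale: simulate
#' `n_birds` deployments, extract and calibrate features, run the
#' requested methods, and score each against the GPS-rule reference at
#' the species evaluation resolution.
#'
#' @inheritParams simulate_cohort
#' @inheritParams run_classifiers
#' @return list: `scores` (per method x bird), `ethograms`, `cohort`.
#' @export
run_benchmark <- function(config,
                          params = behavior_params(config$species, config$stage),
                          n_birds = 10, hours = 48,
                          seeds = seq_len(n_birds),
                          methods = c("HS", "KM", "EM", "NN", "RF", "HMM"),
                          seed = 1, extended_at_fixes = FALSE) {
  cohort <- simulate_cohort(config, params, n_birds = n_birds,
                            hours = hours, seeds = seeds,
                            extended_at_fixes = extended_at_fixes)
  ethograms <- run_classifiers(cohort, methods = methods, seed = seed)
  scores <- score_cohort(ethograms, cohort)
  list(scores = scores, ethograms = ethograms, cohort = cohort)
}
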