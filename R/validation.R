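# GPS rule-based reference labelling, transition exclusion, confusion
# scoring, and energetics.

gps_labels_df <- function(t, behavior, reason) {
  out <- data.frame(t = t, behavior = behavior, exclusion_reason = reason)
  class(out) <- c("gps_labels", "data.frame")
  out
}

#' GPS-rule reference labels for a murre track
#'
#' Rules applied in order of precedence: fixes requiring a ground speed
#' above the error cutoff (30 m/s) are excluded as potential GPS errors;
#' depth below -1 m is diving; remaining speeds above 2 m/s are flying;
#' fixes within 250 m of the nest are colony; the rest is swimming. All
#' speed thresholds are strict inequalities.
#'
#' @param gps a `gps_track` (planar nest-centered meters).
#' @param depth depth in meters at each fix time (from the 1 Hz pressure
#'   channel).
#' @param nest nest coordinates `c(x, y)`.
#' @param config a [species_config()].
#' @return a `gps_labels` data frame.
#' @export
label_gps_murre <- function(gps, depth, nest = c(0, 0), config) {
  if (is.null(nest) || length(nest) != 2 || anyNA(nest)) {
    stop("nest location is required for murre GPS labelling")
  }
  if (length(depth) != nrow(gps)) stop("depth must be synchronised to fixes")
  speed <- ground_speed(gps)
  dist <- sqrt((gps$x - nest[1])^2 + (gps$y - nest[2])^2)
  n <- nrow(gps)
  behavior <- rep("swimming", n)
  reason <- rep("none", n)
  behavior[dist <= config$colony_radius] <- "colony"
  behavior[speed > config$gps_flight_speed] <- "flying"
  behavior[depth < config$dive_depth_threshold] <- "diving"
  err <- speed > config$gps_speed_error_cutoff
  behavior[err] <- "excluded"
  reason[err] <- "speed_error"
  gps_labels_df(gps$t, behavior, reason)
}

#' GPS-rule reference labels for a kittiwake track
#'
#' Fixes needing a ground speed above 20 m/s or separated from the
#' previous fix by more than 10 min are excluded as potential GPS errors;
#' fixes within 500 m of the island are excluded because loafing on tidal
#' flats cannot be separated from swimming there; speeds above 3 m/s are
#' flying and the remainder swimming.
#'
#' @param gps a `gps_track`.
#' @param island island center `c(x, y)`; the exclusion region is the
#'   disc of `config$island_exclusion_radius`.
#' @param config a [species_config()].
#' @return a `gps_labels` data frame.
#' @export
label_gps_kittiwake <- function(gps, island = c(0, 0), config) {
  speed <- ground_speed(gps)
  dist <- sqrt((gps$x - island[1])^2 + (gps$y - island[2])^2)
  n <- nrow(gps)
  behavior <- rep("swimming", n)
  reason <- rep("none", n)
  behavior[speed > config$gps_flight_speed] <- "flying"
  near <- dist <= config$island_exclusion_radius
  behavior[near] <- "excluded"
  reason[near] <- "near_island"
  gap <- c(FALSE, diff(gps$t) > config$gps_gap_cutoff)
  err <- speed > config$gps_speed_error_cutoff
  behavior[gap] <- "excluded"; reason[gap] <- "gap"
  behavior[err] <- "excluded"; reason[err] <- "speed_error"
  gps_labels_df(gps$t, behavior, reason)
}

#' Exclude fixes around GPS-detected behavior transitions
#'
#' The GPS reference is slower to register a behavior change than the
#' accelerometer, so fixes within `window` seconds of a transition
#' between colony, flying, or swimming are excluded. Diving-swimming
#' changes are exempt: the 1 Hz pressure channel times dives exactly.
#' The change time is taken as the midpoint between the two usable fixes
#' bracketing it (it is only known to fix resolution) and the exclusion
#' interval is closed.
#'
#' @param labels a `gps_labels` data frame.
#' @param window exclusion half-width in seconds
#'   (`config$transition_window`).
#' @return the labels with transition fixes excluded.
#' @export
mark_transitions <- function(labels, window) {
  usable <- which(labels$behavior != "excluded")
  if (length(usable) < 2) return(labels)
  cfs <- labels$behavior[usable]
  cfs[cfs == "diving"] <- "swimming"  # dive-swim changes are exempt
  chg <- which(cfs[-1] != cfs[-length(cfs)])
  if (!length(chg)) return(labels)
  mids <- (labels$t[usable[chg]] + labels$t[usable[chg + 1]]) / 2
  drop <- rep(FALSE, nrow(labels))
  for (m in mids) {
    drop <- drop | (abs(labels$t - m) <= window &
                      labels$behavior != "excluded")
  }
  labels$exclusion_reason[drop] <- "transition"
  labels$behavior[drop] <- "excluded"
  labels
}

#' Score an ethogram against GPS reference labels
#'
#' The per-second ethogram is subsampled to the fix times (matching the
#' GPS resolution), excluded fixes are dropped, and a confusion matrix is
#' built with the reference in rows. Overall accuracy is the trace over
#' the total; balanced accuracy per behavior is the one-vs-rest mean of
#' sensitivity and specificity.
#'
#' @param ethogram an ethogram data frame (`t`, `behavior`).
#' @param gps_labels a `gps_labels` data frame (after
#'   [mark_transitions()]).
#' @param config a [species_config()].
#' @return a `confusion_summary` list: `matrix`, `overall_accuracy`,
#'   `balanced_accuracy`, `n_used`, `n_excluded`.
#' @export
score_ethogram <- function(ethogram, gps_labels, config) {
  t0 <- ethogram$t[1]
  step <- stats::median(diff(ethogram$t))
  idx <- round((gps_labels$t - t0) / step) + 1
  in_range <- idx >= 1 & idx <= nrow(ethogram)
  usable <- gps_labels$behavior != "excluded" & in_range
  n_excluded <- sum(gps_labels$behavior == "excluded")
  if (!any(usable)) stop("no usable fixes overlap the ethogram")
  ref <- gps_labels$behavior[usable]
  pred <- ethogram$behavior[idx[usable]]
  classes <- sort(unique(c(ref, pred)))
  cm <- table(reference = factor(ref, classes),
              predicted = factor(pred, classes))
  overall <- sum(diag(cm)) / sum(cm)
  bal <- vapply(classes, function(cl) {
    tp <- sum(ref == cl & pred == cl)
    fn <- sum(ref == cl & pred != cl)
    fp <- sum(ref != cl & pred == cl)
    tn <- sum(ref != cl & pred != cl)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    mean(c(sens, spec), na.rm = TRUE)
  }, 0)
  structure(list(matrix = cm, overall_accuracy = overall,
                 balanced_accuracy = bal,
                 n_used = sum(usable), n_excluded = n_excluded),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.3f (%d fixes used, %d excluded)\n",
              x$overall_accuracy, x$n_used, x$n_excluded))
  print(x$matrix)
  cat("Balanced accuracy:\n")
  print(round(x$balanced_accuracy, 3))
  invisible(x)
}

#' Daily time-activity budget from an ethogram
#'
#' Hours spent in each behavior per bird-day (days split at multiples of
#' 24 h from the track start). Components sum to the labelled hours in
#' each day.
#'
#' @param ethogram an ethogram data frame.
#' @param config a [species_config()].
#' @return data frame with `day` and one hours column per behavior.
#' @export
activity_budget <- function(ethogram, config) {
  step <- stats::median(diff(ethogram$t))
  day <- floor((ethogram$t - ethogram$t[1]) / 86400)
  tab <- table(day = day,
               behavior = factor(ethogram$behavior, config$behaviors))
  out <- as.data.frame.matrix(tab * step / 3600)
  out <- cbind(day = as.integer(rownames(out)), out)
  rownames(out) <- NULL
  attr(out, "bird_id") <- attr(ethogram, "bird_id")
  out
}

#' Daily energy expenditure from an activity budget
#'
#' Linear combination of hours per behavior with the species-specific
#' coefficients (kJ per hour): 32.0 colony, 532.8 flying, 100.8 swimming,
#' 97.2 diving for murres; 21.0 colony, 99.9 flying, 25.8 swimming for
#' kittiwakes (flight and surface metabolic rates converted from CO2
#' production assuming 27.33 kJ/L CO2 and a 416 g bird).
#'
#' @param budget a data frame from [activity_budget()] or a named vector
#'   of hours.
#' @param config a [species_config()].
#' @return kJ per day (one value per budget row).
#' @export
daily_energy <- function(budget, config) {
  coefs <- config$dee_coefficients
  if (!is.data.frame(budget)) budget <- as.data.frame(as.list(budget))
  if (any(!is.finite(as.matrix(budget[intersect(names(budget),
                                                names(coefs))]))) ||
      any(as.matrix(budget[intersect(names(budget), names(coefs))]) < 0)) {
    stop("budget hours must be finite and non-negative")
  }
  extra <- setdiff(setdiff(names(budget), "day"), names(coefs))
  for (e in extra) {
    if (any(budget[[e]] > 0)) {
      stop(sprintf("budget contains hours for '%s', not a %s behavior",
                   e, config$species))
    }
  }
  out <- numeric(nrow(budget))
  for (b in names(coefs)) {
    if (!is.null(budget[[b]])) out <- out + coefs[[b]] * budget[[b]]
  }
  out
}
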