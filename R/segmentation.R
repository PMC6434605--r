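# Track segmentation: convert per-second first-pass labels (diving /
# flying / unknown) into bouts and bounded segments with per-segment mean
# metrics, the shared backbone for the HS/KM/EM classifiers.

#' First-pass per-second labels
#'
#' Diving wherever depth is below -1 m (murres; a missing depth channel is
#' an error for that species), flying wherever the supplied
#' method-specific flight criterion holds, everything else unknown.
#'
#' @param features a `feature_frame` on the 1-s grid.
#' @param config a [species_config()].
#' @param flight_rule function of the feature frame returning a logical
#'   flying indicator (e.g. a WBF threshold for HS, a cluster membership
#'   for KM/EM).
#' @return character vector of labels `diving`/`flying`/`unknown`.
#' @export
first_pass <- function(features, config, flight_rule) {
  n <- nrow(features)
  labels <- rep("unknown", n)
  flying <- flight_rule(features)
  flying[is.na(flying)] <- FALSE
  labels[flying] <- "flying"
  if (config$species == "murre") {
    if (is.null(features$depth)) stop("murre classification requires depth")
    labels[features$depth < config$dive_depth_threshold] <- "diving"
  }
  labels
}

#' Enforce a minimum bout length on per-second labels
#'
#' Any maximal run shorter than `min_bout` seconds is re-assigned to the
#' previous run's label, scanning left to right; leading short runs (which
#' have no previous behavior) take the first following label that survives.
#' Adjacent same-label runs are then merged.
#'
#' @param labels per-second label vector on a regular grid.
#' @param min_bout minimum run length in seconds.
#' @return relabelled vector of the same length.
#' @export
enforce_min_bout <- function(labels, min_bout = 3) {
  r <- rle(labels)
  k <- length(r$lengths)
  if (k <= 1) return(labels)
  first_long <- which(r$lengths >= min_bout)[1]
  if (is.na(first_long)) first_long <- which.max(r$lengths)
  if (first_long > 1) r$values[seq_len(first_long - 1)] <- r$values[first_long]
  for (i in seq.int(first_long + 1, length.out = max(0, k - first_long))) {
    if (r$lengths[i] < min_bout) r$values[i] <- r$values[i - 1]
  }
  inverse.rle(r)
}

#' Build bounded segments with per-segment mean metrics
#'
#' Each maximal constant-label run is split left to right into chunks of
#' at most `max_len` seconds (remainder last), so a missed transition
#' cannot propagate an error beyond one segment and long incubation bouts
#' do not swamp the segment table. Segments are half-open `[start, end)`
#' on the 1-s grid and partition the labelled timeline. Per-segment means
#' of pitch, the species activity metric, WBF, and depth are computed over
#' member seconds.
#'
#' @param labels per-second labels (after [enforce_min_bout()]).
#' @param features the matching `feature_frame`.
#' @param config a [species_config()].
#' @param max_len maximum segment length, seconds.
#' @return a `segment_table` data frame.
#' @export
build_segments <- function(labels, features, config, max_len = 120) {
  r <- rle(labels)
  run_end <- cumsum(r$lengths)
  run_start <- c(0, run_end[-length(run_end)])
  starts <- ends <- integer(0)
  hints <- character(0)
  for (i in seq_along(r$lengths)) {
    s <- seq(run_start[i], run_end[i] - 1, by = max_len)
    e <- pmin(s + max_len, run_end[i])
    starts <- c(starts, s)
    ends <- c(ends, e)
    hints <- c(hints, rep(r$values[i], length(s)))
  }
  act <- activity_metric(features, config)
  seg_idx <- findInterval(seq_len(nrow(features)) - 1, starts)
  mean_by <- function(v) {
    out <- tapply(v, seg_idx, mean, na.rm = TRUE)
    as.numeric(out[as.character(seq_along(starts))])
  }
  out <- data.frame(
    segment_id = seq_along(starts),
    bird_id = attr(features, "bird_id") %||% "bird",
    behavior_hint = hints,
    start = starts, end = ends,
    mean_pitch = mean_by(features$pitch),
    mean_activity = mean_by(act),
    mean_WBF = mean_by(features$WBF)
  )
  out$mean_depth <- if (!is.null(features$depth)) mean_by(features$depth)
    else NA_real_
  class(out) <- c("segment_table", "data.frame")
  out
}

# Expand per-segment behaviors back to the per-second grid.
segments_to_seconds <- function(segments, behaviors, n_sec) {
  lab <- character(n_sec)
  for (i in seq_len(nrow(segments))) {
    lab[(segments$start[i] + 1):segments$end[i]] <- behaviors[i]
  }
  lab
}
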