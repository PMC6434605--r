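#' Read a biologger acceleration CSV
#'
#' Expects comma-separated data with a header row and columns `time`, `X`,
#' `Y`, `Z`, optionally `depth` and `temperature`. `time` is seconds since
#' deployment start; acceleration is in g. Depth and temperature channels
#' are typically logged at 1 Hz; missing values between 1 Hz ticks are
#' carried forward (step fill) onto the 25 Hz acceleration base, so a dive
#' onset is never smeared by interpolation.
#'
#' @param path CSV file.
#' @param config optional [species_config()] used to sanity-check the
#'   sampling rate against the species wing-beat band (Nyquist).
#' @return An `accel_trace` data frame with attribute `bird_id`.
#' @export
read_accel_csv <- function(path, config = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time", "X", "Y", "Z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("accelerometer CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  trace <- data.frame(t = as.numeric(df$time),
                      X = as.numeric(df$X),
                      Y = as.numeric(df$Y),
                      Z = as.numeric(df$Z))
  if (!is.null(df$depth)) trace$depth <- fill_forward(as.numeric(df$depth))
  if (!is.null(df$temperature)) {
    trace$temperature <- fill_forward(as.numeric(df$temperature))
  }
  bird <- if (!is.null(df$bird_id)) as.character(df$bird_id[1]) else
    sub("\\.csv$", "", basename(path))
  as_accel_trace(trace, bird_id = bird, config = config)
}

#' Construct and validate an acceleration trace
#'
#' @param df data frame with columns `t`, `X`, `Y`, `Z` and optionally
#'   `depth`, `temperature`.
#' @param bird_id deployment identifier.
#' @param config optional [species_config()] for the Nyquist check: the
#'   sampling rate must be at least twice the upper edge of the species
#'   wing-beat band or the flight signal cannot be resolved.
#' @return the validated `accel_trace`.
#' @export
as_accel_trace <- function(df, bird_id = "bird", config = NULL) {
  if (!nrow(df)) stop("empty acceleration trace")
  if (any(diff(df$t) <= 0)) stop("time must be strictly increasing")
  if (!all(is.finite(df$X) & is.finite(df$Y) & is.finite(df$Z))) {
    stop("non-finite acceleration values")
  }
  if (!is.null(config) && nrow(df) > 1) {
    fs <- 1 / stats::median(diff(df$t))
    if (fs < 2 * config$flight_wbf_band[2]) {
      stop(sprintf(
        "sampling rate %.1f Hz is below the Nyquist limit for the %g-%g Hz flight band",
        fs, config$flight_wbf_band[1], config$flight_wbf_band[2]))
    }
  }
  attr(df, "bird_id") <- bird_id
  class(df) <- c("accel_trace", "data.frame")
  df
}

#' Write an acceleration trace to CSV
#'
#' Round-trips with [read_accel_csv()] to printed precision.
#'
#' @param trace an `accel_trace`.
#' @param path output file.
#' @export
write_accel_csv <- function(trace, path) {
  out <- as.data.frame(trace)
  names(out)[names(out) == "t"] <- "time"
  out$bird_id <- attr(trace, "bird_id")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Reader hook for Technosmart Axy exports
#'
#' Thin adapter for the tag manufacturer's column naming
#' (`Timestamp`/`accX`/`accY`/`accZ`/`Depth`/`Temp`); timestamps are
#' converted to seconds since the first record. Real-data parsing is a
#' convenience hook, not part of the tested surface.
#'
#' @param path CSV file in Axy export layout.
#' @param config optional [species_config()].
#' @return an `accel_trace`.
#' @export
read_axy_csv <- function(path, config = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  map <- c(Timestamp = "time", accX = "X", accY = "Y", accZ = "Z",
           Depth = "depth", Temp = "temperature")
  for (nm in names(map)) {
    if (nm %in% names(df)) names(df)[names(df) == nm] <- map[[nm]]
  }
  if ("time" %in% names(df) && !is.numeric(df$time)) {
    ts <- as.POSIXct(df$time, tz = "UTC")
    df$time <- as.numeric(ts) - as.numeric(ts[1])
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  out <- read_accel_csv(tmp, config = config)
  attr(out, "bird_id") <- sub("\\.csv$", "", basename(path))
  out
}

#' Read/write a GPS track CSV
#'
#' Columns `time`, `x`, `y` (planar meters in a nest-centered frame) or
#' `time`, `lon`, `lat` (degrees, real data).
#'
#' @param path CSV file.
#' @return a `gps_track` data frame with attribute `bird_id` and
#'   `coord_type` (`"planar"` or `"lonlat"`).
#' @export
read_gps_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("GPS CSV is missing the 'time' column")
  bird <- if (!is.null(df$bird_id)) as.character(df$bird_id[1]) else
    sub("\\.csv$", "", basename(path))
  if (all(c("x", "y") %in% names(df))) {
    out <- data.frame(t = df$time, x = df$x, y = df$y)
    type <- "planar"
  } else if (all(c("lon", "lat") %in% names(df))) {
    out <- data.frame(t = df$time, lon = df$lon, lat = df$lat)
    type <- "lonlat"
  } else {
    stop("GPS CSV needs either x/y or lon/lat columns")
  }
  if (any(diff(out$t) <= 0)) stop("GPS time must be strictly increasing")
  attr(out, "bird_id") <- bird
  attr(out, "coord_type") <- type
  class(out) <- c("gps_track", "data.frame")
  out
}

#' @rdname read_gps_csv
#' @param track a `gps_track`.
#' @export
write_gps_csv <- function(track, path) {
  out <- as.data.frame(track)
  names(out)[names(out) == "t"] <- "time"
  out$bird_id <- attr(track, "bird_id")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Subsample a time-indexed table to a regular grid
#'
#' Keeps the record nearest each grid point `0, interval, 2*interval, ...`
#' measured from the first timestamp. Applied to the 25 Hz trace with
#' `interval = 1` this is the 1-s subsampling used before classification;
#' applied to 1-s features with `interval = 60` (murres) or `30`
#' (kittiwakes) it matches the GPS resolution for validation.
#'
#' @param x data frame with a `t` column (an `accel_trace`, feature frame,
#'   or ethogram).
#' @param interval grid spacing in seconds; must not be finer than the
#'   native sampling interval.
#' @return the subsampled object, attributes preserved.
#' @export
subsample <- function(x, interval) {
  if (!"t" %in% names(x)) stop("subsample() needs a 't' column")
  native <- stats::median(diff(x$t))
  if (interval < native - 1e-9) {
    stop(sprintf("interval %g s is finer than the native step %g s",
                 interval, native))
  }
  t0 <- x$t[1]
  duration <- x$t[nrow(x)] - t0
  grid <- t0 + seq(0, duration, by = interval)
  idx <- round(stats::approx(x$t, seq_len(nrow(x)), xout = grid,
                             rule = 2)$y)
  out <- x[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in setdiff(names(attributes(x)), c("row.names", "names", "class"))) {
    attr(out, a) <- attr(x, a)
  }
  class(out) <- class(x)
  out
}

#' Per-fix ground speed of a GPS track
#'
#' Speed at fix i is the distance from fix i-1 divided by the elapsed time;
#' the first fix is assigned the speed of the second. Planar tracks use
#' Euclidean distance; lon/lat tracks use the haversine great-circle
#' distance.
#'
#' @param track a `gps_track` (or data frame with `t` plus `x`/`y` or
#'   `lon`/`lat`).
#' @return numeric vector of speeds in m/s, one per fix.
#' @export
ground_speed <- function(track) {
  if (nrow(track) < 2) stop("ground speed needs at least two fixes")
  dt <- diff(track$t)
  if (any(dt == 0)) stop("duplicate GPS timestamps")
  if (all(c("x", "y") %in% names(track))) {
    dist <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  } else if (all(c("lon", "lat") %in% names(track))) {
    dist <- haversine_m(track$lon[-nrow(track)], track$lat[-nrow(track)],
                        track$lon[-1], track$lat[-1])
  } else {
    stop("track needs x/y or lon/lat columns")
  }
  speed <- dist / dt
  c(speed[1], speed)
}

haversine_m <- function(lon1, lat1, lon2, lat2, radius = 6371008.8) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

fill_forward <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  # values before the first observation take the first observed value
  first_obs <- which(idx > 0)[1]
  if (is.na(first_obs)) return(x)
  idx[idx == 0L] <- idx[first_obs]
  x[idx]
}
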