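#!/usr/bin/env Rscript
# Compute the per-second feature frames (static/dynamic acceleration,
# pitch, SD_Z / SD_ODBA, WBF, depth) from the simulated deployments of
# 01_simulate.R, calibrate pitch to presumed flight, and write them out.

library(ethogramr)

in_dir <- "results/simulated"
out_dir <- "results/features"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

accel_files <- list.files(in_dir, "_accel\\.csv$", full.names = TRUE)
if (!length(accel_files)) stop("run analysis/01_simulate.R first")

for (path in accel_files) {
  sp <- if (grepl("kittiwake", basename(path))) "kittiwake" else "murre"
  cfg <- species_config(sp, "chick")
  trace <- read_accel_csv(path, config = cfg)
  f <- calibrate_pitch(compute_features(trace, cfg), cfg)
  bid <- attr(trace, "bird_id")
  utils::write.csv(as.data.frame(f),
                   file.path(out_dir, paste0(bid, "_features.csv")),
                   row.names = FALSE)
  message(sprintf(
    "%s: %d s, pitch offset %.1f deg, WBF nonzero fraction %.2f", bid,
    nrow(f), attr(f, "pitch_offset"), mean(f$WBF > 0)))
}
message("Wrote 1-s feature frames under ", out_dir)
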