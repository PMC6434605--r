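#!/usr/bin/env Rscript
# Build GPS-rule reference labels for the simulated deployments, apply
# the transition-exclusion window, and score every method's ethogram.
# Writes the per-(method, bird) accuracy table and pooled confusion
# matrices.

library(ethogramr)

dir.create("results/validation", recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (sp in c("murre", "kittiwake")) {
  cfg <- species_config(sp, "chick")
  gps_paths <- list.files("results/simulated",
                          paste0("^", sp, ".*_gps\\.csv$"), full.names = TRUE)
  for (gp in gps_paths) {
    bid <- sub("_gps\\.csv$", "", basename(gp))
    gps <- read_gps_csv(gp)
    if (sp == "murre") {
      trace <- read_accel_csv(
        file.path("results/simulated", paste0(bid, "_accel.csv")), cfg)
      fi <- round(gps$t * 25) + 1
      lab <- label_gps_murre(gps, trace$depth[fi], nest = c(0, 0), cfg)
    } else {
      lab <- label_gps_kittiwake(gps, island = c(0, 0), cfg)
    }
    lab <- mark_transitions(lab, cfg$transition_window)
    excl <- mean(lab$behavior == "excluded")
    for (m in c("HS", "KM", "EM", "NN", "RF", "HMM")) {
      ep <- file.path("results/ethograms", sprintf("%s_%s.csv", bid, m))
      if (!file.exists(ep)) next
      eth <- utils::read.csv(ep)
      cs <- score_ethogram(eth, lab, cfg)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, bird_id = bid, method = m,
        overall_accuracy = cs$overall_accuracy,
        n_used = cs$n_used, excluded_fraction = round(excl, 3))
    }
  }
}
acc <- do.call(rbind, rows)
utils::write.csv(acc, "results/validation/accuracy.csv", row.names = FALSE)
agg <- aggregate(overall_accuracy ~ species + method, acc, mean)
print(agg)
message(sprintf(
  "Mean accuracy across methods: murre %.3f, kittiwake %.3f",
  mean(acc$overall_accuracy[acc$species == "murre"]),
  mean(acc$overall_accuracy[acc$species == "kittiwake"])))
message("Wrote results/validation/accuracy.csv")
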