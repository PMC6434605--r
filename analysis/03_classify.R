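#!/usr/bin/env Rscript
# Run the six classification methods on the feature frames from
# 02_features.R and write one ethogram CSV per method and bird.

library(ethogramr)

in_dir <- "results/features"
out_dir <- "results/ethograms"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

load_features <- function(path, cfg) {
  f <- utils::read.csv(path)
  attr(f, "bird_id") <- sub("_features\\.csv$", "", basename(path))
  attr(f, "species") <- cfg$species
  class(f) <- c("feature_frame", "data.frame")
  f
}

for (sp in c("murre", "kittiwake")) {
  cfg <- species_config(sp, "chick")
  paths <- list.files(in_dir, paste0("^", sp, ".*_features\\.csv$"),
                      full.names = TRUE)
  if (!length(paths)) stop("run analysis/02_features.R first")
  features <- lapply(paths, load_features, cfg = cfg)
  names(features) <- vapply(features, attr, "", "bird_id")
  eth <- run_classifiers(list(features = features, config = cfg),
                         seed = 1, n_tracks = length(features),
                         per_class = 1000)
  for (m in names(eth)) {
    for (b in names(eth[[m]])) {
      utils::write.csv(as.data.frame(eth[[m]][[b]]),
                       file.path(out_dir, sprintf("%s_%s.csv", b, m)),
                       row.names = FALSE)
    }
    agree <- mean(eth[[m]][[1]]$behavior == eth$HS[[1]]$behavior)
    message(sprintf("%s %s: agreement with HS on %s = %.3f",
                    sp, m, names(eth[[m]])[1], agree))
  }
}
message("Wrote per-method ethograms under ", out_dir)
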