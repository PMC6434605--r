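# Forward variable selection over the extended metric library with
# random-forest models, evaluating candidate variables by their median
# held-out accuracy over repeated random training sets.

sample_selection_training <- function(pool, n_tracks, per_class) {
  tracks <- sample(unique(pool$bird_id), n_tracks)
  idx <- unlist(lapply(tracks, function(b) {
    rows <- which(pool$bird_id == b)
    unlist(lapply(split(rows, pool$behavior[rows]), function(ii) {
      if (length(ii) > per_class) sample(ii, per_class) else ii
    }), use.names = FALSE)
  }), use.names = FALSE)
  sort(idx)
}

# Candidate-evaluation forests are kept small (shallow trees, modest
# tree count): with thousands of fits per selection run, tree size is
# the dominant cost, and held-out accuracy on these class structures is
# insensitive to both knobs.
fit_eval_rf <- function(pool, vars, train_idx, num_trees, seed) {
  df <- data.frame(behavior = factor(pool$behavior),
                   pool[vars])
  fit <- ranger::ranger(behavior ~ ., data = df[train_idx, , drop = FALSE],
                        num.trees = num_trees,
                        mtry = max(1, floor(sqrt(length(vars)))),
                        min.node.size = 50, max.depth = 8,
                        seed = seed, num.threads = 1)
  test_idx <- setdiff(seq_len(nrow(df)), train_idx)
  if (!length(test_idx)) {
    stop("training draw uses every labelled row; lower per_class ",
         "or supply more tracks so a held-out set remains")
  }
  pred <- predict(fit, data = df[test_idx, , drop = FALSE],
                  num.threads = 1)$predictions
  mean(as.character(pred) == as.character(df$behavior[test_idx]))
}

#' Forward variable selection with random forests
#'
#' Training rows are reference-labelled observations (typically usable
#' GPS fixes with the extended metrics evaluated at the fix times),
#' emulating a realistic paired GPS-accelerometer training data set. A
#' global forest on all variables and one full training draw ranks
#' importance and keeps the `top_k` most influential candidates. At each
#' forward step, every remaining candidate is evaluated over `n_sim`
#' random training sets (`n_tracks` tracks, at most `per_class` rows per
#' behavior per track); rows not sampled into the training set form the
#' held-out test set; the variable with the highest median held-out
#' accuracy is added. Confidence bounds are the 2.5th and 97.5th
#' percentiles over simulations.
#'
#' @param metrics named list (per bird) of extended-metric data frames.
#' @param labels named list (per bird) of reference behavior labels, one
#'   per metric row; rows labelled `"excluded"` or `NA` are dropped.
#' @param config a [species_config()].
#' @param n_steps number of forward-selection steps (clipped with a
#'   warning if it exceeds the candidate count).
#' @param n_sim simulations per step.
#' @param n_tracks,per_class training-set sampling parameters.
#' @param top_k prefilter size from global importance.
#' @param num_trees trees per forest in the selection fits.
#' @param seed integer seed.
#' @return a `selection_path` data frame (step, variable,
#'   median_accuracy, lo, hi) with attributes `global_accuracy` and
#'   `global_importance`.
#' @export
forward_selection <- function(metrics, labels, config, n_steps = 10,
                              n_sim = 100, n_tracks = 10, per_class = 1000,
                              top_k = 20, num_trees = 50, seed = 1) {
  stopifnot(identical(names(metrics), names(labels)))
  pool <- do.call(rbind, lapply(names(metrics), function(b) {
    m <- metrics[[b]]
    lab <- labels[[b]]
    keep <- !is.na(lab) & lab != "excluded"
    cbind(m[keep, , drop = FALSE], behavior = lab[keep], bird_id = b)
  }))
  rownames(pool) <- NULL
  cand_all <- intersect(extended_metric_names(config$species == "murre"),
                        names(pool))
  pool <- pool[stats::complete.cases(pool[cand_all]), ]
  if (length(unique(pool$bird_id)) < n_tracks) {
    stop("fewer labelled tracks than n_tracks")
  }
  with_seed(seed, {
    train0 <- sample_selection_training(pool, n_tracks, per_class)
    if (length(train0) >= nrow(pool)) {
      stop("training draw uses every labelled row; lower per_class ",
           "or supply more tracks so a held-out set remains")
    }
    gdf <- data.frame(behavior = factor(pool$behavior), pool[cand_all])
    gfit <- ranger::ranger(behavior ~ ., data = gdf[train0, , drop = FALSE],
                           num.trees = max(num_trees, 200),
                           importance = "impurity", min.node.size = 20,
                           max.depth = 12, seed = seed, num.threads = 1)
    gpred <- predict(gfit, data = gdf[-train0, , drop = FALSE],
                     num.threads = 1)$predictions
    global_acc <- mean(as.character(gpred) ==
                         as.character(gdf$behavior[-train0]))
    imp <- sort(gfit$variable.importance, decreasing = TRUE)
    candidates <- names(imp)[seq_len(min(top_k, length(imp)))]
    if (n_steps > length(candidates)) {
      warning("n_steps exceeds the candidate count; clipping")
      n_steps <- length(candidates)
    }
    selected <- character(0)
    path <- vector("list", n_steps)
    for (step in seq_len(n_steps)) {
      remaining <- setdiff(candidates, selected)
      train_sets <- lapply(seq_len(n_sim), function(i)
        sample_selection_training(pool, n_tracks, per_class))
      accs <- sapply(remaining, function(v) {
        vapply(seq_len(n_sim), function(i) {
          fit_eval_rf(pool, c(selected, v), train_sets[[i]], num_trees,
                      seed = seed + step * 1000L + i)
        }, 0)
      })
      accs <- matrix(accs, nrow = n_sim,
                     dimnames = list(NULL, remaining))
      med <- apply(accs, 2, stats::median)
      best <- remaining[which.max(med)]
      selected <- c(selected, best)
      path[[step]] <- data.frame(
        step = step, chosen_variable = best,
        median_accuracy = max(med),
        lo = stats::quantile(accs[, best], 0.025, names = FALSE),
        hi = stats::quantile(accs[, best], 0.975, names = FALSE))
    }
    out <- do.call(rbind, path)
    attr(out, "global_accuracy") <- global_acc
    attr(out, "global_importance") <- imp
    attr(out, "selected") <- selected
    class(out) <- c("selection_path", "data.frame")
    out
  })
}
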