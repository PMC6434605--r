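test_that("density breakpoints fall in the valley between separated \
modes", {
  set.seed(4)
  x <- c(rnorm(500, 0.5, 0.2), rnorm(500, 8, 0.3))
  thr <- hs_breakpoints(x)
  # oracle: exhaustive grid search of the KDE minimum between the modes
  d <- density(x, bw = "nrd0", n = 2048)
  grid <- d$x > 2 & d$x < 6
  oracle <- d$x[grid][which.min(d$y[grid])]
  expect_gt(thr, 2); expect_lt(thr, 6)
  expect_equal(thr, oracle, tolerance = 0.2)

  pm <- c(rep(0, 300), rep(1, 300))
  thr2 <- hs_breakpoints(pm)
  expect_gt(thr2, 0); expect_lt(thr2, 1)

  expect_error(hs_breakpoints(rep(3, 200)), "constant")
  expect_error(hs_breakpoints(rnorm(500)), "valley|unimodal")
})

test_that("min-max scaling maps range endpoints to 0 and 1", {
  x <- c(3, 7, 11)
  s <- ethogramr:::scale_to_range(x)
  expect_equal(s, c(0, 0.5, 1))
  expect_equal(ethogramr:::scale_to_range(rep(2, 5)), rep(0.5, 5))
})

test_that("cluster-to-behavior mapping depends on feature means only, \
not cluster indices", {
  segs <- data.frame(mean_pitch = c(rep(35, 30), rep(-6, 30)),
                     mean_activity = c(rep(0.05, 30), rep(0.3, 30)))
  cl_a <- rep(c(1, 2), each = 30)
  cl_b <- rep(c(2, 1), each = 30)  # permuted labels, same partition
  map_a <- ethogramr:::map_step2_clusters(cl_a, segs, species_config("murre"))
  map_b <- ethogramr:::map_step2_clusters(cl_b, segs, species_config("murre"))
  expect_equal(map_a, map_b)
  expect_equal(map_a[1], "colony")
  expect_equal(map_a[60], "swimming")
})

test_that("HS recalls every murre behavior on synthetic tracks and obeys \
the depth rule", {
  coh <- murre_cohort()
  cfg <- species_config("murre")
  eth <- classify_hs(coh$features, cfg)
  for (b in names(eth)) {
    truth <- coh$states[[b]]$states
    pred <- eth[[b]]$behavior
    for (beh in unique(truth)) {
      expect_gt(mean(pred[truth == beh] == beh), 0.95)
    }
    dive_sec <- coh$features[[b]]$depth < cfg$dive_depth_threshold
    expect_true(all(pred[dive_sec] == "diving"))
  }
})

test_that("an all-colony track yields no flying labels (WBF fallback \
path)", {
  cfg <- species_config("murre")
  par <- behavior_params("murre")
  st <- as_state_sequence(rep("colony", 3 * 3600), "c")
  tr <- simulate_accel(st, par, cfg, seed = 8)
  f <- suppressWarnings(calibrate_pitch(compute_features(tr, cfg), cfg))
  eth <- classify_hs(f, cfg)[[1]]
  expect_false("flying" %in% eth$behavior)
  expect_gt(mean(eth$behavior == "colony"), 0.95)
})

test_that("training sets follow the sampling protocol and are \
reproducible", {
  coh <- murre_cohort()
  cfg <- species_config("murre")
  eth <- classify_hs(coh$features, cfg)
  ts1 <- build_training_set(eth, coh$features, cfg, n_tracks = 4,
                            per_class = 200, seed = 3)
  ts2 <- build_training_set(eth, coh$features, cfg, n_tracks = 4,
                            per_class = 200, seed = 3)
  expect_identical(ts1, ts2)
  counts <- table(ts1$bird_id, ts1$behavior)
  expect_true(all(counts <= 200))
  # scarce classes are taken in full
  for (b in rownames(counts)) {
    avail <- table(factor(eth[[b]]$behavior, colnames(counts)))
    expect_equal(as.integer(counts[b, ]), as.integer(pmin(avail, 200)))
  }
  expect_error(build_training_set(eth, coh$features, cfg, n_tracks = 10),
               "at least 10")
})

test_that("NN and RF separate well-separated classes and honor the murre \
depth override", {
  coh <- murre_cohort()
  cfg <- species_config("murre")
  eth_hs <- classify_hs(coh$features, cfg)
  training <- build_training_set(eth_hs, coh$features, cfg, n_tracks = 4,
                                 per_class = 500, seed = 1)
  nn <- classify_nn(training, coh$features, cfg, seed = 1)
  rf <- classify_rf(training, coh$features, cfg, seed = 1)
  rf2 <- classify_rf(training, coh$features, cfg, seed = 1)
  for (b in names(coh$features)) {
    truth <- coh$states[[b]]$states
    expect_gt(mean(nn[[b]]$behavior == truth), 0.95)
    expect_gt(mean(rf[[b]]$behavior == truth), 0.95)
    expect_identical(rf[[b]]$behavior, rf2[[b]]$behavior)
    dive_sec <- coh$features[[b]]$depth < cfg$dive_depth_threshold
    expect_true(all(nn[[b]]$behavior[dive_sec] == "diving"))
    expect_true(all(rf[[b]]$behavior[dive_sec] == "diving"))
  }
  # out-of-bag error on well-separated training data is small
  expect_lt(attr(rf, "forest")$prediction.error, 0.02)
  # WBF or depth carries the most importance for murres
  imp <- sort(attr(rf, "forest")$variable.importance, decreasing = TRUE)
  expect_true(any(names(imp)[1:2] %in% c("WBF", "depth")))
})

test_that("NN copes with degenerate single-class training data", {
  cfg <- species_config("kittiwake")
  f <- data.frame(t = 0:99, pitch = 0, SD_Z = 0.1, SD_ODBA = 0.1, WBF = 0)
  attr(f, "bird_id") <- "flat"
  class(f) <- c("feature_frame", "data.frame")
  training <- data.frame(pitch = rep(0, 50), activity = 0.1, WBF = 0,
                         behavior = "colony", bird_id = "flat")
  out <- classify_nn(training, stats::setNames(list(f), "flat"), cfg,
                     seed = 1)
  expect_equal(unique(out$flat$behavior), "colony")
})

test_that("KM and EM two-step classification recover the murre ethogram", {
  coh <- murre_cohort()
  cfg <- species_config("murre")
  km <- classify_km(coh$features, cfg, seed = 1)
  em <- classify_em(coh$features, cfg, seed = 1)
  for (b in names(coh$features)) {
    truth <- coh$states[[b]]$states
    expect_gt(mean(km[[b]]$behavior == truth), 0.95)
    expect_gt(mean(em[[b]]$behavior == truth), 0.95)
  }
})

test_that("BIC selects the true component count for well-separated \
mixtures and recovers unbalanced weights", {
  set.seed(12)
  x <- c(rnorm(900, 0, 1), rnorm(100, 12, 1))
  fit <- mclust::Mclust(x, G = 1:4, modelNames = "V", verbose = FALSE)
  expect_equal(fit$G, 2)
  expect_equal(sort(fit$parameters$pro), c(0.1, 0.9), tolerance = 0.05)
})

test_that("the HMM never decodes a forbidden transition and recovers a \
noiseless two-state chain", {
  coh <- murre_cohort()
  cfg <- species_config("murre")
  hmm <- classify_hmm(coh$features, cfg)
  forbidden <- rbind(c("colony", "swimming"), c("swimming", "colony"),
                     c("colony", "diving"), c("diving", "colony"),
                     c("diving", "flying"), c("flying", "diving"))
  for (b in names(hmm)) {
    r <- rle(hmm[[b]]$behavior)
    pairs <- cbind(r$values[-length(r$values)], r$values[-1])
    for (i in seq_len(nrow(forbidden))) {
      expect_false(any(pairs[, 1] == forbidden[i, 1] &
                         pairs[, 2] == forbidden[i, 2]))
    }
    expect_gt(mean(hmm[[b]]$behavior == coh$states[[b]]$states), 0.95)
  }

  # noiseless limit: two states with non-overlapping emissions decode
  # exactly through Viterbi
  logB <- matrix(log(1e-6), 2, 20)
  truth <- rep(c(1, 2, 1), c(7, 6, 7))
  logB[cbind(truth, 1:20)] <- log(1)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  path <- ethogramr:::hmm_viterbi(logB, A, c(0.5, 0.5))
  expect_equal(path, truth)
})

test_that("HMM emission fitting recovers the generating parameters on \
binned murre data", {
  coh <- murre_cohort()
  cfg <- species_config("murre")
  # fit on one bird and compare the fitted flying WBF location with the
  # generator flight frequency
  f <- coh$features[[1]]
  spec <- hmm_spec("murre")
  obs <- ethogramr:::bin_features(f, cfg, spec$bin)
  par <- ethogramr:::hmm_start_par(spec)
  A <- ethogramr:::hmm_start_transition(spec)
  delta <- rep(0.25, 4)
  for (i in 1:30) {
    logB <- ethogramr:::hmm_log_emissions(obs, par, spec, cfg)
    fb <- ethogramr:::hmm_forward_backward(logB, A, delta)
    par <- ethogramr:::hmm_m_step(obs, fb$gamma, spec, par)
    rs <- rowSums(fb$xi_sum)
    A[rs > 0, ] <- (fb$xi_sum / ifelse(rs > 0, rs, 1))[rs > 0, ]
    delta <- pmax(fb$gamma[, 1], 1e-12); delta <- delta / sum(delta)
  }
  k_fly <- match("flying", spec$states)
  expect_equal(exp(par$wbf_meanlog[k_fly]), 8.1, tolerance = 0.8)
  k_col <- match("colony", spec$states)
  expect_equal(par$pitch_mean[k_col], 37.6, tolerance = 4)
})
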