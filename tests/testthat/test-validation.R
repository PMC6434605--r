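test_that("murre GPS rules label fixes with the stated precedence", {
  cfg <- species_config("murre")
  gps <- data.frame(t = seq(0, 240, by = 60),
                    x = c(100, 100, 1000, 5000, 5060),
                    y = 0)
  # speeds: 0 (first copies second), 0, 15, 66.7 (error), 1
  depth <- c(0, 0, 0, 0, -12)
  class(gps) <- c("gps_track", "data.frame")
  lab <- label_gps_murre(gps, depth, nest = c(0, 0), config = cfg)
  expect_equal(lab$behavior[1], "colony")      # 100 m, slow
  expect_equal(lab$behavior[3], "flying")      # 15 m/s
  expect_equal(lab$behavior[4], "excluded")    # 66 m/s: speed error
  expect_equal(lab$exclusion_reason[4], "speed_error")
  expect_equal(lab$behavior[5], "diving")      # depth rule beats speed

  swim <- data.frame(t = c(0, 60), x = c(4000, 4030), y = 0)
  class(swim) <- c("gps_track", "data.frame")
  sl <- label_gps_murre(swim, c(0, 0), nest = c(0, 0), config = cfg)
  expect_equal(sl$behavior[2], "swimming")     # 0.5 m/s offshore

  expect_error(label_gps_murre(gps, depth, nest = NULL, config = cfg),
               "nest")
})

test_that("kittiwake GPS rules exclude the island, gaps, and speed \
errors", {
  cfg <- species_config("kittiwake")
  gps <- data.frame(t = c(0, 30, 60, 800, 830),
                    x = c(300, 620, 650, 700, 820),
                    y = 0)
  class(gps) <- c("gps_track", "data.frame")
  lab <- label_gps_kittiwake(gps, island = c(0, 0), config = cfg)
  expect_equal(lab$behavior[1], "excluded")   # 300 m from the island
  expect_equal(lab$exclusion_reason[1], "near_island")
  expect_equal(lab$behavior[2], "flying")     # 10.7 m/s offshore
  expect_equal(lab$behavior[3], "swimming")   # 1 m/s offshore
  expect_equal(lab$behavior[4], "excluded")   # 12.3 min gap
  expect_equal(lab$exclusion_reason[4], "gap")
  expect_equal(lab$behavior[5], "flying")     # 4 m/s

  fast <- data.frame(t = c(0, 30), x = c(2000, 2750), y = 0)
  class(fast) <- c("gps_track", "data.frame")
  fl <- label_gps_kittiwake(fast, island = c(0, 0), config = cfg)
  expect_equal(unique(fl$exclusion_reason), "speed_error")  # 25 m/s
})

test_that("transition windows exclude fixes around colony/flying/swimming \
changes but not dive-swim changes", {
  cfg <- species_config("murre")
  lab <- data.frame(
    t = seq(0, 600, by = 60),
    behavior = c("colony", "colony", "colony", "flying", "flying",
                 "swimming", "diving", "swimming", "swimming", "swimming",
                 "swimming"),
    exclusion_reason = "none")
  out <- mark_transitions(lab, cfg$transition_window)
  # colony->flying change between 120 and 180: both bracketing fixes drop
  expect_equal(out$behavior[3], "excluded")
  expect_equal(out$behavior[4], "excluded")
  expect_equal(out$exclusion_reason[3], "transition")
  # flying->swimming change between 240 and 300
  expect_equal(out$behavior[5], "excluded")
  expect_equal(out$behavior[6], "excluded")
  # swim->dive->swim is exempt
  expect_equal(out$behavior[7], "diving")
  expect_equal(out$behavior[8], "swimming")

  const <- data.frame(t = seq(0, 300, 60), behavior = "swimming",
                      exclusion_reason = "none")
  expect_equal(mark_transitions(const, 60)$behavior, const$behavior)
})

test_that("confusion summaries reproduce the balanced-accuracy formula", {
  cfg <- species_config("murre")
  eth <- ethogramr:::ethogram_df(0:239, rep("colony", 240), "b", "HS")
  ref <- data.frame(t = seq(0, 239, by = 60), behavior = "colony",
                    exclusion_reason = "none")
  cs <- score_ethogram(eth, ref, cfg)
  expect_equal(cs$overall_accuracy, 1)
  expect_true(all(cs$balanced_accuracy == 1))

  # binary worked example: TP=8 FN=2 TN=9 FP=1 -> balanced 0.85
  ref2 <- data.frame(t = 0:19,
                     behavior = rep(c("flying", "swimming"), c(10, 10)),
                     exclusion_reason = "none")
  pred2 <- c(rep("flying", 8), rep("swimming", 2),
             rep("swimming", 9), "flying")
  eth2 <- ethogramr:::ethogram_df(0:19, pred2, "b", "HS")
  cs2 <- score_ethogram(eth2, ref2, cfg)
  expect_equal(unname(cs2$balanced_accuracy["flying"]), 0.85)
  expect_equal(cs2$overall_accuracy, 17 / 20)
  expect_equal(cs2$n_used + cs2$n_excluded, 20)

  # random labels over four balanced classes score about chance
  set.seed(5)
  classes <- c("colony", "flying", "swimming", "diving")
  refr <- data.frame(t = 0:3999,
                     behavior = sample(classes, 4000, replace = TRUE),
                     exclusion_reason = "none")
  ethr <- ethogramr:::ethogram_df(0:3999,
                                  sample(classes, 4000, replace = TRUE),
                                  "b", "HS")
  csr <- score_ethogram(ethr, refr, cfg)
  expect_equal(csr$overall_accuracy, 0.25, tolerance = 0.03)

  # relabelling both inputs together leaves the scores unchanged
  swap <- function(x) ifelse(x == "flying", "swimming",
                             ifelse(x == "swimming", "flying", x))
  cs_swap <- score_ethogram(
    ethogramr:::ethogram_df(0:19, swap(pred2), "b", "HS"),
    transform(ref2, behavior = swap(behavior)), cfg)
  expect_equal(cs_swap$overall_accuracy, cs2$overall_accuracy)
})

test_that("confusion summary agrees with an independent implementation", {
  skip_if_not_installed("caret")
  cfg <- species_config("murre")
  set.seed(11)
  classes <- c("colony", "flying", "swimming")
  ref <- sample(classes, 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.8, ref, sample(classes, 500, replace = TRUE))
  eth <- ethogramr:::ethogram_df(0:499, pred, "b", "HS")
  labs <- data.frame(t = 0:499, behavior = ref, exclusion_reason = "none")
  cs <- score_ethogram(eth, labs, cfg)
  cm <- caret::confusionMatrix(factor(pred, classes), factor(ref, classes))
  expect_equal(cs$overall_accuracy, unname(cm$overall["Accuracy"]))
  expect_equal(unname(cs$balanced_accuracy),
               unname(cm$byClass[, "Balanced Accuracy"]),
               tolerance = 1e-12)
})

test_that("daily energy expenditure reproduces the species coefficients \
and is linear", {
  m <- species_config("murre")
  k <- species_config("kittiwake")
  expect_equal(daily_energy(c(colony = 24), m), 768.0)
  expect_equal(daily_energy(c(colony = 12, flying = 2, swimming = 8,
                              diving = 2), m), 2450.4)
  expect_equal(daily_energy(c(colony = 24), k), 504.0)
  a <- c(colony = 3, flying = 1, swimming = 2, diving = 0.5)
  b <- c(colony = 5, flying = 0.2, swimming = 1, diving = 0)
  expect_equal(daily_energy(a, m) + daily_energy(b, m),
               daily_energy(a + b, m))
  expect_error(daily_energy(c(colony = 20, diving = 4), k), "diving")
})

test_that("activity budgets partition labelled time into behavior hours", {
  cfg <- species_config("murre")
  coh <- murre_cohort()
  eth <- classify_hs(coh$features, cfg)[[1]]
  bud <- activity_budget(eth, cfg)
  expect_equal(sum(bud[cfg$behaviors]), nrow(eth) / 3600, tolerance = 1e-6)
  expect_true(all(as.matrix(bud[cfg$behaviors]) >= 0))
  dee <- daily_energy(bud, cfg)
  expect_true(all(dee > 0))
})

test_that("end-to-end synthetic benchmark keeps every method accurate \
and accounts for every fix", {
  coh <- murre_cohort()
  eth <- run_classifiers(coh, seed = 1, n_tracks = 4, per_class = 500)
  scores <- score_cohort(eth, coh)
  expect_setequal(unique(scores$method),
                  c("HS", "KM", "EM", "NN", "RF", "HMM"))
  expect_gt(mean(scores$overall_accuracy), 0.95)
  for (b in names(coh$gps_labels)) {
    lab <- coh$gps_labels[[b]]
    n_total <- nrow(lab)
    expect_equal(sum(lab$behavior == "excluded") +
                   sum(lab$behavior != "excluded"), n_total)
  }
})
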