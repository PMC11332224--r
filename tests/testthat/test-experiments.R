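test_that("normalization achieves exact z-scores per scope", {
  d <- tibble::tibble(
    baby_id = rep(c("A", "B"), each = 2),
    pitch_median = c(400, 420, 500, 540),
    entropy = c(0.3, 0.4, 0.5, 0.8)
  )
  w <- normalize_features(d, "within_baby")
  # two cries per baby: sign-symmetric pair at +/- 1/sqrt(2)
  expect_equal(sort(w$pitch_median[1:2]), c(-1, 1) / sqrt(2))
  # within-baby scope removes between-baby offsets
  expect_equal(mean(w$pitch_median[d$baby_id == "A"]), 0)
  expect_equal(mean(w$pitch_median[d$baby_id == "B"]), 0)

  g <- normalize_features(d, "global")
  expect_equal(mean(g$pitch_median), 0, tolerance = 1e-12)
  expect_equal(sd(g$pitch_median), 1, tolerance = 1e-12)
  # global scope preserves between-baby separation
  expect_gt(abs(mean(g$pitch_median[d$baby_id == "B"]) -
                  mean(g$pitch_median[d$baby_id == "A"])), 0.5)

  d$flat <- 1
  expect_warning(normalize_features(d, "global", features = "flat"),
                 "zero-variance")
})

test_that("grouped splits are session-disjoint and class-balanced", {
  d <- sim_features(n_babies = 3, ages = c(0.5, 1.5), sessions_per_age = 2,
                    sequences_per_session = 4, cries_per_sequence = 6,
                    cause_probs = c(hunger = 0.8, discomfort = 0.15,
                                    isolation = 0.05), seed = 61)
  for (s in 1:20) {
    sp <- grouped_split(d, stratify_by = "cause", seed = s)
    expect_length(intersect(sp$train$session_id, sp$test$session_id), 0)
    for (side in sp) {
      tab <- table(side$cause)
      expect_lte(max(tab) - min(tab), 1)
    }
  }
  # a class living in a single session cannot be split
  d1 <- d
  d1$cause[d1$session_id == d1$session_id[1]] <- "colic_like"
  d1 <- d1[d1$cause != "colic_like" | d1$session_id == d1$session_id[1], ]
  one <- d1[d1$cause == "colic_like", ]
  rest <- d1[d1$cause != "colic_like", ]
  dd <- rbind(one, rest)
  expect_error(grouped_split(dd, stratify_by = "cause", seed = 1), "colic_like")
})

test_that("odds ratio to chance follows the odds formula", {
  expect_equal(odds_ratio_to_chance(0.40, 4), 2)
  expect_equal(odds_ratio_to_chance(1 / 3, 3), 1)
  expect_equal(odds_ratio_to_chance(0.36, 3), 1.125)
  expect_equal(round(odds_ratio_to_chance(0.36, 3), 1), 1.1)
  # monotone in accuracy; identity at chance for every K
  for (K in 2:6) {
    expect_equal(odds_ratio_to_chance(1 / K, K), 1)
    accs <- seq(0.05, 0.95, by = 0.1)
    expect_true(all(diff(odds_ratio_to_chance(accs, K)) > 0))
  }
  expect_equal(odds_ratio_to_chance(1, 4), Inf)
  expect_equal(odds_ratio_to_chance(0, 4), 0)
})

test_that("shuffled labels calibrate the experiment to chance", {
  d <- sim_features(n_babies = 6, sessions_per_age = 2,
                    sequences_per_session = 3, cries_per_sequence = 6,
                    seed = 8)
  d$shuffled <- with_seed(2, sample(d$cause))
  ex <- run_experiment(d, "shuffled", n_runs = 15, num_trees = 200, seed = 4)
  expect_gt(ex$odds_ratio, 0.8)
  expect_lt(ex$odds_ratio, 1.25)
})

test_that("experiments are reproducible and surface feature importance", {
  d <- sim_features(n_babies = 5, sessions_per_age = 2,
                    sequences_per_session = 2, cries_per_sequence = 5,
                    seed = 19)
  dn <- normalize_features(d, "global")
  a <- run_experiment(dn, "baby_id", n_runs = 5, num_trees = 100, seed = 9)
  b <- run_experiment(dn, "baby_id", n_runs = 5, num_trees = 100, seed = 9)
  expect_identical(a$accuracies, b$accuracies)
  expect_length(a$importance, 10)
  expect_true(all(sort(names(a$importance)) == sort(feature_names())))
  expect_equal(a$chance, 1 / 5)
  expect_output(print(a), "odds ratio to chance")
  d$entropy[1] <- NA
  expect_error(run_experiment(d, "baby_id", n_runs = 2, seed = 1), "non-finite")
})

test_that("random forest behaviour is consistent with an independent implementation", {
  skip_if_not_installed("randomForest")
  d <- sim_features(n_babies = 4, sessions_per_age = 2,
                    sequences_per_session = 2, cries_per_sequence = 6,
                    seed = 23)
  dn <- normalize_features(d, "global")
  sp <- grouped_split(dn, stratify_by = "baby_id", seed = 3)
  fo <- as.formula(paste("factor(baby_id) ~", paste(feature_names(), collapse = "+")))
  rf <- randomForest::randomForest(fo, data = sp$train, ntree = 500)
  acc_ref <- mean(as.character(predict(rf, sp$test)) == sp$test$baby_id)
  ex <- run_experiment(dn, "baby_id", n_runs = 8, num_trees = 500, seed = 3)
  # same data, same design: the two implementations agree on the broad level
  expect_lt(abs(ex$median_accuracy - acc_ref), 0.2)
})

test_that("per-baby cause models detect a private cause code only where injected", {
  base <- sim_features(n_babies = 5, sessions_per_age = 2,
                       sequences_per_session = 4, cries_per_sequence = 6,
                       seed = 37)
  dn <- normalize_features(base, "within_baby")
  # inject a strong cause code for baby B01 only
  focal <- dn$baby_id == "B01"
  shift <- (dn$cause == "hunger") - (dn$cause == "isolation")
  dn$pitch_median[focal] <- dn$pitch_median[focal] + 2.5 * shift[focal]
  dn$entropy[focal] <- dn$entropy[focal] - 2.5 * shift[focal]
  pb <- per_baby_cause_models(dn, n_runs = 8, num_trees = 150, seed = 5)
  expect_true("B01" %in% pb$baby_id)
  b01 <- pb[pb$baby_id == "B01", ]
  others <- pb[pb$baby_id != "B01", ]
  expect_gt(b01$same_or, 1.5)
  expect_lt(median(others$same_or), 1.5)
  expect_lt(median(pb$other_or), 1.3)
})

test_that("context distance matrices have the right geometry and null behaviour", {
  d <- sim_features(n_babies = 8, sessions_per_age = 2,
                    sequences_per_session = 4, cries_per_sequence = 5,
                    seed = 21)
  cd <- context_distances(d, n_perm = 99, seed = 1)
  expect_equal(cd$n_pairs, choose(length(cd$babies), 2))
  for (m in cd$matrices) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, nrow(m)))
  }
  # null cohort: cause-specific matrices are weakly correlated at most
  expect_lt(max(abs(cd$correlations$r)), 0.5)

  # identical baby-varying effects in every cause correlate matrices ~ 1
  # (global scope keeps the shared signature in the summaries)
  cdg <- context_distances(d, scope = "global", n_perm = 19, seed = 1)
  expect_gt(min(cdg$correlations$r), 0.7)
})

test_that("age-slope estimator is exact on noise-free data", {
  d <- tibble::tibble(
    baby_id = "B1", sex = "M",
    age_months = rep(c(0.5, 1.5, 2.5, 3.5), each = 3),
    pitch_median = 400 + 10 * rep(c(0.5, 1.5, 2.5, 3.5), each = 3) +
      rep(c(-1, 0, 1), 4)
  )
  est <- suppressMessages(
    estimate_age_sex_effects(d, predictors = "pitch_median", n_boot = 50, seed = 1))
  # slope 10 Hz/month over the OLS residual SD: SSR = 8 on 10 df
  expect_equal(est$age_slope, 10 / sqrt(8 / 10), tolerance = 1e-6)
})

test_that("a null sex difference yields a CI covering zero", {
  d <- sim_features(n_babies = 10, sessions_per_age = 1,
                    sequences_per_session = 3, cries_per_sequence = 5,
                    seed = 55)
  est <- estimate_age_sex_effects(d, n_boot = 150, seed = 2)
  row <- est[est$feature == "shimmer_pct", ]
  expect_true(row$sex_lo <= 0 && 0 <= row$sex_hi)
  expect_true(all(est$slope_lo <= est$age_slope & est$age_slope <= est$slope_hi))
})
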