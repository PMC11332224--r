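test_that("cohort simulation is reproducible and nested", {
  cfg <- cohort_config(n_babies = 4, sessions_per_age = 1,
                       sequences_per_session = 2, cries_per_sequence = 3,
                       seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$features, b$features)

  # nesting: sequence -> one session; session -> one (baby, age)
  r <- a$records
  expect_true(all(vapply(split(r$session_id, r$sequence_id),
                         function(s) length(unique(s)) == 1, logical(1))))
  expect_true(all(vapply(split(paste(r$baby_id, r$age_months), r$session_id),
                         function(s) length(unique(s)) == 1, logical(1))))
})

test_that("per-baby seed streams: adding babies never reshuffles existing ones", {
  small <- simulate_cohort(cohort_config(n_babies = 3, sessions_per_age = 1,
                                         sequences_per_session = 2,
                                         cries_per_sequence = 2, seed = 5))
  big <- simulate_cohort(cohort_config(n_babies = 6, sessions_per_age = 1,
                                       sequences_per_session = 2,
                                       cries_per_sequence = 2, seed = 5))
  sm <- small$features[, -1]  # cry ids renumber; values must match
  bg <- big$features[big$records$baby_id %in% unique(small$records$baby_id), -1]
  expect_equal(as.data.frame(sm), as.data.frame(bg))
})

test_that("the longitudinal design arithmetic matches the corpus layout", {
  # 24 babies x 4 ages, 21 sessions missing in expectation -> 75 sessions
  cfg <- cohort_config(n_babies = 24, missing_session_rate = 21 / 96, seed = 2)
  expect_equal(expected_sessions(cfg), 75)
  # realized missingness is close to its expectation
  sim <- simulate_cohort(cfg)
  n_sessions <- length(unique(sim$records$session_id))
  expect_gt(n_sessions, 60)
  expect_lt(n_sessions, 90)
})

test_that("exchangeable babies: no signature means no between-baby excess variance", {
  d <- sim_features(n_babies = 8, sessions_per_age = 1,
                    sequences_per_session = 3, cries_per_sequence = 6,
                    baby_signature_sd = 0, slope_sd = 0, age_slope = 0,
                    session_effect_sd = 0, seed = 77)
  f <- aov(pitch_median ~ baby_id, data = d)
  p <- summary(f)[[1]][["Pr(>F)"]][1]
  expect_gt(p, 0.01)
})

test_that("with zero cause effect, cause labels are independent of acoustics", {
  d <- sim_features(n_babies = 12, sessions_per_age = 2,
                    sequences_per_session = 3, cries_per_sequence = 7,
                    seed = 42)
  expect_gt(nrow(d), 1900)
  dn <- normalize_features(d, "within_baby")
  for (f in c("pitch_median", "entropy", "hnr_db")) {
    for (cs in c("hunger", "isolation")) {
      r <- cor(dn[[f]], as.numeric(dn$cause == cs))
      expect_lt(abs(r), 0.05, label = paste(f, cs))
    }
  }
})

test_that("latent values map into valid physical ranges", {
  d <- sim_features(n_babies = 6, sessions_per_age = 1,
                    sequences_per_session = 2, cries_per_sequence = 4,
                    baby_signature_sd = 3, residual_sd = 3, seed = 13)
  m <- latent_maps()
  for (f in feature_names()) {
    lo <- m$lo[m$feature == f]; hi <- m$hi[m$feature == f]
    expect_true(all(d[[f]] >= lo & d[[f]] <= hi), label = f)
  }
})

test_that("the audio tier writes a readable corpus matching its metadata", {
  cfg <- cohort_config(n_babies = 2, ages = c(0.5, 1.5), sessions_per_age = 1,
                       sequences_per_session = 1, cries_per_sequence = 2,
                       sample_rate = 22050, seed = 3)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, audio = TRUE, out_dir = dir)
  expect_true(all(file.exists(sim$records$wav_path)))
  rc <- read_corpus(file.path(dir, "metadata.csv"))
  expect_equal(nrow(rc), nrow(sim$records))
  expect_equal(rc$cry_id, sim$records$cry_id)
  # identical config reproduces identical audio checksums
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_cohort(cfg, audio = TRUE, out_dir = dir2)
  sum1 <- unname(tools::md5sum(sort(sim$records$wav_path)))
  sum2 <- unname(tools::md5sum(sort(sim2$records$wav_path)))
  expect_identical(sum1, sum2)
})
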