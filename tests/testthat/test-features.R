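sr <- 44100

test_that("Wiener entropy matches its closed-form values", {
  expect_equal(wiener_entropy(rep(3, 64)), 1)
  expect_equal(wiener_entropy(c(1, 4)), 0.8)
  # a single nonzero bin among N is at the pure-tone limit (near 0)
  expect_lt(wiener_entropy(c(1, numeric(99))), 1e-6)
  expect_lt(wiener_entropy(c(1, numeric(999))), 1e-6)
  expect_true(is.na(wiener_entropy(numeric(8))))
  expect_error(wiener_entropy(c(1, -1)), "non-negative")
})

test_that("HNR follows the autocorrelation formula with clipping", {
  expect_equal(hnr_from_acf(0.5), 0)
  expect_equal(hnr_from_acf(0.99), 10 * log10(0.99 / 0.01))
  expect_equal(round(hnr_from_acf(0.99), 2), 19.96)
  expect_warning(h <- hnr_from_acf(1.0), "clipping")
  expect_equal(h, 40)
  expect_equal(hnr_from_acf(1e-9), -10)    # clipped at the floor
})

test_that("jitter and shimmer reproduce hand-computed local values", {
  expect_equal(jitter_local(c(2.0, 2.1, 2.0)), (0.1 + 0.1) / 2 / mean(c(2, 2.1, 2)) * 100)
  expect_equal(round(jitter_local(c(2.0, 2.1, 2.0)), 3), 4.918)
  expect_equal(shimmer_local(c(1.0, 1.1, 1.0)), 0.1 * 3 / 3.1 * 100)
  expect_equal(jitter_local(rep(3.3, 10)), 0)
  expect_true(is.na(jitter_local(c(2.0, 2.1))))
})

test_that("spectral centroid matches simple spectra", {
  freqs <- seq(0, 8000, by = 10)
  mag <- numeric(length(freqs)); mag[freqs == 440] <- 1
  expect_equal(spectral_centroid(mag, freqs), 440)
  mag2 <- numeric(length(freqs)); mag2[freqs %in% c(300, 500)] <- 1
  expect_equal(spectral_centroid(mag2, freqs), 400)
  # content above fmax is ignored
  mag3 <- mag2; mag3[length(mag3)] <- 100
  expect_equal(spectral_centroid(mag3, freqs, fmax = 7000), 400)
})

test_that("frame analysis classifies tones, noise, and silence correctly", {
  t <- seq(0, 0.5, by = 1 / sr)
  tone <- sin(2 * pi * 440 * t)
  fa <- frame_analysis(tone, sr)
  expect_equal(mean(fa$voiced), 1)
  expect_lt(abs(median(fa$f0_hz) - 440), 1)
  expect_lt(median(fa$entropy, na.rm = TRUE), 0.1)

  noise <- with_seed(9, rnorm(length(t)))
  fn <- frame_analysis(noise, sr)
  expect_lt(mean(fn$voiced), 0.1)
  expect_gt(median(fn$entropy, na.rm = TRUE), 0.6)

  half <- c(tone, numeric(length(t)))
  fh <- frame_analysis(half, sr)
  expect_lt(abs(mean(fh$voiced) - 0.5), 0.08)

  expect_error(frame_analysis(tone, sr, frame_ms = 5, f0_range = c(150, 1200)),
               "frame too short")
  expect_error(frame_analysis(tone, sr, f0_range = c(10, 1200)), "f0_range")
})

test_that("roughness responds to amplitude modulation in the 30-150 Hz band", {
  t <- seq(0, 0.5, by = 1 / sr)
  carrier <- sin(2 * pi * 440 * t)
  expect_lt(roughness(carrier, sr), 5)
  am70 <- carrier * (1 + 1.0 * sin(2 * pi * 70 * t)) / 2
  expect_gt(roughness(am70, sr), 50)
  am10 <- carrier * (1 + 1.0 * sin(2 * pi * 10 * t)) / 2
  expect_lt(roughness(am10, sr), 10)
  expect_true(is.na(roughness(carrier[1:2000], sr)))   # below 200 ms
})

test_that("injected jitter and shimmer are recovered closed-loop", {
  pj <- cry_params(jitter_pct = 3, shimmer_pct = 0, am_depth = 0,
                   voiced_fraction = 1, hnr_db = 40, f0_iqr = 30)
  prj <- profile_cry(synthesize_cry(pj, 2), sr)$profile
  expect_lt(abs(prj$jitter_pct - 3), 0.5)

  ps <- cry_params(jitter_pct = 0, shimmer_pct = 5, am_depth = 0,
                   voiced_fraction = 1, hnr_db = 40, f0_iqr = 30)
  prs <- profile_cry(synthesize_cry(ps, 3), sr)$profile
  expect_lt(abs(prs$shimmer_pct - 5), 1)
})

test_that("descriptors are invariant to overall amplitude scaling", {
  x <- synthesize_cry(cry_params(duration_s = 0.5, voiced_fraction = 0.9), 6)
  a <- profile_cry(x, sr)$profile
  b <- profile_cry(0.4 * x, sr)$profile
  for (f in setdiff(feature_names(), "duration_s")) {
    expect_equal(a[[f]], b[[f]], tolerance = 1e-6, label = f)
  }
})

test_that("descriptors agree across 44.1 and 22.05 kHz within 5%", {
  mk <- function(s) cry_params(f0_median = 450, f0_iqr = 40, jitter_pct = 2,
                               shimmer_pct = 4, am_depth = 0.2, hnr_db = 20,
                               voiced_fraction = 0.9, duration_s = 0.7,
                               sample_rate = s)
  a <- profile_cry(synthesize_cry(mk(44100), 8), 44100)$profile
  b <- profile_cry(synthesize_cry(mk(22050), 8), 22050)$profile
  for (f in c("pitch_median", "voicing", "spectral_centroid", "hnr_db")) {
    expect_lt(abs(a[[f]] - b[[f]]) / abs(a[[f]]), 0.05, label = f)
  }
})

test_that("a fully unvoiced cry is flagged rather than profiled", {
  noise <- with_seed(4, rnorm(0.4 * sr)) * 0.3
  pr <- profile_cry(noise, sr)$profile
  expect_equal(pr$voicing, 0)
  expect_true(is.na(pr$pitch_median))
  flt <- filter_cries(pr)
  expect_equal(nrow(flt$kept), 0)
})
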