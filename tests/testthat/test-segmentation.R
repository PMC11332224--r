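sr <- 22050
tone <- function(dur, f = 500) sin(2 * pi * f * seq(0, dur, by = 1 / sr))[-1]
sil <- function(dur) numeric(round(dur * sr))

test_that("segmentation finds cries and respects duration and gap rules", {
  x <- c(sil(0.1), tone(0.3), sil(0.2), tone(0.4), sil(0.1))
  iv <- segment_sequence(x, sr)
  expect_equal(nrow(iv), 2)
  hop <- 0.01
  expect_lt(abs(iv$start_s[1] - 0.1), 2 * hop)
  expect_lt(abs(iv$end_s[1] - 0.4), 2 * hop)
  expect_lt(abs(iv$start_s[2] - 0.6), 2 * hop)
  expect_lt(abs(iv$end_s[2] - 1.0), 2 * hop)

  # 50 ms gap is bridged into one cry
  y <- c(sil(0.1), tone(0.2), sil(0.05), tone(0.2), sil(0.1))
  expect_equal(nrow(segment_sequence(y, sr)), 1)

  # 30 ms blip alone is below the duration floor
  z <- c(sil(0.2), tone(0.03), sil(0.2))
  expect_equal(nrow(segment_sequence(z, sr)), 0)

  # all-silent input returns an empty table, not an error
  expect_equal(nrow(segment_sequence(sil(0.5), sr)), 0)
})

test_that("intervals are sorted, disjoint, and segmentation is idempotent", {
  x <- c(sil(0.15), tone(0.35), sil(0.3), tone(0.25), sil(0.3), tone(0.5), sil(0.1))
  iv <- segment_sequence(x, sr)
  expect_equal(nrow(iv), 3)
  expect_true(all(diff(iv$start_s) > 0))
  expect_true(all(iv$end_s[-nrow(iv)] <= iv$start_s[-1]))
  # re-segmenting each cut yields exactly one interval per cut
  for (i in seq_len(nrow(iv))) {
    a <- round(iv$start_s[i] * sr) + 1
    b <- round(iv$end_s[i] * sr)
    expect_equal(nrow(segment_sequence(x[a:b], sr)), 1)
  }
})

test_that("the four-condition filter applies the printed inequalities strictly", {
  battery <- tibble::tibble(
    voicing      = c(0.5, 0.5,   0.19, 0.20, 0.5,  0.5, 0.5,  0.5),
    pitch_median = c(400, 150.0, 400,  400,  400,  400, 400,  400),
    duration_s   = c(0.5, 0.5,   0.5,  0.5,  0.250, 0.5, 0.5, 0.251),
    entropy      = c(0.3, 0.3,   0.3,  0.3,  0.3,  0.6, 0.59, 0.3),
    id = letters[1:8]
  )
  out <- filter_cries(battery)
  expect_setequal(out$kept$id, c("a", "d", "g", "h"))
  rej <- setNames(out$rejected$reject_reasons, out$rejected$id)
  expect_equal(unname(rej["b"]), "pitch")      # boundary 150.0 is strict
  expect_equal(unname(rej["c"]), "voicing")
  expect_equal(unname(rej["e"]), "duration")   # boundary 250 ms is strict
  expect_equal(unname(rej["f"]), "entropy")    # boundary 0.6 is strict
  # partition invariant: nothing lost, nothing duplicated
  expect_equal(sort(c(out$kept$id, out$rejected$id)), battery$id)
})

test_that("missing descriptors reject as unmeasurable and multiple failures are listed", {
  cand <- tibble::tibble(
    voicing = c(NA, 0.1), pitch_median = c(400, 100),
    duration_s = c(0.5, 0.2), entropy = c(0.3, 0.7))
  out <- filter_cries(cand)
  expect_equal(nrow(out$kept), 0)
  expect_equal(out$rejected$reject_reasons[1], "unmeasurable")
  expect_setequal(strsplit(out$rejected$reject_reasons[2], ",")[[1]],
                  c("voicing", "pitch", "duration", "entropy"))
})

test_that("unvoiced noise bursts rarely pass the cry filter", {
  # injected non-cry sounds: broadband noise bursts, plausible durations
  profiles <- lapply(1:20, function(i) {
    burst <- with_seed(100 + i, rnorm(round(0.4 * sr))) * 0.5
    profile_cry(burst, sr)$profile
  })
  out <- filter_cries(dplyr::bind_rows(profiles))
  expect_lte(nrow(out$kept) / 20, 0.05)
})

test_that("rare-cause exclusion keeps the three major causes and tallies removals", {
  rec <- tibble::tibble(cause = c(rep("hunger", 10), rep("pain", 2), "unknown"))
  out <- exclude_rare_causes(rec)
  expect_equal(nrow(out$records), 10)
  expect_equal(out$tally[["pain"]], 2L)
  expect_equal(out$tally[["unknown"]], 1L)

  allunk <- tibble::tibble(cause = rep("unknown", 5))
  out2 <- exclude_rare_causes(allunk)
  expect_equal(nrow(out2$records), 0)
  expect_equal(sum(out2$tally), 5L)

  clean <- tibble::tibble(cause = c("hunger", "discomfort", "isolation"))
  out3 <- exclude_rare_causes(clean)
  expect_equal(out3$records, clean)
})
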