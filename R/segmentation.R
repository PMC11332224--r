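#' Segmentation settings
#'
#' Controls the amplitude-envelope segmenter: cries must last at least
#' `min_cry_ms` and be separated from neighbours by at least `min_gap_ms`
#' (shorter gaps are bridged). The envelope is the RMS over
#' `envelope_window_ms` windows at half-window hop, median-smoothed over 3
#' points; the silence threshold is `threshold_rel` times the sequence's
#' 95th-percentile envelope.
#'
#' @param min_cry_ms Minimum cry duration (ms, default 50).
#' @param min_gap_ms Minimum between-cry gap (ms, default 100).
#' @param envelope_window_ms RMS window (ms, default 20).
#' @param threshold_rel Threshold as a fraction of the 95th-percentile
#'   envelope (default 0.05).
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(min_cry_ms = 50, min_gap_ms = 100,
                         envelope_window_ms = 20, threshold_rel = 0.05) {
  stopifnot(min_cry_ms > 0, min_gap_ms > 0, envelope_window_ms > 0,
            threshold_rel > 0, threshold_rel < 1)
  structure(list(min_cry_ms = min_cry_ms, min_gap_ms = min_gap_ms,
                 envelope_window_ms = envelope_window_ms,
                 threshold_rel = threshold_rel),
            class = "segment_spec")
}

#' Segment a crying bout into individual cries
#'
#' Finds above-threshold runs of the smoothed RMS envelope, bridges gaps
#' shorter than `min_gap_ms` into one cry, and drops runs shorter than
#' `min_cry_ms`. Intervals are half-open `[start, end)` in seconds from file
#' start, disjoint and sorted.
#'
#' @param wave Numeric waveform (non-empty).
#' @param sample_rate Sampling rate (Hz).
#' @param spec A [segment_spec()].
#' @return A tibble with columns `start_s`, `end_s` (possibly zero rows for
#'   all-silent input).
#' @export
segment_sequence <- function(wave, sample_rate, spec = segment_spec()) {
  stopifnot(length(wave) > 0, sample_rate > 0, inherits(spec, "segment_spec"))
  win <- max(2L, round(spec$envelope_window_ms / 1000 * sample_rate))
  hop <- max(1L, round(win / 2))
  starts <- seq(1L, max(1L, length(wave) - win + 1L), by = hop)
  env <- vapply(starts, function(s) {
    sqrt(mean(wave[s:min(length(wave), s + win - 1)]^2))
  }, numeric(1))
  env <- stats::runmed(env, 3)
  ref <- stats::quantile(env, 0.95, names = FALSE)
  if (ref <= 0) return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  above <- env >= spec$threshold_rel * ref
  if (!any(above)) return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))

  hop_s <- hop / sample_rate
  t_env <- (starts - 1) / sample_rate            # window start times
  r <- rle(above)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1
  iv <- cbind(t_env[begs[r$values]],
              t_env[ends[r$values]] + win / sample_rate)

  # bridge gaps < min_gap_ms
  min_gap <- spec$min_gap_ms / 1000
  if (nrow(iv) > 1) {
    merged <- iv[1, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] - merged[nrow(merged), 2] < min_gap) {
        merged[nrow(merged), 2] <- iv[i, 2]
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
    iv <- merged
  }
  iv[, 2] <- pmin(iv[, 2], length(wave) / sample_rate)

  # the coarse 20 ms windows smear boundaries by up to a window; refine each
  # boundary on a 5 ms / 1 ms RMS envelope so short blips are not inflated
  # past the duration floor
  fwin <- max(2L, round(0.005 * sample_rate))
  fhop <- max(1L, round(0.001 * sample_rate))
  fstarts <- seq(1L, max(1L, length(wave) - fwin + 1L), by = fhop)
  fenv <- vapply(fstarts, function(s) {
    sqrt(mean(wave[s:min(length(wave), s + fwin - 1)]^2))
  }, numeric(1))
  fcen <- (fstarts - 1 + fwin / 2) / sample_rate
  thr <- spec$threshold_rel * ref
  win_s <- win / sample_rate
  for (k in seq_len(nrow(iv))) {
    near_a <- which(fcen >= iv[k, 1] - win_s & fcen <= iv[k, 1] + win_s & fenv >= thr)
    if (length(near_a) > 0) iv[k, 1] <- fcen[near_a[1]] - fwin / (2 * sample_rate)
    near_b <- which(fcen >= iv[k, 2] - win_s & fcen <= iv[k, 2] + win_s & fenv >= thr)
    if (length(near_b) > 0) {
      iv[k, 2] <- fcen[near_b[length(near_b)]] + fwin / (2 * sample_rate)
    }
  }
  iv[, 1] <- pmax(iv[, 1], 0)
  iv[, 2] <- pmin(iv[, 2], length(wave) / sample_rate)

  keep <- (iv[, 2] - iv[, 1]) * 1000 >= spec$min_cry_ms
  iv <- iv[keep, , drop = FALSE]
  tibble::tibble(start_s = iv[, 1], end_s = iv[, 2])
}

#' Cry inclusion filter settings
#'
#' The four inclusion conditions for a segmented vocalization to count as a
#' cry: at least 20% voiced frames, median pitch strictly above 150 Hz,
#' duration strictly above 250 ms, and Wiener entropy strictly below 0.6.
#'
#' @param min_voiced Minimum voiced fraction (inclusive, default 0.20).
#' @param min_median_pitch_hz Pitch floor (exclusive, default 150).
#' @param min_duration_s Duration floor (exclusive, default 0.250).
#' @param max_entropy Entropy ceiling (exclusive, default 0.6).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_voiced = 0.20, min_median_pitch_hz = 150,
                        min_duration_s = 0.250, max_entropy = 0.6) {
  stopifnot(min_voiced >= 0, min_voiced <= 1, min_median_pitch_hz > 0,
            min_duration_s > 0, max_entropy >= 0, max_entropy <= 1)
  structure(list(min_voiced = min_voiced,
                 min_median_pitch_hz = min_median_pitch_hz,
                 min_duration_s = min_duration_s,
                 max_entropy = max_entropy),
            class = "filter_spec")
}

#' Apply the four-condition cry filter
#'
#' Keeps a candidate iff `voicing >= min_voiced` AND
#' `pitch_median > min_median_pitch_hz` AND `duration_s > min_duration_s` AND
#' `entropy < max_entropy` (inequality directions are exactly the printed
#' inclusion rules; boundary values on the strict conditions are rejected).
#' A missing descriptor rejects the candidate with reason `"unmeasurable"`.
#'
#' @param candidates A data frame with (at least) columns `voicing`,
#'   `pitch_median`, `duration_s`, `entropy`; other columns pass through.
#' @param spec A [filter_spec()].
#' @return A list with `kept` (tibble of passing rows), `rejected` (tibble of
#'   failing rows with a `reject_reasons` column listing every failed
#'   condition, comma-separated).
#' @export
filter_cries <- function(candidates, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  candidates <- tibble::as_tibble(candidates)
  need <- c("voicing", "pitch_median", "duration_s", "entropy")
  missing_cols <- setdiff(need, names(candidates))
  if (length(missing_cols) > 0) {
    stop("candidates lack descriptor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  reasons <- vapply(seq_len(nrow(candidates)), function(i) {
    row <- candidates[i, ]
    # voicing 0 is measurable (fully unvoiced); NA pitch with voicing 0 is a
    # voicing failure, not an unmeasurable one
    if (is.na(row$voicing) || is.na(row$duration_s) || is.na(row$entropy) ||
        (is.na(row$pitch_median) && row$voicing > 0)) {
      return("unmeasurable")
    }
    fails <- character(0)
    if (!(row$voicing >= spec$min_voiced)) fails <- c(fails, "voicing")
    if (is.na(row$pitch_median) || !(row$pitch_median > spec$min_median_pitch_hz)) {
      fails <- c(fails, "pitch")
    }
    if (!(row$duration_s > spec$min_duration_s)) fails <- c(fails, "duration")
    if (!(row$entropy < spec$max_entropy)) fails <- c(fails, "entropy")
    paste(fails, collapse = ",")
  }, character(1))
  keep <- reasons == ""
  rejected <- candidates[!keep, , drop = FALSE]
  rejected$reject_reasons <- reasons[!keep]
  list(kept = candidates[keep, , drop = FALSE], rejected = rejected)
}

#' Remove cries with rare or unknown causes
#'
#' Retains only the three major causes (hunger, discomfort, isolation),
#' dropping causes in `drop` (by default `pain` and `other`) and, when
#' `drop_unknown`, cries labelled `unknown`; returns a tally of removals per
#' dropped category.
#'
#' @param records Data frame with a `cause` column.
#' @param drop Causes to remove (default `c("pain", "other")`).
#' @param drop_unknown Drop `"unknown"` causes too (default TRUE).
#' @return List with `records` (filtered tibble) and `tally` (named integer
#'   vector of removed counts per dropped category).
#' @export
exclude_rare_causes <- function(records, drop = c("pain", "other"),
                                drop_unknown = TRUE) {
  records <- tibble::as_tibble(records)
  stopifnot("cause" %in% names(records))
  retained <- c("hunger", "discomfort", "isolation")
  drop_set <- union(drop, if (drop_unknown) "unknown" else character(0))
  drop_set <- union(drop_set, setdiff(unique(records$cause), retained))
  tally <- vapply(drop_set, function(d) sum(records$cause == d), integer(1))
  tally <- tally[tally > 0 | names(tally) %in% drop]
  list(records = records[records$cause %in% retained, , drop = FALSE],
       tally = tally)
}
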