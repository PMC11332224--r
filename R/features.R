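#' Names of the ten per-cry acoustic descriptors
#'
#' Column order used by every statistical stage: duration, median pitch and
#' pitch IQR, voicing, spectral centroid, Wiener entropy, harmonics-to-noise
#' ratio, jitter, shimmer, modulation-spectrum roughness.
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() {
  c("duration_s", "pitch_median", "pitch_iqr", "voicing", "spectral_centroid",
    "entropy", "hnr_db", "jitter_pct", "shimmer_pct", "roughness_pct")
}

#' Wiener entropy (spectral flatness) of a power spectrum
#'
#' Geometric mean divided by arithmetic mean of spectral power across bins:
#' 1 for a flat (white) spectrum, approaching 0 for a pure tone. Zero bins are
#' floored at machine epsilon.
#'
#' @param power_spectrum Non-negative numeric vector, not all zero.
#' @return Scalar in \[0, 1\]; `NA` if the spectrum is all zero.
#' @export
wiener_entropy <- function(power_spectrum) {
  p <- as.numeric(power_spectrum)
  if (any(p < 0, na.rm = TRUE)) stop("power spectrum must be non-negative")
  if (all(!is.finite(p)) || sum(p, na.rm = TRUE) <= 0) return(NA_real_)
  p <- pmax(p[is.finite(p)], .Machine$double.eps)
  exp(mean(log(p))) / mean(p)
}

#' Harmonics-to-noise ratio from an autocorrelation peak
#'
#' `10 * log10(r / (1 - r))` where `r` is the normalized autocorrelation at
#' the pitch lag, clipped to \[-10, 40\] dB. Values of `r >= 1` (numerical)
#' clip to 40 dB with a warning.
#'
#' @param r Normalized autocorrelation peak height(s), in \[0, 1\].
#' @return HNR in dB.
#' @export
hnr_from_acf <- function(r) {
  out <- numeric(length(r))
  bad <- !is.finite(r)
  hi <- !bad & r >= 1
  if (any(hi)) warning("autocorrelation peak >= 1; clipping HNR to 40 dB")
  lo <- !bad & r <= 0
  mid <- !bad & !hi & !lo
  out[bad] <- NA_real_
  out[hi] <- 40
  out[lo] <- -10
  out[mid] <- pmin(40, pmax(-10, 10 * log10(r[mid] / (1 - r[mid]))))
  out
}

#' Local jitter of a period sequence
#'
#' `mean(|T_i - T_(i-1)|) / mean(T_i) * 100`, the period-to-period ("local")
#' perturbation measure.
#'
#' @param periods Consecutive voiced glottal periods (any consistent unit).
#' @return Percentage; `NA` with fewer than 3 periods.
#' @export
jitter_local <- function(periods) {
  periods <- as.numeric(periods)
  if (length(periods) < 3 || anyNA(periods)) return(NA_real_)
  mean(abs(diff(periods))) / mean(periods) * 100
}

#' Local shimmer of a per-cycle peak-amplitude sequence
#'
#' Same formula as [jitter_local()], applied to per-period peak amplitudes.
#'
#' @param amplitudes Consecutive per-cycle peak amplitudes.
#' @return Percentage; `NA` with fewer than 3 amplitudes.
#' @export
shimmer_local <- function(amplitudes) jitter_local(amplitudes)

#' Spectral centroid of a magnitude spectrum
#'
#' Amplitude-weighted mean frequency over bins up to `fmax`.
#'
#' @param magnitude Non-negative spectrum magnitudes.
#' @param freqs Bin frequencies (Hz), same length.
#' @param fmax Upper frequency limit (Hz, default 8000).
#' @return Centroid in Hz; `NA` if no energy below `fmax`.
#' @export
spectral_centroid <- function(magnitude, freqs, fmax = 8000) {
  stopifnot(length(magnitude) == length(freqs))
  keep <- freqs <= fmax & is.finite(magnitude)
  if (!any(keep) || sum(magnitude[keep]) <= 0) return(NA_real_)
  sum(freqs[keep] * magnitude[keep]) / sum(magnitude[keep])
}

gaussian_window <- function(n) {
  i <- seq_len(n) - (n + 1) / 2
  exp(-0.5 * (i / (n / 6))^2)
}

#' Frame-by-frame acoustic analysis
#'
#' Slides a Gaussian-windowed frame over the waveform and, per frame, decides
#' voicing and estimates f0 by normalized autocorrelation (peak height within
#' `f0_range` against `voicing_threshold`, corrected for the window's own
#' autocorrelation, with parabolic interpolation of the peak), plus
#' log-magnitude spectrum statistics: spectral centroid, Wiener entropy of
#' the band-smoothed power spectrum, HNR from the pitch-lag peak, and an RMS
#' loudness proxy.
#'
#' @param wave Numeric waveform.
#' @param sample_rate Sampling rate (Hz).
#' @param frame_ms Frame length (ms, default 40).
#' @param hop_ms Hop (ms, default 10).
#' @param f0_range Two-element f0 search range (Hz), default `c(150, 1200)`.
#' @param voicing_threshold Autocorrelation peak height for voicing (0.45).
#' @param centroid_max_hz Band limit for spectral statistics (8000 Hz).
#' @param entropy_smooth_bins Width (bins) of the running-mean spectrum
#'   smoother applied before spectral flatness (9 bins, about 200 Hz at
#'   44.1 kHz) so that white noise measures near 1.
#' @return A tibble (the per-cry contour matrix): `time`, `voiced`, `f0_hz`,
#'   `pitch_st` (semitones re 1 Hz, `NA` when unvoiced), `hnr_db`, `entropy`,
#'   `centroid_hz` (also kHz column `centroid_khz`), `loudness_db`, with the
#'   hop stored in attribute `hop_s`.
#' @export
frame_analysis <- function(wave, sample_rate, frame_ms = 40, hop_ms = 10,
                           f0_range = c(150, 1200), voicing_threshold = 0.45,
                           centroid_max_hz = 8000, entropy_smooth_bins = 9) {
  stopifnot(length(wave) > 0, sample_rate > 0)
  if (f0_range[1] <= 50 || f0_range[2] >= sample_rate / 2) {
    stop("f0_range must lie within (50 Hz, Nyquist)")
  }
  flen <- round(frame_ms / 1000 * sample_rate)
  hop <- max(1L, round(hop_ms / 1000 * sample_rate))
  max_lag <- ceiling(sample_rate / f0_range[1])
  if (flen < 2 * max_lag) {
    stop("frame too short for f0 floor (needs >= 2 max-periods, ",
         signif(2 * max_lag / sample_rate * 1000, 3), " ms)")
  }
  n <- length(wave)
  if (n < flen) wave <- c(wave, numeric(flen - n))
  starts <- seq(1L, max(1L, length(wave) - flen + 1L), by = hop)

  w <- gaussian_window(flen)
  nfft <- 2^ceiling(log2(2 * flen))
  # window autocorrelation for Boersma-style peak normalization
  wf <- stats::fft(c(w, numeric(nfft - flen)))
  w_acf <- Re(stats::fft(Mod(wf)^2, inverse = TRUE))[seq_len(max_lag + 2)]
  w_acf <- w_acf / w_acf[1]

  nspec <- nfft / 2 + 1
  freqs <- (seq_len(nspec) - 1) * sample_rate / nfft
  lag_min <- max(2L, floor(sample_rate / f0_range[2]))
  lag_max <- min(max_lag, flen - 1L)
  sm_k <- max(1L, as.integer(entropy_smooth_bins))
  kern <- rep(1 / sm_k, sm_k)

  global_peak <- max(abs(wave))
  res <- lapply(starts, function(s) {
    x <- wave[s:(s + flen - 1)]
    x <- x - mean(x)
    rms <- sqrt(mean(x^2))
    if (rms < 1e-7 || rms < 1e-4 * global_peak) {
      return(c(rms = rms, voiced = 0, f0 = NA, r = NA,
               centroid = NA, entropy = NA))
    }
    xw <- x * w
    xf <- stats::fft(c(xw, numeric(nfft - flen)))
    pw <- Mod(xf[seq_len(nspec)])^2
    acf_x <- Re(stats::fft(Mod(xf)^2, inverse = TRUE))[seq_len(lag_max + 2)]
    r_norm <- acf_x / acf_x[1] / w_acf[seq_len(lag_max + 2)]
    seg <- r_norm[(lag_min + 1):(lag_max + 1)]    # r_norm[k+1] is lag k
    # prefer the shortest lag whose peak is within 0.02 of the maximum:
    # for periodic signals r is near-equal at T, 2T, 3T (octave ambiguity)
    loc <- which(diff(sign(diff(c(-Inf, seg, -Inf)))) < 0)
    rmax <- max(seg[loc])
    pk <- loc[seg[loc] >= rmax - 0.02][1]
    lag <- lag_min + pk - 1
    # parabolic interpolation of the peak
    if (lag > lag_min && lag < lag_max) {
      y1 <- r_norm[lag]; y2 <- r_norm[lag + 1]; y3 <- r_norm[lag + 2]
      denom <- y1 - 2 * y2 + y3
      d <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
      d <- max(-0.5, min(0.5, d))
      r_pk <- y2 - 0.25 * (y1 - y3) * d
      lag_star <- lag + d
    } else {
      r_pk <- r_norm[lag + 1]
      lag_star <- lag
    }
    r_pk <- min(r_pk, 1 - 1e-9)
    voiced <- as.numeric(r_pk >= voicing_threshold)
    band <- freqs <= centroid_max_hz
    cen <- spectral_centroid(sqrt(pw[band]), freqs[band], fmax = centroid_max_hz)
    psm <- stats::filter(pw[band], kern, sides = 2, circular = TRUE)
    ent <- wiener_entropy(as.numeric(psm))
    c(rms = rms, voiced = voiced,
      f0 = if (voiced > 0) sample_rate / lag_star else NA,
      r = r_pk, centroid = cen, entropy = ent)
  })
  m <- do.call(rbind, res)
  voiced <- m[, "voiced"] > 0
  out <- tibble::tibble(
    time = (starts - 1 + flen / 2) / sample_rate,
    voiced = voiced,
    f0_hz = m[, "f0"],
    pitch_st = ifelse(voiced, 12 * log2(m[, "f0"]), NA_real_),
    hnr_db = ifelse(voiced, hnr_from_acf(m[, "r"]), NA_real_),
    entropy = m[, "entropy"],
    centroid_hz = m[, "centroid"],
    centroid_khz = m[, "centroid"] / 1000,
    loudness_db = 20 * log10(pmax(m[, "rms"], 1e-9))
  )
  attr(out, "hop_s") <- hop / sample_rate
  attr(out, "sample_rate") <- sample_rate
  out
}

# Track per-cycle glottal pulses within voiced runs, guided by the frame f0
# contour. Returns a list of runs, each with pulse times (s) and peak
# amplitudes (parabolically interpolated).
pulse_track <- function(wave, sample_rate, contour) {
  runs <- voiced_runs(contour)
  out <- list()
  for (rn in runs) {
    f0s <- contour$f0_hz[rn]
    times_f <- contour$time[rn]
    i_lo <- max(1L, round(min(times_f) * sample_rate) - round(0.02 * sample_rate))
    i_hi <- min(length(wave), round(max(times_f) * sample_rate) + round(0.02 * sample_rate))
    if (i_hi - i_lo < 8) next
    seg <- wave[i_lo:i_hi]
    # rolling-median baseline (~1.5 periods) so per-pulse amplitudes are
    # measured from the inter-pulse floor, not from the AC-coupled zero line
    T_mid <- 1 / stats::median(f0s)
    bw <- min(length(seg), round(1.5 * T_mid * sample_rate))
    if (bw %% 2 == 0) bw <- bw + 1
    base <- if (bw >= 3 && length(seg) > bw) stats::runmed(seg, bw) else rep(stats::median(seg), length(seg))
    T_at <- function(t) {
      f <- stats::approx(times_f, f0s, xout = t, rule = 2)$y
      1 / f
    }
    peak_at <- function(center, halfwin) {
      a <- max(1L, floor(center - halfwin)); b <- min(length(seg), ceiling(center + halfwin))
      if (b - a < 2) return(NULL)
      j <- a - 1 + which.max(seg[a:b])
      if (j <= 1 || j >= length(seg)) return(list(pos = j, amp = seg[j] - base[j]))
      y1 <- seg[j - 1]; y2 <- seg[j]; y3 <- seg[j + 1]
      denom <- y1 - 2 * y2 + y3
      d <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
      d <- max(-0.5, min(0.5, d))
      list(pos = j + d, amp = y2 - 0.25 * (y1 - y3) * d - base[j])
    }
    mid <- round(length(seg) / 2)
    T0 <- T_at((i_lo + mid) / sample_rate) * sample_rate
    p0 <- peak_at(mid, T0 / 2)
    if (is.null(p0)) next
    walk <- function(start, dir) {
      pos <- numeric(0); amp <- numeric(0)
      cur <- start$pos
      repeat {
        Tc <- T_at((i_lo + cur) / sample_rate) * sample_rate
        nxt <- cur + dir * Tc
        if (nxt < Tc * 0.3 || nxt > length(seg) - Tc * 0.3) break
        pk <- peak_at(nxt, 0.3 * Tc)
        if (is.null(pk) || pk$amp <= 0) break
        pos <- c(pos, pk$pos); amp <- c(amp, pk$amp)
        cur <- pk$pos
        if (length(pos) > 5000) break
      }
      list(pos = pos, amp = amp)
    }
    right <- walk(p0, +1)
    left <- walk(p0, -1)
    pos <- c(rev(left$pos), p0$pos, right$pos)
    amp <- c(rev(left$amp), p0$amp, right$amp)
    med_a <- stats::median(amp)
    # drop weak pulses and the onset/offset ramp regions (12 ms at edges)
    edge <- 0.012 * sample_rate
    keep <- amp > 0.1 * med_a &
      (i_lo - 1 + pos) > edge &
      (i_lo - 1 + pos) < length(wave) - edge
    pos <- pos[keep]; amp <- amp[keep]
    if (length(pos) >= 4) {
      out[[length(out) + 1]] <- list(
        times = (i_lo - 1 + pos) / sample_rate,
        amps = amp
      )
    }
  }
  out
}

# Split a tracked pulse run at skipped/doubled pulses: periods outside
# [0.55, 1.45] x the run median indicate tracking glitches, not phonation,
# and must not contaminate period-to-period perturbation measures.
clean_period_stretches <- function(run) {
  p <- diff(run$times)
  if (length(p) < 3) return(list())
  med <- stats::median(p)
  good <- p > 0.55 * med & p < 1.45 * med
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= 3)
  lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    list(periods = p[idx], amps = run$amps[c(idx, idx[length(idx)] + 1)])
  })
}

# index ranges of consecutive voiced frames in a contour
voiced_runs <- function(contour, min_frames = 3L) {
  v <- contour$voiced
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_frames
  Map(function(s, e) s:e, starts[keep], ends[keep])
}

#' Modulation-spectrum roughness of voiced segments
#'
#' Per voiced segment of at least `min_segment_s` seconds, computes the
#' amplitude envelope (rectification plus a 4th-order Butterworth low-pass at
#' 400 Hz) and its modulation spectrum, and takes the proportion of
#' modulation power falling in the 30-150 Hz roughness band relative to the
#' 1-400 Hz band, times 100. The per-cry value is the median across voiced
#' segments.
#'
#' @param wave Numeric waveform.
#' @param sample_rate Sampling rate (Hz).
#' @param segments List of integer sample ranges (or `NULL` for the whole
#'   waveform as one segment).
#' @param min_segment_s Minimum usable segment duration (default 0.2 s, the
#'   30 Hz resolution floor).
#' @param band Roughness band (Hz), default `c(30, 150)`.
#' @param total_band Denominator band (Hz), default `c(1, 400)`.
#' @return Percentage in \[0, 100\]; `NA` when no segment is long enough.
#' @export
roughness <- function(wave, sample_rate, segments = NULL, min_segment_s = 0.2,
                      band = c(30, 150), total_band = c(1, 400)) {
  if (is.null(segments)) segments <- list(seq_along(wave))
  bf <- signal::butter(4, min(0.99, 400 / (sample_rate / 2)), type = "low")
  vals <- vapply(segments, function(idx) {
    if (length(idx) < min_segment_s * sample_rate) return(NA_real_)
    env <- signal::filtfilt(bf, abs(wave[idx]))
    env <- env - mean(env)
    nn <- length(env)
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nn) / (nn + 1))
    sp <- Mod(stats::fft(env * win))^2
    fr <- (seq_len(nn) - 1) * sample_rate / nn
    half <- fr <= sample_rate / 2
    sp <- sp[half]; fr <- fr[half]
    num <- sum(sp[fr >= band[1] & fr <= band[2]])
    den <- sum(sp[fr >= total_band[1] & fr <= total_band[2]])
    if (den <= 0) return(NA_real_)
    100 * num / den
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  stats::median(vals, na.rm = TRUE)
}

#' Full acoustic profile of one cry
#'
#' Aggregates the frame analysis into the ten per-cry descriptors: duration,
#' median and IQR of voiced-frame f0, voicing fraction, median voiced-frame
#' spectral centroid, median Wiener entropy, median voiced-frame HNR, local
#' jitter and shimmer from tracked glottal pulses (weighted by run length),
#' and modulation-spectrum roughness of voiced segments. A fully unvoiced cry
#' gets `voicing = 0` with pitch-dependent fields `NA` (it will fail the cry
#' filter downstream).
#'
#' @param wave Numeric waveform (>= 0.05 s).
#' @param sample_rate Sampling rate (Hz).
#' @param ... Passed to [frame_analysis()].
#' @return A list with `profile` (one-row tibble of the ten descriptors) and
#'   `contour` (the frame-by-frame tibble, for DTW).
#' @export
profile_cry <- function(wave, sample_rate, ...) {
  if (length(wave) < 0.05 * sample_rate) stop("cry shorter than 0.05 s")
  contour <- frame_analysis(wave, sample_rate, ...)
  voiced <- contour$voiced
  f0 <- contour$f0_hz[voiced]
  dur <- length(wave) / sample_rate

  jit <- shi <- NA_real_
  if (any(voiced)) {
    runs <- pulse_track(wave, sample_rate, contour)
    stretches <- unlist(lapply(runs, clean_period_stretches), recursive = FALSE)
    if (length(stretches) > 0) {
      jits <- vapply(stretches, function(r) jitter_local(r$periods), numeric(1))
      shis <- vapply(stretches, function(r) shimmer_local(r$amps), numeric(1))
      wts <- vapply(stretches, function(r) length(r$periods), numeric(1))
      ok <- !is.na(jits)
      if (any(ok)) jit <- sum(jits[ok] * wts[ok]) / sum(wts[ok])
      ok <- !is.na(shis)
      if (any(ok)) shi <- sum(shis[ok] * wts[ok]) / sum(wts[ok])
    }
  }

  rough <- NA_real_
  if (any(voiced)) {
    hop_s <- attr(contour, "hop_s")
    segs <- lapply(voiced_runs(contour), function(rn) {
      a <- max(1L, round((contour$time[rn[1]] - 0.02) * sample_rate))
      b <- min(length(wave), round((contour$time[rn[length(rn)]] + 0.02) * sample_rate))
      a:b
    })
    rough <- roughness(wave, sample_rate, segs)
  }

  profile <- tibble::tibble(
    duration_s = dur,
    pitch_median = if (any(voiced)) stats::median(f0) else NA_real_,
    pitch_iqr = if (any(voiced)) stats::IQR(f0) else NA_real_,
    voicing = mean(voiced),
    spectral_centroid = if (any(voiced)) {
      stats::median(contour$centroid_hz[voiced], na.rm = TRUE)
    } else NA_real_,
    entropy = stats::median(contour$entropy, na.rm = TRUE),
    hnr_db = if (any(voiced)) stats::median(contour$hnr_db[voiced], na.rm = TRUE) else NA_real_,
    jitter_pct = jit,
    shimmer_pct = shi,
    roughness_pct = rough
  )
  list(profile = profile, contour = contour)
}
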