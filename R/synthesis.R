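#' Parameters of a synthetic cry
#'
#' Bundles the synthesis-side counterparts of the ten acoustic descriptors:
#' each control maps one-to-one onto a measurable property of the generated
#' waveform, so the feature extractor can be validated closed-loop.
#'
#' @param f0_median Target median fundamental frequency (Hz).
#' @param f0_iqr Target interquartile range of the f0 contour (Hz).
#' @param jitter_pct Cycle-to-cycle period perturbation, as the expected
#'   measured local jitter (%).
#' @param shimmer_pct Cycle-to-cycle amplitude perturbation, as the expected
#'   measured local shimmer (%).
#' @param hnr_db Target harmonics-to-noise ratio (dB).
#' @param centroid_hz Target spectral centre of gravity of voiced frames (Hz).
#' @param am_depth Amplitude-modulation depth, 0-1.
#' @param am_freq Amplitude-modulation frequency (Hz); in 30-150 Hz it drives
#'   the roughness descriptor.
#' @param voiced_fraction Proportion of cry time that is voiced, 0-1.
#' @param duration_s Cry duration (s).
#' @param sample_rate Sampling rate (Hz).
#' @return An object of class `cry_params` (a validated list).
#' @export
cry_params <- function(f0_median = 450, f0_iqr = 60, jitter_pct = 2.5,
                       shimmer_pct = 6, hnr_db = 15, centroid_hz = 1500,
                       am_depth = 0.3, am_freq = 70, voiced_fraction = 0.85,
                       duration_s = 0.9, sample_rate = 44100) {
  p <- list(
    f0_median = f0_median, f0_iqr = f0_iqr, jitter_pct = jitter_pct,
    shimmer_pct = shimmer_pct, hnr_db = hnr_db, centroid_hz = centroid_hz,
    am_depth = am_depth, am_freq = am_freq, voiced_fraction = voiced_fraction,
    duration_s = duration_s, sample_rate = sample_rate
  )
  stopifnot(
    f0_median > 0, f0_iqr >= 0, jitter_pct >= 0, shimmer_pct >= 0,
    am_depth >= 0, am_depth <= 1, voiced_fraction >= 0, voiced_fraction <= 1,
    duration_s > 0, sample_rate > 0, am_freq > 0
  )
  if (f0_median > sample_rate / 8) {
    stop("f0_median ", f0_median, " Hz exceeds Nyquist/4 at sample_rate ", sample_rate)
  }
  if (duration_s < 4 / f0_median) {
    stop("duration_s shorter than 4 pitch periods (", signif(4 / f0_median, 3), " s)")
  }
  structure(p, class = "cry_params")
}

# Evaluate code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Zero-phase FFT filtering with a magnitude response evaluated at |f|.
fft_shape <- function(x, sample_rate, response) {
  n <- length(x)
  nfft <- 2^ceiling(log2(n))
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * sample_rate / nfft
  h <- response(abs(f))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) * h, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Spectral tilt exp(-f/beta) such that a harmonic comb at f0 (magnitude
# weighting, band limited to fmax) has the requested centroid.
solve_tilt <- function(f0, centroid, fmax = 8000) {
  k <- seq_len(max(2, floor(fmax / f0)))
  cen <- function(beta) {
    w <- exp(-k * f0 / beta)
    sum(k * f0 * w) / sum(w)
  }
  lo <- f0 / 20
  hi <- fmax * 4
  target <- min(max(centroid, cen(lo) * 1.01), cen(hi) * 0.999)
  stats::uniroot(function(b) cen(b) - target, c(lo, hi), tol = 1e-6)$root
}

# Alternating voiced/unvoiced mask realizing voiced_fraction. Unvoiced gaps
# are kept under 80 ms so the segmenter (100 ms merge rule) sees one cry,
# and the leading voiced run is at least 240 ms whenever the budget allows,
# so the roughness descriptor (200 ms floor) stays measurable.
voicing_mask <- function(n, sample_rate, voiced_fraction) {
  if (voiced_fraction >= 0.999) return(rep(TRUE, n))
  if (voiced_fraction <= 0.001) return(rep(FALSE, n))
  dur <- n / sample_rate
  voiced_total <- voiced_fraction * dur
  unv_total <- dur - voiced_total
  n_gaps <- max(1L, ceiling(unv_total / 0.08))
  gap <- unv_total / n_gaps
  lead <- min(voiced_total, max(0.24, voiced_total / (n_gaps + 1)))
  rest <- voiced_total - lead
  run_len <- c(lead, rep(c(gap, rest / n_gaps), n_gaps))
  run_voiced <- c(TRUE, rep(c(FALSE, TRUE), n_gaps))
  bounds <- round(cumsum(run_len) * sample_rate)
  mask <- logical(n)
  a <- 1L
  for (k in seq_along(run_len)) {
    b <- min(n, bounds[k])
    if (b >= a) mask[a:b] <- run_voiced[k]
    a <- b + 1L
  }
  if (a <= n) mask[a:n] <- run_voiced[length(run_voiced)]
  mask
}

raised_cosine_smooth <- function(mask, sample_rate, ramp_s = 0.004) {
  k <- max(3L, round(ramp_s * sample_rate))
  w <- (1 - cos(2 * pi * seq_len(k) / (k + 1))) / 2
  w <- w / sum(w)
  stats::filter(as.numeric(mask), w, sides = 2) |>
    (\(z) { z[is.na(z)] <- as.numeric(mask)[is.na(z)]; as.numeric(z) })()
}

#' Synthesize a cry-like vocalization
#'
#' Source-filter synthesis: a glottal pulse train follows a slow random f0
#' contour (median `f0_median`, spread `f0_iqr`), with per-cycle period noise
#' (jitter) and amplitude noise (shimmer); the pulse train and an additive
#' broadband noise bed (level set by `hnr_db`) share a spectral tilt chosen so
#' the voiced-frame spectral centroid lands near `centroid_hz`; sinusoidal
#' amplitude modulation at `am_freq` with depth `am_depth` supplies roughness;
#' unvoiced gaps realize `voiced_fraction`. Deterministic given
#' `(params, seed)`; the caller's RNG state is untouched.
#'
#' Injected jitter/shimmer are pre-scaled by `sqrt(pi)/2` (the expected
#' absolute first difference of unit-variance Gaussian noise) so that the
#' *measured* local perturbation matches the requested percentage.
#'
#' @param params A [cry_params()] object.
#' @param seed Integer seed.
#' @return Numeric waveform at `params$sample_rate`, peak-normalized to 0.9.
#' @export
synthesize_cry <- function(params, seed = 1L) {
  stopifnot(inherits(params, "cry_params"))
  with_seed(seed, {
    sr <- params$sample_rate
    n <- max(16L, round(params$duration_s * sr))
    dur <- n / sr

    # slow f0 contour: smooth gaussian noise, centred at zero median,
    # scaled (log-domain) to the requested IQR
    n_knots <- max(4L, ceiling(dur * 6))
    knots <- stats::rnorm(n_knots)
    tk <- seq(0, dur, length.out = n_knots)
    contour_fun <- stats::splinefun(tk, knots, method = "natural")
    g_of <- function(t) contour_fun(t)
    tg <- seq(0, dur, length.out = 200)
    gv <- g_of(tg)
    gv <- gv - stats::median(gv)
    iqr_g <- stats::IQR(gv)
    s <- if (params$f0_iqr > 0 && iqr_g > 1e-9) {
      params$f0_iqr / (params$f0_median * iqr_g)
    } else 0
    med_g <- stats::median(g_of(tg))
    f0_at <- function(t) params$f0_median * exp(s * (g_of(t) - med_g))

    # glottal cycles
    jit_sd <- params$jitter_pct / 100 / (2 / sqrt(pi))
    shi_sd <- params$shimmer_pct / 100 / (2 / sqrt(pi))
    times <- numeric(0)
    amps <- numeric(0)
    t <- 0.002
    while (t < dur - 0.001) {
      times <- c(times, t)
      T0 <- 1 / f0_at(t)
      t <- t + T0 * max(0.5, 1 + jit_sd * stats::rnorm(1))
    }
    amps <- pmax(0.05, 1 + shi_sd * stats::rnorm(length(times)))

    # pulse train with linear-interpolated fractional sample placement
    pulses <- numeric(n)
    pos <- times * sr
    i0 <- floor(pos) + 1
    frac <- pos - (i0 - 1)
    ok <- i0 >= 1 & i0 < n
    for (j in which(ok)) {
      pulses[i0[j]] <- pulses[i0[j]] + amps[j] * (1 - frac[j])
      pulses[i0[j] + 1] <- pulses[i0[j] + 1] + amps[j] * frac[j]
    }

    beta <- solve_tilt(params$f0_median, params$centroid_hz)
    shape <- function(f) ifelse(f < 60, 0, exp(-f / beta))
    harm <- fft_shape(pulses, sr, shape)

    vmask <- voicing_mask(n, sr, params$voiced_fraction)
    vsm <- raised_cosine_smooth(vmask, sr)

    p_h <- stats::var(harm[vmask])
    if (!is.finite(p_h) || p_h <= 0) p_h <- stats::var(harm)
    noise <- fft_shape(stats::rnorm(n), sr, shape)
    noise <- noise / stats::sd(noise)
    noise_v <- noise * sqrt(p_h * 10^(-params$hnr_db / 10))
    noise_u <- noise * sqrt(p_h) * 0.5

    tt <- seq_len(n) / sr
    am <- (1 + params$am_depth * sin(2 * pi * params$am_freq * tt)) /
      (1 + params$am_depth)

    x <- (harm + noise_v) * am * vsm + noise_u * (1 - vsm)

    # onset/offset ramps (8 ms) against clicks
    k <- min(round(0.008 * sr), floor(n / 4))
    ramp <- sin(seq(0, pi / 2, length.out = k))^2
    x[seq_len(k)] <- x[seq_len(k)] * ramp
    x[(n - k + 1):n] <- x[(n - k + 1):n] * rev(ramp)

    peak <- max(abs(x))
    if (peak > 0) x <- x * 0.9 / peak
    x
  })
}
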