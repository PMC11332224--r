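#' Latent-dimension to physical-parameter maps
#'
#' Fixed affine maps taking latent SD-unit trait values to physical
#' descriptor values, with clipping to plausible infant-cry ranges. Centres
#' sit inside the range implied by the 150 Hz pitch floor of the cry filter.
#'
#' @return A data frame with columns `feature`, `center`, `scale`, `lo`, `hi`.
#' @export
latent_maps <- function() {
  tibble::tibble(
    feature = feature_names(),
    center = c(NA, 450, 60, 0.78, 1500, 0.32, 12, 2.5, 6, 45),
    scale  = c(NA, 50, 18, 0.07, 300, 0.08, 4, 0.9, 2, 12),
    lo     = c(0.25, 250, 8, 0.25, 700, 0.03, 0, 0.15, 0.8, 1),
    hi     = c(12, 850, 220, 1.00, 3800, 0.90, 34, 9, 22, 97)
  )
}

map_latent <- function(z, feature) {
  m <- latent_maps()
  m <- m[m$feature == feature, ]
  if (feature == "duration_s") {
    # log-normal, median 0.86 s, truncated to [0.25, 12] s
    return(pmin(m$hi, pmax(m$lo, 0.86 * exp(0.5 * z))))
  }
  v <- m$center + m$scale * z
  if (any(!is.finite(v))) {
    stop("non-finite mapped value for ", feature)
  }
  pmin(m$hi, pmax(m$lo, v))
}

default_age_slopes <- function() {
  c(duration_s = 0, pitch_median = 0.11, pitch_iqr = 0, voicing = 0.24,
    spectral_centroid = -0.19, entropy = -0.42, hnr_db = 0.17,
    jitter_pct = -0.15, shimmer_pct = -0.15, roughness_pct = -0.20)
}

as_dim_vector <- function(x, name) {
  feats <- feature_names()
  if (is.null(x)) x <- 0
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), 10), feats))
  }
  out <- stats::setNames(numeric(10), feats)
  if (is.null(names(x))) {
    stopifnot(length(x) == 10)
    out[] <- as.numeric(x)
  } else {
    bad <- setdiff(names(x), feats)
    if (length(bad)) stop("unknown feature in ", name, ": ", paste(bad, collapse = ", "))
    out[names(x)] <- as.numeric(x)
  }
  out
}

#' Configuration of a synthetic cry cohort
#'
#' Defines the ground-truth generative model: per baby `b` and latent
#' acoustic dimension `d`, the latent SD-unit value of a cry is
#' `u_bd + (slope_d + v_bd) * age + cause_d[c] + s_d(session) + e`, with
#' `u_bd ~ N(0, baby_signature_sd)` (the individual signature),
#' `v_bd ~ N(0, slope_sd)` (between-baby drift variation), a per-session
#' confound `s_d ~ N(0, session_effect_sd)` shared by every cry of the
#' session, and residual `e ~ N(0, residual_sd)`. The default structure
#' mirrors a longitudinal home-recording design: 24 babies, ages 0.5/1.5/2.5/
#' 3.5 months, cries nested in crying sequences within 48-h sessions, three
#' cause labels with zero acoustic cause effect.
#'
#' @param n_babies Number of babies (>= 2, default 24).
#' @param ages Recording ages in months (default 0.5, 1.5, 2.5, 3.5).
#' @param sessions_per_age Sessions per baby and age (default 1).
#' @param sequences_per_session Crying sequences per session (default 4).
#' @param cries_per_sequence Cries per sequence (default 6).
#' @param missing_session_rate Probability a session is missing (default 0).
#' @param baby_signature_sd SD of the per-baby random intercepts (default 1).
#' @param age_slope Population drift in SD units/month; scalar or named
#'   vector over features. Defaults encode the tonality-up / roughness-down
#'   developmental pattern.
#' @param slope_sd SD of between-baby slope deviations (default 0.05).
#' @param cause_effect Per-cause latent offsets: 0, or a list with elements
#'   `hunger`, `discomfort`, `isolation`, each scalar or named vector.
#' @param session_effect_sd SD of the session-level confound (default 0.25).
#' @param residual_sd Residual SD (default 1).
#' @param cause_probs Probabilities of (hunger, discomfort, isolation),
#'   default the observed corpus shares (0.334, 0.268, 0.398).
#' @param prop_female Proportion of girls (default 10/24).
#' @param sample_rate Sampling rate for rendered audio (default 22050;
#'   44100 matches field recordings).
#' @param seed Master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_babies = 24, ages = c(0.5, 1.5, 2.5, 3.5),
                          sessions_per_age = 1, sequences_per_session = 4,
                          cries_per_sequence = 6, missing_session_rate = 0,
                          baby_signature_sd = 1, age_slope = default_age_slopes(),
                          slope_sd = 0.05, cause_effect = 0,
                          session_effect_sd = 0.25, residual_sd = 1,
                          cause_probs = c(hunger = 0.334, discomfort = 0.268,
                                          isolation = 0.398),
                          prop_female = 10 / 24, sample_rate = 22050,
                          seed = 1L) {
  stopifnot(n_babies >= 2, length(ages) >= 1, sessions_per_age >= 1,
            sequences_per_session >= 1, cries_per_sequence >= 1,
            missing_session_rate >= 0, missing_session_rate < 1,
            baby_signature_sd >= 0, slope_sd >= 0, session_effect_sd >= 0,
            residual_sd >= 0, abs(sum(cause_probs) - 1) < 1e-8,
            all(cause_probs >= 0))
  causes <- c("hunger", "discomfort", "isolation")
  if (is.list(cause_effect)) {
    stopifnot(all(causes %in% names(cause_effect)))
    ce <- lapply(cause_effect[causes], as_dim_vector, name = "cause_effect")
  } else {
    ce <- stats::setNames(rep(list(as_dim_vector(cause_effect, "cause_effect")), 3), causes)
  }
  structure(list(
    n_babies = n_babies, ages = ages, sessions_per_age = sessions_per_age,
    sequences_per_session = sequences_per_session,
    cries_per_sequence = cries_per_sequence,
    missing_session_rate = missing_session_rate,
    baby_signature_sd = baby_signature_sd,
    age_slope = as_dim_vector(age_slope, "age_slope"),
    slope_sd = slope_sd, cause_effect = ce,
    session_effect_sd = session_effect_sd, residual_sd = residual_sd,
    cause_probs = cause_probs[causes] / sum(cause_probs),
    prop_female = prop_female, sample_rate = sample_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Expected number of realized sessions under a cohort design
#'
#' @param config A [cohort_config()].
#' @return `n_babies * length(ages) * sessions_per_age * (1 - missing_session_rate)`.
#' @export
expected_sessions <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$n_babies * length(config$ages) * config$sessions_per_age *
    (1 - config$missing_session_rate)
}

# deterministic counter-based per-baby seed: adding babies never reshuffles
# existing ones
baby_seed <- function(master, b) {
  as.integer((abs(as.double(master)) * 104729 + b * 7919) %% 2147483629)
}

#' Simulate a labelled synthetic cry cohort
#'
#' Draws the latent trait structure of [cohort_config()] and realizes it at
#' one of two tiers. The descriptor tier (`audio = FALSE`) maps latent values
#' straight through the fixed affine maps ([latent_maps()]) to measured
#' descriptor values — the fast path for statistical experiments. The audio
#' tier (`audio = TRUE`) additionally renders each cry with
#' [synthesize_cry()] and writes per-cry WAV files plus a `metadata.csv` to
#' `out_dir`; measured descriptors are then obtained with
#' [extract_features()]. The latent model is identical in both tiers.
#'
#' @param config A [cohort_config()].
#' @param audio Render audio? (default FALSE).
#' @param out_dir Output directory for WAV files and metadata (required when
#'   `audio = TRUE`).
#' @return A list with `records` (one row per cry: `cry_id`, `baby_id`,
#'   `sex`, `age_months`, `session_id`, `sequence_id`, `cause`, `wav_path`,
#'   `duration_s`), `features` (descriptor-tier measured features;
#'   descriptor tier only), `latent` (per-cry latent SD-unit values),
#'   `params` (per-cry physical synthesis parameters), `maps`
#'   (the affine map table), and `config`.
#' @export
simulate_cohort <- function(config, audio = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (audio && is.null(out_dir)) stop("out_dir required when audio = TRUE")
  if (audio) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- feature_names()
  causes <- names(config$cause_probs)
  n_f <- round(config$prop_female * config$n_babies)

  rec_list <- list()
  lat_list <- list()
  for (b in seq_len(config$n_babies)) {
    bid <- sprintf("B%02d", b)
    sex <- if (b <= n_f) "F" else "M"
    rows <- with_seed(baby_seed(config$seed, b), {
      u <- stats::rnorm(10, 0, config$baby_signature_sd)
      v <- stats::rnorm(10, 0, config$slope_sd)
      out <- list()
      for (age in config$ages) {
        for (k in seq_len(config$sessions_per_age)) {
          if (stats::runif(1) < config$missing_session_rate) next
          sid <- sprintf("%s_a%s_s%d", bid, format(age), k)
          s_eff <- stats::rnorm(10, 0, config$session_effect_sd)
          for (q in seq_len(config$sequences_per_session)) {
            cause <- sample(causes, 1, prob = config$cause_probs)
            qid <- sprintf("%s_q%d", sid, q)
            for (cr in seq_len(config$cries_per_sequence)) {
              z <- u + (config$age_slope + v) * age +
                config$cause_effect[[cause]] + s_eff +
                stats::rnorm(10, 0, config$residual_sd)
              names(z) <- feats
              out[[length(out) + 1]] <- list(
                baby_id = bid, sex = sex, age_months = age, session_id = sid,
                sequence_id = qid, cause = cause, z = z,
                synth_seed = sample.int(.Machine$integer.max, 1)
              )
            }
          }
        }
      }
      out
    })
    rec_list <- c(rec_list, rows)
  }
  n <- length(rec_list)
  if (n == 0) stop("cohort design produced no cries")

  z_mat <- do.call(rbind, lapply(rec_list, `[[`, "z"))
  measured <- sapply(feats, function(f) map_latent(z_mat[, f], f))
  colnames(measured) <- feats

  cry_id <- sprintf("cry%05d", seq_len(n))
  records <- tibble::tibble(
    cry_id = cry_id,
    baby_id = vapply(rec_list, `[[`, character(1), "baby_id"),
    sex = vapply(rec_list, `[[`, character(1), "sex"),
    age_months = vapply(rec_list, `[[`, numeric(1), "age_months"),
    session_id = vapply(rec_list, `[[`, character(1), "session_id"),
    sequence_id = vapply(rec_list, `[[`, character(1), "sequence_id"),
    cause = vapply(rec_list, `[[`, character(1), "cause"),
    wav_path = NA_character_,
    duration_s = measured[, "duration_s"]
  )
  latent <- tibble::as_tibble(as.data.frame(z_mat))
  names(latent) <- paste0("z_", feats)
  latent <- tibble::add_column(latent, cry_id = cry_id, .before = 1)

  # physical synthesis parameters (entropy has no direct control: its latent
  # value lowers the effective HNR so noisier cries measure higher entropy)
  m <- latent_maps()
  hnr_eff <- map_latent(z_mat[, "hnr_db"] - 0.5 * z_mat[, "entropy"], "hnr_db")
  params <- tibble::tibble(
    cry_id = cry_id,
    f0_median = measured[, "pitch_median"],
    f0_iqr = measured[, "pitch_iqr"],
    jitter_pct = measured[, "jitter_pct"],
    shimmer_pct = measured[, "shimmer_pct"],
    hnr_db = hnr_eff,
    centroid_hz = measured[, "spectral_centroid"],
    am_depth = pmin(0.9, pmax(0.02, 0.3 + 0.12 * z_mat[, "roughness_pct"])),
    am_freq = 70,
    voiced_fraction = measured[, "voicing"],
    duration_s = measured[, "duration_s"],
    synth_seed = vapply(rec_list, `[[`, numeric(1), "synth_seed")
  )

  features <- NULL
  if (audio) {
    for (i in seq_len(n)) {
      p <- params[i, ]
      cp <- cry_params(
        f0_median = p$f0_median, f0_iqr = p$f0_iqr, jitter_pct = p$jitter_pct,
        shimmer_pct = p$shimmer_pct, hnr_db = p$hnr_db,
        centroid_hz = p$centroid_hz, am_depth = p$am_depth, am_freq = p$am_freq,
        voiced_fraction = p$voiced_fraction, duration_s = p$duration_s,
        sample_rate = config$sample_rate
      )
      wav <- file.path(out_dir, paste0(cry_id[i], ".wav"))
      write_wav(synthesize_cry(cp, seed = p$synth_seed), wav, config$sample_rate)
      records$wav_path[i] <- wav
    }
    utils::write.csv(records, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
  } else {
    features <- tibble::as_tibble(as.data.frame(measured))
    features <- tibble::add_column(features, cry_id = cry_id, .before = 1)
  }

  list(records = records, features = features, latent = latent,
       params = params, maps = latent_maps(), config = config)
}

#' Extract the ten descriptors from a corpus of cry WAV files
#'
#' Runs [profile_cry()] on each record's `wav_path`.
#'
#' @param records Tibble with `cry_id` and `wav_path` columns.
#' @param ... Passed to [profile_cry()].
#' @return A list with `features` (tibble: `cry_id` + ten descriptors) and
#'   `contours` (named list of per-cry contour tibbles).
#' @export
extract_features <- function(records, ...) {
  stopifnot(all(c("cry_id", "wav_path") %in% names(records)))
  contours <- vector("list", nrow(records))
  names(contours) <- records$cry_id
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    au <- read_wav(records$wav_path[i])
    pc <- profile_cry(au$wave, au$sample_rate, ...)
    rows[[i]] <- pc$profile
    contours[[i]] <- pc$contour
  }
  features <- dplyr::bind_rows(rows)
  features <- tibble::add_column(features, cry_id = records$cry_id, .before = 1)
  list(features = features, contours = contours)
}
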