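corpus_schema <- c("cry_id", "baby_id", "sex", "age_months", "session_id",
                   "sequence_id", "cause", "wav_path", "duration_s")

#' Read a cry corpus from a metadata CSV and audio directory
#'
#' Validates the documented schema (`cry_id, baby_id, sex, age_months,
#' session_id, sequence_id, cause, wav_path, duration_s`), checks that every
#' WAV file exists and that its duration matches the metadata within 1 ms.
#' Unknown extra columns are preserved with a warning.
#'
#' @param metadata_csv Path to the metadata CSV.
#' @param audio_dir Directory that `wav_path` entries are resolved against
#'   when not found as given (default: the CSV's directory).
#' @return A tibble of validated cry records.
#' @export
read_corpus <- function(metadata_csv, audio_dir = dirname(metadata_csv)) {
  meta <- tibble::as_tibble(utils::read.csv(metadata_csv, stringsAsFactors = FALSE))
  missing_cols <- setdiff(corpus_schema, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(meta), corpus_schema)
  if (length(extra) > 0) {
    warning("preserving unknown metadata column(s): ", paste(extra, collapse = ", "))
  }
  for (i in seq_len(nrow(meta))) {
    wp <- meta$wav_path[i]
    if (is.na(wp) || !file.exists(wp)) {
      alt <- file.path(audio_dir, basename(ifelse(is.na(wp), paste0(meta$cry_id[i], ".wav"), wp)))
      if (!file.exists(alt)) {
        stop("missing WAV for cry_id ", meta$cry_id[i])
      }
      meta$wav_path[i] <- alt
    }
    au <- read_wav(meta$wav_path[i])
    dur <- length(au$wave) / au$sample_rate
    if (abs(dur - meta$duration_s[i]) > 0.001 + 0.5 / au$sample_rate) {
      stop("duration mismatch for cry_id ", meta$cry_id[i], ": file ",
           signif(dur, 6), " s vs metadata ", signif(meta$duration_s[i], 6), " s")
    }
  }
  meta
}

#' Run the full cry-analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration under one master seed: simulate a cohort
#' (audio tier), concatenate each crying sequence into a bout WAV with
#' between-cry silences, segment the bouts, extract the ten descriptors per
#' segmented cry, apply the four-condition cry filter and the rare-cause
#' exclusion, and run the identity classification experiment. Every stage's
#' record counts are reconciled in the returned manifest
#' (`analyzed = segmented - filtered_out - excluded`), and a rerun with the
#' same configuration reproduces identical outputs.
#'
#' @param config A [cohort_config()] (keep it small: audio synthesis costs
#'   about 0.2 s per cry).
#' @param out_dir Working directory for audio and CSV outputs.
#' @param gap_s Between-cry silence inside a bout (default 0.3 s; must be
#'   above the 100 ms segmenter bridge).
#' @param n_runs Experiment repetitions (default 20).
#' @param seed Master seed (default: the config's seed).
#' @return A list with `manifest` (stage counts, config snapshot, seed,
#'   per-stage output checksums), `segments`, `features`, `kept`,
#'   `records`, `experiment`.
#' @export
run_pipeline <- function(config, out_dir, gap_s = 0.3, n_runs = 20,
                         seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  audio_dir <- file.path(out_dir, "cries")
  sim <- simulate_cohort(config, audio = TRUE, out_dir = audio_dir)
  records <- sim$records

  # assemble bout WAVs per sequence
  bout_dir <- file.path(out_dir, "bouts")
  dir.create(bout_dir, showWarnings = FALSE)
  seqs <- split(records, records$sequence_id)
  seg_rows <- list()
  for (sq in names(seqs)) {
    rs <- seqs[[sq]]
    waves <- lapply(rs$wav_path, function(p) read_wav(p)$wave)
    gap <- numeric(round(gap_s * config$sample_rate))
    bout <- numeric(0)
    for (w in waves) bout <- c(bout, w, gap)
    bout_path <- file.path(bout_dir, paste0(sq, ".wav"))
    write_wav(bout, bout_path, config$sample_rate)
    iv <- segment_sequence(bout, config$sample_rate)
    if (nrow(iv) > 0) {
      iv$sequence_id <- sq
      iv$bout_path <- bout_path
      seg_rows[[sq]] <- iv
    }
  }
  segments <- dplyr::bind_rows(seg_rows)
  n_segmented <- nrow(segments)

  # profile each segmented cry
  feats <- list()
  for (i in seq_len(n_segmented)) {
    au <- read_wav(segments$bout_path[i])
    a <- max(1L, round(segments$start_s[i] * au$sample_rate) + 1L)
    b <- min(length(au$wave), round(segments$end_s[i] * au$sample_rate))
    pr <- profile_cry(au$wave[a:b], au$sample_rate)$profile
    pr$sequence_id <- segments$sequence_id[i]
    feats[[i]] <- pr
  }
  features <- dplyr::bind_rows(feats)
  features$cry_id <- sprintf("seg%05d", seq_len(nrow(features)))

  flt <- filter_cries(features)
  meta_by_seq <- records[!duplicated(records$sequence_id),
                         c("sequence_id", "baby_id", "sex", "age_months",
                           "session_id", "cause")]
  kept <- dplyr::inner_join(flt$kept, meta_by_seq, by = "sequence_id")
  # a cry passing the four conditions can still lack jitter/shimmer or
  # roughness (no usable voiced stretch); it cannot enter the classifiers
  complete <- stats::complete.cases(kept[, feature_names()])
  n_unmeasurable <- sum(!complete)
  kept <- kept[complete, , drop = FALSE]
  exc <- exclude_rare_causes(kept)
  kept <- exc$records
  n_filtered <- nrow(flt$rejected) + n_unmeasurable
  n_excluded <- sum(exc$tally)
  n_analyzed <- nrow(kept)

  exp_res <- NULL
  if (length(unique(kept$baby_id)) >= 2) {
    exp_res <- tryCatch(
      run_experiment(kept, "baby_id", n_runs = n_runs, num_trees = 200,
                     seed = seed),
      error = function(e) {
        message("identity experiment skipped: ", conditionMessage(e))
        NULL
      }
    )
  }

  utils::write.csv(segments, file.path(out_dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  reject_tab <- table(c(unlist(strsplit(flt$rejected$reject_reasons, ",")),
                        rep("incomplete_descriptors", n_unmeasurable)))
  manifest <- list(
    seed = seed,
    config = unclass(config),
    counts = list(
      cries_written = nrow(records),
      segmented = n_segmented,
      filtered_out = n_filtered,
      filtered_out_by_reason = as.list(reject_tab),
      excluded_rare_cause = n_excluded,
      analyzed = n_analyzed
    ),
    reconciles = (n_analyzed == n_segmented - n_filtered - n_excluded),
    checksums = list(
      metadata = unname(tools::md5sum(file.path(audio_dir, "metadata.csv"))),
      segments = unname(tools::md5sum(file.path(out_dir, "segments.csv"))),
      features = unname(tools::md5sum(file.path(out_dir, "features.csv"))),
      audio = unname(tools::md5sum(sort(list.files(audio_dir, "\\.wav$", full.names = TRUE))))
    )
  )
  jsonlite::write_json(manifest$counts, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(manifest = manifest, segments = segments, features = features,
       kept = kept, records = records, experiment = exp_res)
}
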