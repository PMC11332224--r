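# Shared fixtures built in code.

# descriptor-tier cohort joined with metadata, ready for experiments
sim_features <- function(..., seed = 1) {
  cfg <- cohort_config(..., seed = seed)
  sim <- simulate_cohort(cfg)
  dplyr::inner_join(sim$features, sim$records, by = c("cry_id", "duration_s"))
}

# brute-force DTW oracle: minimum total cost over all monotone warping
# paths, divided by the (shortest) minimizing path's length
dtw_brute <- function(a, b) {
  paths <- list()
  rec <- function(i, j, len, cost) {
    cost <- cost + sqrt(sum((a[i, ] - b[j, ])^2))
    if (i == nrow(a) && j == nrow(b)) {
      paths[[length(paths) + 1]] <<- c(cost, len)
      return(invisible())
    }
    if (i < nrow(a) && j < nrow(b)) rec(i + 1, j + 1, len + 1, cost)
    if (i < nrow(a)) rec(i + 1, j, len + 1, cost)
    if (j < nrow(b)) rec(i, j + 1, len + 1, cost)
  }
  rec(1, 1, 1, 0)
  m <- do.call(rbind, paths)
  mc <- min(m[, 1])
  mc / min(m[m[, 1] <= mc + 1e-12, 2])
}

# quick synthetic contour from a rendered cry
synth_contour <- function(f0 = 450, seed = 1, duration_s = 0.4, sr = 22050, ...) {
  p <- cry_params(f0_median = f0, f0_iqr = 30, jitter_pct = 1, shimmer_pct = 2,
                  am_depth = 0.1, hnr_db = 25, voiced_fraction = 1,
                  duration_s = duration_s, sample_rate = sr, ...)
  profile_cry(synthesize_cry(p, seed), sr)$contour
}
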