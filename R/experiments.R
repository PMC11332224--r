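#' Z-score acoustic features within babies or globally
#'
#' Within-baby scope removes each baby's mean and SD per feature (the
#' normalization used for age and cause analyses, so that individual
#' signatures do not masquerade as context effects); global scope z-scores
#' across all cries (used for identity analyses, where between-baby
#' differences are the signal).
#'
#' @param data Data frame holding the feature columns (and `baby_id` for
#'   within-baby scope).
#' @param scope `"within_baby"` or `"global"`.
#' @param features Feature columns (default the ten descriptors present).
#' @return `data` with the feature columns replaced by z-scores. A
#'   zero-variance feature within a scope unit is set to 0 with a warning.
#' @export
normalize_features <- function(data, scope = c("within_baby", "global"),
                               features = intersect(feature_names(), names(data))) {
  scope <- match.arg(scope)
  data <- tibble::as_tibble(data)
  stopifnot(length(features) > 0, all(features %in% names(data)))
  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance feature within scope; set to 0")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  if (scope == "global") {
    for (f in features) data[[f]] <- zscore(data[[f]])
  } else {
    stopifnot("baby_id" %in% names(data))
    if (min(table(data$baby_id)) < 2) stop("need >= 2 cries per baby")
    for (f in features) {
      data[[f]] <- stats::ave(data[[f]], data$baby_id, FUN = zscore)
    }
  }
  data
}

#' Session-grouped, class-balanced train/test split
#'
#' Assigns whole groups (recording sessions by default) to train or test so
#' that no group contributes to both sides — blocking leakage through
#' session-constant confounds — then downsamples each side to the rarest
#' class so class frequencies are balanced ("stratification": no
#' over-representation of common classes). `group_key = NULL` gives the
#' naive per-cry split (used to demonstrate leakage, not for inference).
#'
#' @param data Data frame with the label and grouping columns.
#' @param stratify_by Name of the class-label column.
#' @param group_key Name of the grouping column (default `"session_id"`);
#'   `NULL` for a per-cry split.
#' @param test_fraction Fraction of groups (or cries) for testing (1/3).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
grouped_split <- function(data, stratify_by, group_key = "session_id",
                          test_fraction = 1 / 3, seed = 1L) {
  data <- tibble::as_tibble(data)
  stopifnot(stratify_by %in% names(data))
  labels <- as.character(data[[stratify_by]])
  with_seed(seed, {
    if (is.null(group_key)) {
      n <- nrow(data)
      test_idx <- sort(sample.int(n, round(test_fraction * n)))
      in_test <- seq_len(n) %in% test_idx
    } else {
      stopifnot(group_key %in% names(data))
      groups <- unique(data[[group_key]])
      for (cl in unique(labels)) {
        if (length(unique(data[[group_key]][labels == cl])) < 2) {
          stop("class '", cl, "' is present in fewer than 2 groups; ",
               "a grouped split cannot place it on both sides")
        }
      }
      n_test <- max(1L, round(test_fraction * length(groups)))
      # prefer splits with every class on both sides; settle for every class
      # in training and at least two classes in testing (e.g. when classes
      # have too few groups to cover both sides simultaneously)
      ok <- FALSE
      for (try in 1:200) {
        test_groups <- sample(groups, n_test)
        in_test <- data[[group_key]] %in% test_groups
        full <- all(unique(labels) %in% labels[in_test]) &&
          all(unique(labels) %in% labels[!in_test])
        if (full) {
          ok <- TRUE
          break
        }
        if (try > 100 &&
            all(unique(labels) %in% labels[!in_test]) &&
            length(unique(labels[in_test])) >= 2) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not realize a grouped split with every class in training")
    }
    balance <- function(idx) {
      tab <- table(labels[idx])
      n_min <- min(tab)
      unlist(lapply(names(tab), function(cl) {
        i <- idx[labels[idx] == cl]
        if (length(i) > n_min) sample(i, n_min) else i
      }), use.names = FALSE)
    }
    tr <- balance(which(!in_test))
    te <- balance(which(in_test))
    list(train = data[sort(tr), , drop = FALSE],
         test = data[sort(te), , drop = FALSE])
  })
}

#' Odds ratio of a classifier's accuracy to chance
#'
#' `(acc / (1 - acc)) / (p0 / (1 - p0))` with `p0 = 1 / n_classes`; 1 means
#' no better than random guessing. By convention an accuracy of exactly 1
#' returns `Inf` and exactly 0 returns 0.
#'
#' @param accuracy Proportion correct in \[0, 1\].
#' @param n_classes Number of balanced classes (>= 2).
#' @return Nonnegative odds ratio.
#' @export
odds_ratio_to_chance <- function(accuracy, n_classes) {
  stopifnot(all(accuracy >= 0 & accuracy <= 1), n_classes >= 2)
  p0 <- 1 / n_classes
  odds0 <- p0 / (1 - p0)
  ifelse(accuracy >= 1, Inf,
         ifelse(accuracy <= 0, 0, (accuracy / (1 - accuracy)) / odds0))
}

fit_rf <- function(train, test, target, predictors, num_trees, seed) {
  bad <- !stats::complete.cases(train[, predictors, drop = FALSE]) |
    !apply(is.finite(as.matrix(train[, predictors, drop = FALSE])), 1, all)
  if (any(bad)) {
    ids <- if ("cry_id" %in% names(train)) train$cry_id[bad] else which(bad)
    stop("non-finite features in cries: ", paste(utils::head(ids, 5), collapse = ", "))
  }
  train[[target]] <- factor(train[[target]])
  fit <- ranger::ranger(
    dependent.variable.name = target,
    data = train[, c(target, predictors), drop = FALSE],
    num.trees = num_trees, importance = "impurity", seed = seed,
    num.threads = 1, respect.unordered.factors = TRUE
  )
  pred <- stats::predict(fit, data = test[, predictors, drop = FALSE],
                         num.threads = 1, seed = seed)$predictions
  list(accuracy = mean(as.character(pred) == as.character(test[[target]])),
       importance = fit$variable.importance)
}

#' Repeated session-grouped random-forest experiment
#'
#' The core information test: can an ensemble of decision trees (random
#' forest; 500 trees, sqrt(p) candidate features per split) predict the
#' target label from the ten acoustic descriptors better than chance, when
#' training and testing never share a recording session and classes are
#' balanced by downsampling? Each of `n_runs` repetitions redraws the
#' grouped split; performance is summarized by the median accuracy, the
#' empirical 2.5%/97.5% coverage interval, and the odds ratio to chance.
#'
#' @param data Data frame with predictor columns, the target column, and the
#'   grouping column.
#' @param target Name of the label column (e.g. `"baby_id"`, `"cause"`,
#'   `"sex"`, `"age_months"`).
#' @param predictors Predictor column names (default the ten descriptors).
#' @param group_key Grouping column (default `"session_id"`; `NULL` for the
#'   naive per-cry split).
#' @param n_runs Number of repetitions (default 100).
#' @param num_trees Trees per forest (default 500).
#' @param test_fraction Fraction of groups for testing (default 1/3).
#' @param seed Integer seed.
#' @return An object of class `cry_experiment`: list with `target`,
#'   `accuracies`, `median_accuracy`, `coverage_95`, `chance`, `odds_ratio`,
#'   `or_coverage_95`, `n_classes`, `importance` (mean impurity importance,
#'   sorted), `n_runs`.
#' @export
run_experiment <- function(data, target, predictors = intersect(feature_names(), names(data)),
                           group_key = "session_id", n_runs = 100,
                           num_trees = 500, test_fraction = 1 / 3, seed = 1L) {
  data <- tibble::as_tibble(data)
  stopifnot(target %in% names(data), length(predictors) > 0)
  data[[target]] <- as.character(data[[target]])
  n_classes <- length(unique(data[[target]]))
  stopifnot(n_classes >= 2)
  accs <- numeric(n_runs)
  imps <- matrix(0, n_runs, length(predictors),
                 dimnames = list(NULL, predictors))
  for (r in seq_len(n_runs)) {
    sp <- grouped_split(data, stratify_by = target, group_key = group_key,
                        test_fraction = test_fraction, seed = seed + 7919L * r)
    fr <- fit_rf(sp$train, sp$test, target, predictors, num_trees,
                 seed = seed + 104729L * r)
    accs[r] <- fr$accuracy
    imps[r, names(fr$importance)] <- fr$importance
  }
  med <- stats::median(accs)
  cov <- stats::quantile(accs, c(0.025, 0.975), names = FALSE)
  structure(list(
    target = target,
    accuracies = accs,
    median_accuracy = med,
    coverage_95 = cov,
    chance = 1 / n_classes,
    odds_ratio = odds_ratio_to_chance(med, n_classes),
    or_coverage_95 = odds_ratio_to_chance(cov, n_classes),
    n_classes = n_classes,
    importance = sort(colMeans(imps), decreasing = TRUE),
    n_runs = n_runs
  ), class = "cry_experiment")
}

#' @export
print.cry_experiment <- function(x, ...) {
  cat(sprintf(
    "Cry experiment: target = %s (%d classes, chance %.1f%%)\n", x$target,
    x$n_classes, 100 * x$chance))
  cat(sprintf("  median accuracy %.1f%% [%.1f, %.1f] over %d runs\n",
              100 * x$median_accuracy, 100 * x$coverage_95[1],
              100 * x$coverage_95[2], x$n_runs))
  cat(sprintf("  odds ratio to chance %.2f [%.2f, %.2f]\n", x$odds_ratio,
              x$or_coverage_95[1], x$or_coverage_95[2]))
  cat("  top predictor:", names(x$importance)[1], "\n")
  invisible(x)
}

#' Test-retest transfer matrix across age groups
#'
#' Trains a classifier on cries from one age group and tests it on every age
#' group (columns = training age, rows = testing age), restricted to babies
#' recorded at all ages so the panel is complete. Train and test sets never
#' share a session, including on the diagonal. Entries are median odds
#' ratios to chance over `n_runs` splits.
#'
#' @param data Data frame with predictors, `target` column, `age_months` and
#'   `session_id`.
#' @param target Label column (default `"baby_id"`).
#' @param predictors Predictor columns.
#' @param n_runs Splits per cell (default 25).
#' @param num_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @return A square matrix of odds ratios (dimnames = age groups), class
#'   `test_retest`, with the accuracy array in attribute `accuracies`.
#' @export
test_retest <- function(data, target = "baby_id",
                        predictors = intersect(feature_names(), names(data)),
                        n_runs = 25, num_trees = 500, seed = 1L) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c(target, "age_months", "session_id") %in% names(data)))
  ages <- sort(unique(data$age_months))
  # keep only classes observed at every age
  keep <- names(which(vapply(
    split(data$age_months, data[[target]]),
    function(a) all(ages %in% a), logical(1))))
  if (length(keep) < 2) stop("fewer than 2 classes present at all ages")
  data <- data[data[[target]] %in% keep, , drop = FALSE]
  n_classes <- length(keep)
  K <- length(ages)
  acc <- array(NA_real_, c(K, K, n_runs))
  for (j in seq_len(K)) {
    d_train_age <- data[data$age_months == ages[j], , drop = FALSE]
    for (r in seq_len(n_runs)) {
      sp <- grouped_split(d_train_age, stratify_by = target,
                          seed = seed + 7919L * r + 104729L * j)
      used <- unique(sp$train$session_id)
      for (i in seq_len(K)) {
        d_test <- if (i == j) {
          sp$test
        } else {
          pool <- data[data$age_months == ages[i] &
                         !(data$session_id %in% used), , drop = FALSE]
          balance_classes(pool, target, seed = seed + r + 13L * i + 37L * j)
        }
        if (nrow(d_test) == 0) next
        acc[i, j, r] <- fit_rf(sp$train, d_test, target, predictors,
                               num_trees, seed = seed + r + 17L * i + 41L * j)$accuracy
      }
    }
  }
  or <- apply(acc, c(1, 2), function(a) {
    odds_ratio_to_chance(stats::median(a, na.rm = TRUE), n_classes)
  })
  dimnames(or) <- list(test_age = ages, train_age = ages)
  structure(or, accuracies = acc, n_classes = n_classes, class = "test_retest")
}

balance_classes <- function(data, target, seed = 1L) {
  labels <- as.character(data[[target]])
  with_seed(seed, {
    tab <- table(labels)
    n_min <- min(tab)
    idx <- unlist(lapply(names(tab), function(cl) {
      i <- which(labels == cl)
      if (length(i) > n_min) sample(i, n_min) else i
    }), use.names = FALSE)
    data[sort(idx), , drop = FALSE]
  })
}

#' Per-baby cry-cause models
#'
#' For each focal baby with at least 2 sessions and all three causes, trains
#' a cause classifier on the focal baby's cries (session-grouped split) and
#' tests it (a) on the focal baby's held-out sessions and (b) on all other
#' babies' cries — probing whether any baby has a private acoustic code for
#' cry cause, and whether such a code transfers.
#'
#' @param data Data frame with predictors, `cause`, `baby_id`, `session_id`.
#' @param predictors Predictor columns.
#' @param n_runs Splits per baby (default 20).
#' @param num_trees Trees per forest (default 300).
#' @param seed Integer seed.
#' @return Tibble: `baby_id`, `n_sessions`, `same_or`, `other_or` (median
#'   odds ratios to chance).
#' @export
per_baby_cause_models <- function(data, predictors = intersect(feature_names(), names(data)),
                                  n_runs = 20, num_trees = 300, seed = 1L) {
  data <- tibble::as_tibble(data)
  causes <- sort(unique(data$cause))
  n_classes <- length(causes)
  eligible <- vapply(split(data, data$baby_id), function(d) {
    length(unique(d$session_id)) >= 2 && all(causes %in% d$cause)
  }, logical(1))
  out <- list()
  for (b in names(which(eligible))) {
    focal <- data[data$baby_id == b, , drop = FALSE]
    others <- data[data$baby_id != b, , drop = FALSE]
    same_acc <- other_acc <- rep(NA_real_, n_runs)
    for (r in seq_len(n_runs)) {
      sp <- tryCatch(
        grouped_split(focal, stratify_by = "cause",
                      seed = seed + 7919L * r + utf8ToInt(substr(b, 2, 2))),
        error = function(e) NULL
      )
      if (is.null(sp)) next
      same_acc[r] <- fit_rf(sp$train, sp$test, "cause", predictors, num_trees,
                            seed = seed + r)$accuracy
      ob <- balance_classes(others, "cause", seed = seed + 31L * r)
      other_acc[r] <- fit_rf(sp$train, ob, "cause", predictors, num_trees,
                             seed = seed + 2L * r)$accuracy
    }
    if (all(is.na(same_acc))) next
    out[[b]] <- tibble::tibble(
      baby_id = b,
      n_sessions = length(unique(focal$session_id)),
      same_or = odds_ratio_to_chance(stats::median(same_acc, na.rm = TRUE), n_classes),
      other_or = odds_ratio_to_chance(stats::median(other_acc, na.rm = TRUE), n_classes)
    )
  }
  dplyr::bind_rows(out)
}

#' Between-baby acoustic distance matrices per cry cause
#'
#' Summarizes each baby in each cause by the mean normalized descriptor
#' vector of its cries, computes the Euclidean baby-by-baby distance matrix
#' per cause, and correlates the matrices' upper triangles (with a
#' permutation p-value over babies). Correlated matrices would indicate
#' sub-groups of babies sharing a cause-coding strategy. The default
#' within-baby normalization isolates each baby's cause-specific deviation:
#' under global normalization the stable individual signature dominates
#' every cause's matrix and correlates them trivially, regardless of any
#' cause coding.
#'
#' @param data Data frame with descriptor columns, `baby_id` and `cause`;
#'   only babies with cries in every cause are used.
#' @param predictors Descriptor columns.
#' @param scope Normalization scope, `"within_baby"` (default) or
#'   `"global"`.
#' @param n_perm Permutations for the p-value (default 999).
#' @param seed Integer seed.
#' @return List with `matrices` (named list of symmetric matrices),
#'   `correlations` (tibble: `pair`, `r`, `p_perm`), `n_pairs`, `babies`.
#' @export
context_distances <- function(data, predictors = intersect(feature_names(), names(data)),
                              scope = c("within_baby", "global"),
                              n_perm = 999, seed = 1L) {
  scope <- match.arg(scope)
  data <- tibble::as_tibble(data)
  causes <- sort(unique(data$cause))
  have_all <- vapply(split(data$cause, data$baby_id),
                     function(cc) all(causes %in% cc), logical(1))
  babies <- sort(names(which(have_all)))
  if (length(babies) < 3) stop("need >= 3 babies with cries in every cause")
  data <- data[data$baby_id %in% babies, , drop = FALSE]
  data <- normalize_features(data, scope, predictors)
  mats <- lapply(causes, function(cs) {
    d <- data[data$cause == cs, , drop = FALSE]
    centro <- t(vapply(babies, function(b) {
      colMeans(as.matrix(d[d$baby_id == b, predictors, drop = FALSE]))
    }, numeric(length(predictors))))
    as.matrix(stats::dist(centro))
  })
  names(mats) <- causes
  ut <- function(m) m[upper.tri(m)]
  pairs <- utils::combn(causes, 2)
  cors <- with_seed(seed, {
    lapply(seq_len(ncol(pairs)), function(k) {
      a <- mats[[pairs[1, k]]]
      b <- mats[[pairs[2, k]]]
      r_obs <- stats::cor(ut(a), ut(b))
      r_perm <- vapply(seq_len(n_perm), function(i) {
        p <- sample(nrow(b))
        stats::cor(ut(a), ut(b[p, p]))
      }, numeric(1))
      tibble::tibble(
        pair = paste(pairs[1, k], pairs[2, k], sep = "-"),
        r = r_obs,
        p_perm = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
      )
    })
  })
  list(matrices = mats, correlations = dplyr::bind_rows(cors),
       n_pairs = length(babies) * (length(babies) - 1) / 2, babies = babies)
}

#' Per-feature age slopes and sex contrasts
#'
#' A deliberately simple frequentist estimator of developmental drift:
#' per baby and feature, an ordinary least-squares slope of the feature
#' against age (months), expressed in SD units per month by dividing by the
#' residual SD of that same fit (z-scoring against the baby's *total* SD
#' would fold the drift itself into the unit and attenuate every slope
#' toward zero). Slopes are aggregated across babies by a precision-weighted
#' mean, with a cluster bootstrap over babies for the 95% CI (normal
#' approximation with a t critical value on the bootstrap SE — percentile
#' intervals undercover with the few clusters typical of such cohorts). If a baby's
#' residual SD is exactly 0 (noise-free data) the raw slope is returned
#' unscaled. The sex contrast (M - F) is computed from per-baby mean
#' features under global normalization (within-baby normalization removes
#' between-baby, hence between-sex, differences by construction), with the
#' same cluster bootstrap.
#'
#' @param data Data frame with descriptor columns, `baby_id`, `sex`,
#'   `age_months` (raw, un-normalized features).
#' @param predictors Descriptor columns.
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return Tibble: `feature`, `age_slope` (SD/month), `slope_lo`, `slope_hi`,
#'   `sex_contrast` (SD units), `sex_lo`, `sex_hi`, `n_slope_babies`.
#' @export
estimate_age_sex_effects <- function(data, predictors = intersect(feature_names(), names(data)),
                                     n_boot = 500, seed = 1L) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("baby_id", "sex", "age_months") %in% names(data)))
  gdata <- normalize_features(data, "global", predictors)

  babies <- unique(data$baby_id)
  multi_age <- vapply(split(data$age_months, data$baby_id),
                      function(a) length(unique(a)) >= 2, logical(1))
  slope_babies <- intersect(babies, names(which(multi_age)))
  if (length(slope_babies) < length(babies)) {
    message(length(babies) - length(slope_babies),
            " baby/babies with a single age excluded from slope estimation")
  }
  if (length(slope_babies) == 0) stop("no baby recorded at >= 2 ages")

  slope_tab <- lapply(slope_babies, function(b) {
    d <- data[data$baby_id == b, , drop = FALSE]
    t(vapply(predictors, function(f) {
      fit <- stats::lm(d[[f]] ~ d$age_months)
      sm <- summary(fit)
      sigma <- sm$sigma
      co <- sm$coefficients
      if (nrow(co) < 2) return(c(slope = 0, w = NA_real_))
      if (!is.finite(sigma) || sigma == 0) {
        return(c(slope = unname(co[2, 1]), w = NA_real_))
      }
      se <- co[2, 2] / sigma
      c(slope = co[2, 1] / sigma,
        w = if (is.finite(se) && se > 0) 1 / se^2 else NA_real_)
    }, numeric(2)))
  })
  names(slope_tab) <- slope_babies

  sexes <- vapply(split(data$sex, data$baby_id), function(s) s[1], character(1))
  baby_means <- matrix(
    vapply(babies, function(b) {
      colMeans(as.matrix(gdata[gdata$baby_id == b, predictors, drop = FALSE]))
    }, numeric(length(predictors))),
    nrow = length(babies), ncol = length(predictors), byrow = TRUE,
    dimnames = list(babies, predictors)
  )

  agg_slope <- function(ids) {
    vapply(predictors, function(f) {
      s <- vapply(ids, function(b) slope_tab[[b]][f, "slope"], numeric(1))
      w <- vapply(ids, function(b) slope_tab[[b]][f, "w"], numeric(1))
      if (all(is.na(w))) return(mean(s, na.rm = TRUE))
      w[is.na(w)] <- stats::median(w, na.rm = TRUE)
      sum(w * s) / sum(w)
    }, numeric(1))
  }
  agg_sex <- function(ids) {
    m <- baby_means[ids, , drop = FALSE]
    sx <- sexes[ids]
    if (length(unique(sx)) < 2) return(rep(NA_real_, length(predictors)))
    colMeans(m[sx == "M", , drop = FALSE]) - colMeans(m[sx == "F", , drop = FALSE])
  }

  point_slope <- agg_slope(slope_babies)
  point_sex <- agg_sex(babies)

  boot <- with_seed(seed, {
    bs <- matrix(NA_real_, n_boot, length(predictors))
    bx <- matrix(NA_real_, n_boot, length(predictors))
    for (i in seq_len(n_boot)) {
      bs[i, ] <- agg_slope(sample(slope_babies, replace = TRUE))
      bx[i, ] <- agg_sex(sample(babies, replace = TRUE))
    }
    list(slope = bs, sex = bx)
  })
  tcrit_s <- stats::qt(0.975, max(1, length(slope_babies) - 1))
  tcrit_x <- stats::qt(0.975, max(1, length(babies) - 1))
  se_s <- apply(boot$slope, 2, stats::sd, na.rm = TRUE)
  se_x <- apply(boot$sex, 2, stats::sd, na.rm = TRUE)
  tibble::tibble(
    feature = predictors,
    age_slope = unname(point_slope),
    slope_lo = unname(point_slope - tcrit_s * se_s),
    slope_hi = unname(point_slope + tcrit_s * se_s),
    sex_contrast = unname(point_sex),
    sex_lo = unname(point_sex - tcrit_x * se_x),
    sex_hi = unname(point_sex + tcrit_x * se_x),
    n_slope_babies = length(slope_babies)
  )
}
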