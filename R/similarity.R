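#' Default contour features used for DTW
#'
#' Pitch in semitones (ratio-scaled), harmonicity in dB, Wiener entropy, and
#' spectral centroid in kHz.
#'
#' @return Character vector of contour column names.
#' @export
dtw_features <- function() c("pitch_st", "hnr_db", "entropy", "centroid_khz")

# Last-observation-carried-forward; leading gaps take the first value.
locf <- function(x) {
  if (all(is.na(x))) return(rep(0, length(x)))
  first <- which(!is.na(x))[1]
  x[seq_len(first - 1)] <- x[first]
  for (i in seq_along(x)) if (is.na(x[i])) x[i] <- x[i - 1]
  x
}

#' Prepare contour matrices for DTW
#'
#' Imputes missing (unvoiced) values by last-observation-carried-forward
#' within each cry (leading gaps by the first observed value) and z-scores
#' each feature globally across the whole collection, so that every feature
#' contributes on a comparable scale.
#'
#' @param contours List of contour tibbles from [frame_analysis()].
#' @param features Contour columns to use (default [dtw_features()]).
#' @return List of numeric matrices (frames x features).
#' @export
prepare_contours <- function(contours, features = dtw_features()) {
  stopifnot(length(contours) >= 1)
  mats <- lapply(contours, function(ct) {
    stopifnot(all(features %in% names(ct)))
    m <- as.matrix(ct[, features, drop = FALSE])
    apply(m, 2, locf)
  })
  mats <- lapply(mats, function(m) matrix(m, ncol = length(features),
                                          dimnames = list(NULL, features)))
  all_rows <- do.call(rbind, mats)
  mu <- colMeans(all_rows)
  sg <- apply(all_rows, 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  lapply(mats, function(m) sweep(sweep(m, 2, mu), 2, sg, "/"))
}

#' Dynamic time warping distance between two acoustic contours
#'
#' Classic DTW with the symmetric step pattern (diagonal, horizontal,
#' vertical), Euclidean local cost over the feature vector, and total path
#' cost divided by path length so longer cries are not penalized.
#' `dtw_distance(a, a) = 0` and the distance is symmetric. Inputs are
#' numeric matrices (frames x features) that have already been imputed and
#' scaled (see [prepare_contours()]), or contour tibbles which are prepared
#' as a pair.
#'
#' @param a,b Numeric matrices with identical feature columns, or contour
#'   tibbles.
#' @param features Contour columns when tibbles are given.
#' @return Nonnegative scalar distance.
#' @export
dtw_distance <- function(a, b, features = dtw_features()) {
  if (is.data.frame(a) || is.data.frame(b)) {
    pr <- prepare_contours(list(a, b), features)
    a <- pr[[1]]; b <- pr[[2]]
  }
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty contour")
  .dtw_core(a, b)
}

#' Pairwise DTW distance matrix over a set of cries
#'
#' Computes the full pairwise DTW distance matrix on the (optionally
#' subsampled) contour set. Subsampling is proportional within the classes
#' of `labels` when given. Computing the matrix once and embedding it is far
#' cheaper than using DTW as a metric inside an embedding algorithm.
#'
#' @param contours Named list of contour tibbles.
#' @param subsample Optional number of cries to keep.
#' @param labels Optional class labels (same length) for proportional
#'   subsampling.
#' @param features Contour columns (default [dtw_features()]).
#' @param seed Integer seed for subsampling.
#' @return A symmetric matrix with zero diagonal; rownames are the contour
#'   names; kept indices in attribute `kept`.
#' @export
distance_matrix <- function(contours, subsample = NULL, labels = NULL,
                            features = dtw_features(), seed = 1L) {
  n_all <- length(contours)
  stopifnot(n_all >= 2)
  idx <- seq_len(n_all)
  if (!is.null(subsample) && subsample < n_all) {
    idx <- with_seed(seed, {
      if (is.null(labels)) {
        sort(sample.int(n_all, subsample))
      } else {
        stopifnot(length(labels) == n_all)
        tab <- table(labels)
        take <- pmax(1, round(subsample * as.numeric(tab) / n_all))
        sort(unlist(lapply(seq_along(tab), function(k) {
          i <- which(labels == names(tab)[k])
          sample(i, min(length(i), take[k]))
        }), use.names = FALSE))
      }
    })
  }
  mats <- prepare_contours(contours[idx], features)
  n <- length(mats)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- .dtw_core(mats[[i]], mats[[j]])
    }
  }
  nm <- names(contours)[idx]
  if (!is.null(nm)) dimnames(D) <- list(nm, nm)
  attr(D, "kept") <- idx
  D
}

#' Project a cry distance matrix to 2D
#'
#' Embeds a precomputed (DTW) distance matrix into two dimensions with
#' non-metric multidimensional scaling (initialized from classical MDS, so
#' the result is deterministic for a given matrix), or plain classical MDS.
#'
#' @param dist_matrix Symmetric nonnegative matrix with zero diagonal.
#' @param method `"nmds"` (default) or `"pcoa"`.
#' @param seed Integer seed, recorded in the output (the embedding itself is
#'   deterministic).
#' @return A tibble with `cry_id` (rownames or index), `x`, `y`; parameters
#'   in attribute `params`.
#' @export
embed_cries <- function(dist_matrix, method = c("nmds", "pcoa"), seed = 1L) {
  method <- match.arg(method)
  D <- as.matrix(dist_matrix)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 points to embed")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  # strictly positive off-diagonal required by isoMDS; jitter exact ties
  eps <- max(D) * 1e-9 + 1e-12
  Dp <- D + eps
  diag(Dp) <- 0
  init <- stats::cmdscale(Dp, k = 2)
  if (ncol(init) < 2) init <- cbind(init, 0)
  coords <- if (method == "nmds") {
    utils::capture.output(fit <- MASS::isoMDS(stats::as.dist(Dp), y = init, k = 2))
    fit$points
  } else {
    init
  }
  out <- tibble::tibble(
    cry_id = if (!is.null(rownames(D))) rownames(D) else as.character(seq_len(n)),
    x = coords[, 1], y = coords[, 2]
  )
  attr(out, "params") <- list(method = method, seed = seed)
  out
}

#' Silhouette-based cluster separation of a labelling
#'
#' Mean silhouette width of the labelling, computed on the distance matrix
#' (preferred) or on the 2D embedding coordinates. Near 1 means tight,
#' separated label clusters; near 0 means the labelling does not structure
#' the acoustic space.
#'
#' @param x Distance matrix, or an embedding tibble with `x`, `y`.
#' @param labels Vector of labels (>= 2 distinct values).
#' @return Mean silhouette width (scalar).
#' @export
cluster_separation <- function(x, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need >= 2 distinct labels")
  if (is.data.frame(x)) {
    D <- as.matrix(stats::dist(cbind(x$x, x$y)))
  } else {
    D <- as.matrix(x)
  }
  stopifnot(length(labels) == nrow(D))
  sil <- cluster::silhouette(labels, dmatrix = D)
  mean(sil[, "sil_width"])
}
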