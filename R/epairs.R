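#' Mean nearest-neighbor angles of a coding-vector cloud
#'
#' For each vector (row), the mean angle to its `k` nearest neighbors, where
#' neighborhood and angle both use the angular metric. With `fold = TRUE`
#' (default) antipodal vectors are identified — the angle is
#' `acos(|cos similarity|)`, in `[0, 90]` degrees — because the sign of a mode
#' weight encodes trial-type preference rather than a distinct profile. Scale
#' invariant: row lengths do not matter.
#'
#' @param vectors n x d numeric matrix (rows = neurons); all-zero rows are
#'   dropped with a message.
#' @param k Number of nearest neighbors, `1 <= k < n`.
#' @param fold Identify antipodal vectors?
#' @return Numeric vector of per-point mean angles in degrees.
#' @export
nn_angles <- function(vectors, k = 3, fold = TRUE) {
  X <- as.matrix(vectors)
  if (ncol(X) < 2) stop("need d >= 2 dimensions")
  zero <- rowSums(X^2) == 0
  if (any(zero)) {
    message(sprintf("dropping %d all-zero coding vectors", sum(zero)))
    X <- X[!zero, , drop = FALSE]
  }
  n <- nrow(X)
  if (!(k >= 1 && k < n)) stop("need n > k >= 1")
  as.numeric(nn_angles_cpp(X, as.integer(k), fold)) * 180 / pi
}

#' ePAIRS test for clustered (non-uniformly mixed) coding vectors
#'
#' Monte-Carlo test of whether a cloud of coding vectors (PC loadings or
#' activity-mode weights) is clustered rather than a uniform elliptical
#' continuum. The statistic is the median over points of the mean
#' nearest-neighbor angle; the null resamples `n` vectors from a zero-mean
#' Gaussian with per-dimension variances matched to the data (diagonal
#' covariance in the analysis basis). The p-value is the fraction of null
#' medians less than or equal to the empirical median, so small p indicates
#' clustering (unusually small nearest-neighbor angles).
#'
#' @inheritParams nn_angles
#' @param n_null Number of null replicates (values below 100 trigger a
#'   resolution warning).
#' @param seed Integer seed; the test is deterministic given it.
#' @return Object of class `epairs_result`: `list(angles, median_angle,
#'   null_medians, p_value, k, n, d, n_null, fold, seed)`, angles in degrees.
#' @export
epairs_test <- function(vectors, k = 3, n_null = 10000, seed = 1, fold = TRUE) {
  X <- as.matrix(vectors)
  zero <- rowSums(X^2) == 0
  if (any(zero)) X <- X[!zero, , drop = FALSE]
  n <- nrow(X)
  if (n < 20) warning("fewer than 20 vectors; ePAIRS p-value will be unstable")
  if (n_null < 100) warning("n_null < 100 gives a coarse p-value resolution")
  ang <- nn_angles(X, k = k, fold = fold)
  emp <- median(ang)
  sds <- apply(X, 2, sd)
  nulls <- with_seed(seed,
    epairs_null_medians_cpp(n, sds, as.integer(k), as.integer(n_null), fold)) *
    180 / pi
  p <- mean(nulls <= emp)
  structure(list(angles = ang, median_angle = emp, null_medians = nulls,
                 p_value = p, k = k, n = n, d = ncol(X), n_null = n_null,
                 fold = fold, seed = seed),
            class = "epairs_result")
}

#' @export
print.epairs_result <- function(x, ...) {
  cat(sprintf("ePAIRS: n=%d d=%d k=%d  median NN angle %.2f deg  (null median %.2f)  p = %.4g\n",
              x$n, x$d, x$k, x$median_angle, median(x$null_medians), x$p_value))
  invisible(x)
}

#' ePAIRS sensitivity sweep over k (and dimensionality)
#'
#' Re-runs [epairs_test()] across a range of neighbor counts and retained
#' dimensions, for robustness reporting.
#'
#' @inheritParams epairs_test
#' @param k_range Integer vector of k values.
#' @param d_range Integer vector of leading-dimension counts (default: all
#'   columns).
#' @return data.frame with columns `k`, `d`, `median_angle`, `p_value`.
#' @export
epairs_sensitivity <- function(vectors, k_range = 1:10, d_range = NULL,
                               n_null = 1000, seed = 1, fold = TRUE) {
  X <- as.matrix(vectors)
  d_range <- d_range %||% ncol(X)
  out <- list()
  for (d in d_range) {
    for (k in k_range) {
      r <- epairs_test(X[, seq_len(d), drop = FALSE], k = k, n_null = n_null,
                       seed = seed, fold = fold)
      out[[length(out) + 1L]] <- data.frame(k = k, d = d,
                                            median_angle = r$median_angle,
                                            p_value = r$p_value)
    }
  }
  do.call(rbind, out)
}
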