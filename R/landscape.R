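#' PCA reduction of the response matrix
#'
#' Column-centered principal component analysis of the n x t response matrix;
#' neurons are represented by their loadings (scores) on the top components.
#'
#' @param pm A `psth_matrix` or plain numeric matrix (rows = neurons).
#' @param n_components Number of components to keep, or
#' @param variance_fraction keep the smallest d reaching this cumulative
#'   explained-variance fraction (e.g. 0.98).
#' @return Object of class `pc_loadings`: `list(loadings, explained, d,
#'   unit_ids, rotation, center)`.
#' @export
pca_reduce <- function(pm, n_components = NULL, variance_fraction = NULL) {
  M <- if (inherits(pm, "psth_matrix")) pm$matrix else as.matrix(pm)
  if (nrow(M) < 2) stop("need at least 2 rows")
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  evar <- pc$sdev^2
  if (sum(evar) == 0) stop("degenerate (rank-0) matrix")
  frac <- evar / sum(evar)
  d <- if (!is.null(n_components)) {
    min(n_components, length(frac))
  } else if (!is.null(variance_fraction)) {
    which(cumsum(frac) >= variance_fraction - 1e-12)[1]
  } else {
    stop("give n_components or variance_fraction")
  }
  structure(list(loadings = pc$x[, seq_len(d), drop = FALSE],
                 explained = frac, d = d,
                 unit_ids = rownames(M) %||% as.character(seq_len(nrow(M))),
                 rotation = pc$rotation[, seq_len(d), drop = FALSE],
                 center = pc$center),
            class = "pc_loadings")
}

cosine_dist <- function(X) {
  Xn <- X / sqrt(rowSums(X^2))
  D <- 1 - tcrossprod(Xn)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' t-SNE embedding of neuron loadings
#'
#' Two-dimensional t-SNE on the cosine-distance matrix of the PC loadings,
#' restarted `restarts` times (seeds `seed .. seed+restarts-1`); the embedding
#' with the lowest final Kullback-Leibler divergence is returned.
#'
#' @param loadings A `pc_loadings` or numeric matrix.
#' @param perplexity t-SNE perplexity (requires `n >= 3*perplexity + 2`).
#' @param metric `"cosine"` or `"euclidean"`.
#' @param restarts Number of random restarts.
#' @param seed Base seed.
#' @param ... Passed to [Rtsne::Rtsne()] (e.g. `max_iter`).
#' @return Object of class `embedding2d`: `list(coords, kl, restart,
#'   perplexity, unit_ids)`.
#' @export
embed_tsne <- function(loadings, perplexity = 50, metric = c("cosine", "euclidean"),
                       restarts = 10, seed = 1, ...) {
  metric <- match.arg(metric)
  X <- if (inherits(loadings, "pc_loadings")) loadings$loadings else as.matrix(loadings)
  n <- nrow(X)
  if (n < 3 * perplexity + 2) {
    stop(sprintf("n = %d too small for perplexity %g; lower the perplexity (need n >= 3*perplexity + 2)",
                 n, perplexity))
  }
  D <- if (metric == "cosine") stats::as.dist(cosine_dist(X)) else stats::dist(X)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(substream_seed(seed, 10, r), {
      Rtsne::Rtsne(D, is_distance = TRUE, dims = 2, perplexity = perplexity,
                   pca = FALSE, ...)
    })
    kl <- tail(fit$itercosts, 1)
    if (is.null(best) || kl < best$kl) {
      best <- list(coords = fit$Y, kl = kl, restart = r)
    }
  }
  ids <- if (inherits(loadings, "pc_loadings")) loadings$unit_ids else
    rownames(X) %||% as.character(seq_len(n))
  rownames(best$coords) <- ids
  structure(list(coords = best$coords, kl = best$kl, restart = best$restart,
                 perplexity = perplexity, unit_ids = ids),
            class = "embedding2d")
}

#' Density-peak clustering
#'
#' Clustering by local density: each point gets a Gaussian-kernel local
#' density `rho` (bandwidth `dc` = `dc_frac` of the point-cloud diameter) and
#' the distance `delta` to its nearest neighbor of higher density (the global
#' density maximum takes the largest pairwise distance). Cluster centers are
#' points with extreme `gamma = rho_scaled * delta_scaled` (both min-max
#' scaled); remaining points join, in order of decreasing density, the cluster
#' of their nearest higher-density neighbor.
#'
#' Center selection is either a requested count (`n_centers`), an explicit set
#' of indices (`centers`, mirroring the original manual selection), or the
#' automatic default: the largest multiplicative gap in the sorted `gamma`
#' sequence.
#'
#' @param embedding An `embedding2d`, or a numeric matrix of coordinates.
#' @param n_centers Optional number of cluster centers.
#' @param centers Optional explicit center indices (manual selection).
#' @param dc_frac Density bandwidth as a fraction of the cloud diameter.
#' @param max_centers Cap on the auto-selected number of centers.
#' @return Object of class `density_peak`: `list(rho, delta, gamma, centers,
#'   labels, dc)` with integer labels `1..n_centers`.
#' @export
density_peak_cluster <- function(embedding, n_centers = NULL, centers = NULL,
                                 dc_frac = 0.02, max_centers = 30) {
  X <- if (inherits(embedding, "embedding2d")) embedding$coords else as.matrix(embedding)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 points")
  D <- as.matrix(stats::dist(X))
  diam <- max(D)
  if (diam == 0) {
    warning("all points identical; returning a single cluster")
    return(structure(list(rho = rep(1, n), delta = rep(0, n), gamma = rep(0, n),
                          centers = 1L, labels = rep(1L, n), dc = 0),
                     class = "density_peak"))
  }
  dc <- dc_frac * diam
  rho <- rowSums(exp(-(D / dc)^2)) - 1
  # deterministic tie-break on equal densities: earlier index counts as denser
  ord <- order(rho, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1]] <- max(D[ord[1], ])
  nn_higher[ord[1]] <- NA_integer_
  for (r in 2:n) {
    i <- ord[r]
    higher <- ord[1:(r - 1)]
    j <- higher[which.min(D[i, higher])]
    delta[i] <- D[i, j]
    nn_higher[i] <- j
  }
  sc <- function(x) (x - min(x)) / max(1e-300, diff(range(x)))
  gamma <- sc(rho) * sc(delta)
  if (!is.null(centers)) {
    centers <- as.integer(centers)
  } else if (!is.null(n_centers)) {
    n_centers <- min(n_centers, n)
    centers <- order(gamma, decreasing = TRUE)[seq_len(n_centers)]
  } else {
    gs <- sort(gamma, decreasing = TRUE)
    m <- min(max_centers, n - 1)
    # floored ratio gap: the 5% floor keeps noise among near-zero gamma
    # values from masquerading as a gap
    floor_c <- 0.05 * gs[1]
    ratios <- (gs[1:m] + floor_c) / (gs[2:(m + 1)] + floor_c)
    ncl <- which.max(ratios)
    centers <- order(gamma, decreasing = TRUE)[seq_len(ncl)]
  }
  labels <- integer(n)
  labels[centers] <- seq_along(centers)
  for (r in seq_len(n)) {
    i <- ord[r]
    if (labels[i] == 0L) labels[i] <- labels[nn_higher[i]]
  }
  structure(list(rho = rho, delta = delta, gamma = gamma,
                 centers = centers, labels = labels, dc = dc),
            class = "density_peak")
}

#' Mean response profiles of clusters
#'
#' @param pm A `psth_matrix` (or plain matrix with rows matching `labels`).
#' @param labels Integer cluster labels per row.
#' @return k x t matrix of cluster-mean profiles (rows named by label).
#' @export
cluster_mean_profiles <- function(pm, labels) {
  M <- if (inherits(pm, "psth_matrix")) pm$matrix else as.matrix(pm)
  stopifnot(nrow(M) == length(labels))
  ms <- rowsum(M, labels) / as.vector(table(labels))
  ms
}

#' Merge clusters with nearly identical mean profiles
#'
#' Greedy correction for over-clustering: repeatedly merges the cluster pair
#' whose mean-profile Pearson correlation is highest, while it exceeds
#' `r_threshold`, recomputing means after each merge.
#'
#' @param result A `density_peak` result (or any list with `labels`).
#' @param pm The `psth_matrix` the labels refer to.
#' @param r_threshold Correlation threshold above which clusters merge.
#' @return The result with updated `labels` (relabeled `1..k`) and a
#'   `merge_log` data.frame (`from`, `into`, `r`).
#' @export
merge_similar_clusters <- function(result, pm, r_threshold = 0.95) {
  labels <- result$labels
  log <- list()
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2) break
    means <- cluster_mean_profiles(pm, labels)
    cc <- suppressWarnings(cor(t(means)))
    diag(cc) <- -Inf
    cc[!is.finite(cc)] <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] <= r_threshold) break
    a <- ids[min(best)]; b <- ids[max(best)]
    log[[length(log) + 1L]] <- data.frame(from = b, into = a,
                                          r = cc[best[1], best[2]])
    labels[labels == b] <- a
  }
  result$labels <- as.integer(factor(labels))
  result$merge_log <- if (length(log)) do.call(rbind, log) else
    data.frame(from = integer(0), into = integer(0), r = numeric(0))
  result$n_merged <- nrow(result$merge_log)
  result
}

#' Match clusters across datasets by profile correlation
#'
#' Greedy best-correlation assignment of clusters in B to clusters in A
#' (pairs are taken in decreasing order of correlation; a cluster already
#' matched is skipped, so conflicting clusters receive their next-best
#' available match). Profiles must live on a common time grid (use
#' [resample_delay()] for long-delay data first).
#'
#' @param means_a,means_b k x t matrices of cluster-mean profiles.
#' @return data.frame (`cluster_b`, `cluster_a`, `r`); unmatched clusters of B
#'   get `cluster_a = NA`.
#' @export
match_clusters <- function(means_a, means_b) {
  if (nrow(means_a) == 0 || nrow(means_b) == 0) stop("empty cluster set")
  if (ncol(means_a) != ncol(means_b)) {
    stop("profiles not on a common grid (resample the delay first)")
  }
  cc <- cor(t(means_b), t(means_a))  # b x a
  ids_a <- rownames(means_a) %||% as.character(seq_len(nrow(means_a)))
  ids_b <- rownames(means_b) %||% as.character(seq_len(nrow(means_b)))
  pairs <- expand.grid(b = seq_len(nrow(cc)), a = seq_len(ncol(cc)))
  pairs$r <- cc[cbind(pairs$b, pairs$a)]
  pairs <- pairs[order(-pairs$r), ]
  used_a <- logical(ncol(cc)); used_b <- logical(nrow(cc))
  out <- data.frame(cluster_b = ids_b, cluster_a = NA_character_, r = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    b <- pairs$b[i]; a <- pairs$a[i]
    if (used_a[a] || used_b[b]) next
    used_a[a] <- TRUE; used_b[b] <- TRUE
    out$cluster_a[b] <- ids_a[a]
    out$r[b] <- pairs$r[i]
    if (all(used_a) || all(used_b)) break
  }
  out
}

#' Louvain community detection on the Jaccard neighbor graph
#'
#' The comparison clustering used for reproducibility scoring: a k-nearest
#' neighbor graph (Euclidean) whose edges are weighted by the Jaccard overlap
#' of the endpoints' neighbor sets, partitioned by Louvain modularity.
#'
#' @param X Numeric matrix (rows = neurons), `pc_loadings`, or `embedding2d`.
#' @param k_nn Neighborhood size.
#' @param seed Seed for the (stochastic) Louvain pass.
#' @return Integer label vector.
#' @export
louvain_jaccard_cluster <- function(X, k_nn = 15, seed = 1) {
  if (inherits(X, "pc_loadings")) X <- X$loadings
  if (inherits(X, "embedding2d")) X <- X$coords
  X <- as.matrix(X)
  n <- nrow(X)
  k_nn <- min(k_nn, n - 1)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nbrs <- t(apply(D, 1, function(r) order(r)[seq_len(k_nn)]))
  edges <- list()
  for (i in seq_len(n)) {
    for (j in nbrs[i, ]) {
      if (j > i || !(i %in% nbrs[j, ])) {
        jac <- length(intersect(nbrs[i, ], nbrs[j, ])) /
          length(union(nbrs[i, ], nbrs[j, ]))
        if (jac > 0) edges[[length(edges) + 1L]] <- c(min(i, j), max(i, j), jac)
      }
    }
  }
  em <- unique(do.call(rbind, edges))
  g <- igraph::graph_from_edgelist(em[, 1:2, drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  cl <- with_seed(seed, igraph::cluster_louvain(g, weights = em[, 3]))
  as.integer(igraph::membership(cl))
}

#' Cluster reproducibility between two labelings
#'
#' For each cluster of method 1, a matching method-2 cluster must have more
#' than half of its own units inside the method-1 cluster; the method-1
#' cluster is reproducible if, additionally, more than half of its units are
#' captured by that matching cluster (both inequalities strict). Reports the
#' matched and reproducible clusters and the fraction of units covered by
#' reproducible clusters.
#'
#' @param labels1,labels2 Integer label vectors over the same units.
#' @return `list(table, reproducible, coverage, cocluster1, cocluster2)`;
#'   `table` has one row per method-1 cluster.
#' @export
coclustering_reproducibility <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) stop("label vectors differ in length")
  n <- length(labels1)
  tab <- table(labels1, labels2)
  size1 <- rowSums(tab); size2 <- colSums(tab)
  rows <- list()
  for (c1 in rownames(tab)) {
    ov <- tab[c1, ]
    frac_of_2 <- ov / size2            # fraction of each c2 inside c1
    cand <- which(frac_of_2 > 0.5)
    if (length(cand) == 0) {
      rows[[c1]] <- data.frame(cluster1 = c1, match2 = NA_character_,
                               captured = NA_real_, reproducible = FALSE)
      next
    }
    # among qualifying matches take the one capturing most of c1
    best <- cand[which.max(ov[cand])]
    captured <- ov[best] / size1[c1]
    rows[[c1]] <- data.frame(cluster1 = c1, match2 = colnames(tab)[best],
                             captured = as.numeric(captured),
                             reproducible = captured > 0.5)
  }
  tabdf <- do.call(rbind, rows)
  rownames(tabdf) <- NULL
  rep_ids <- tabdf$cluster1[tabdf$reproducible]
  coverage <- sum(as.character(labels1) %in% rep_ids) / n
  co <- function(l) outer(l, l, "==")
  list(table = tabdf, reproducible = rep_ids, coverage = coverage,
       cocluster1 = co(labels1), cocluster2 = co(labels2))
}

#' Cluster count versus population size
#'
#' Subsamples the response matrix at the given fractions and re-runs the
#' embed-and-cluster pipeline with automatic center selection, recording the
#' cluster count; used to check that the count saturates with population size.
#'
#' @param pm A `psth_matrix`.
#' @param fractions Subsample fractions in (0, 1].
#' @param seeds One seed per replicate at each fraction.
#' @param n_pcs,perplexity,restarts Embedding parameters.
#' @param dc_frac Density-peak bandwidth fraction.
#' @return data.frame (`fraction`, `n`, `seed`, `n_clusters`).
#' @export
cluster_count_vs_samplesize <- function(pm, fractions = c(0.25, 0.5, 0.75, 1),
                                        seeds = 1:3, n_pcs = 50,
                                        perplexity = 30, restarts = 3,
                                        dc_frac = 0.02) {
  M <- pm$matrix
  out <- list()
  for (f in fractions) {
    for (s in seeds) {
      idx <- if (f >= 1) seq_len(nrow(M)) else
        with_seed(substream_seed(s, 11), sample(nrow(M), round(f * nrow(M))))
      sub <- M[idx, , drop = FALSE]
      ld <- pca_reduce(sub, n_components = min(n_pcs, nrow(sub) - 1, ncol(sub)))
      perp <- min(perplexity, floor((nrow(sub) - 2) / 3))
      emb <- embed_tsne(ld, perplexity = perp, restarts = restarts, seed = s)
      dp <- density_peak_cluster(emb, dc_frac = dc_frac)
      out[[length(out) + 1L]] <- data.frame(fraction = f, n = length(idx),
                                            seed = s,
                                            n_clusters = length(dp$centers))
    }
  }
  do.call(rbind, out)
}
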