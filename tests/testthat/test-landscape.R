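test_that("PCA reduction honors rank and variance targets", {
  set.seed(2)
  # exact rank-2 matrix: two latent profiles
  B <- matrix(rnorm(2 * 50), 2)
  W <- matrix(rnorm(40 * 2), 40)
  M <- W %*% B
  ld <- pca_reduce(M, variance_fraction = 0.98)
  expect_equal(ld$d, 2)
  # orthogonal rotation of the time axis preserves the spectrum
  Q <- qr.Q(qr(matrix(rnorm(50 * 50), 50)))
  ld_rot <- pca_reduce(M %*% Q, n_components = 5)
  expect_equal(ld_rot$explained[1:5], ld$explained[1:5], tolerance = 1e-9)
  expect_error(pca_reduce(matrix(0, 5, 4), n_components = 2), "degenerate")
})

test_that("t-SNE separates well-separated clouds, is deterministic, respects n", {
  set.seed(4)
  X <- rbind(matrix(rnorm(120 * 5, mean = 0), 120),
             matrix(rnorm(120 * 5, mean = 6), 120))
  lab <- rep(1:2, each = 120)
  emb <- embed_tsne(X, perplexity = 30, restarts = 2, seed = 3, max_iter = 400)
  sil <- cluster::silhouette(lab, dist(emb$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  emb2 <- embed_tsne(X, perplexity = 30, restarts = 2, seed = 3, max_iter = 400)
  expect_identical(emb$coords, emb2$coords)
  # duplicated points land close together
  Xd <- rbind(X, X[1, , drop = FALSE])
  embd <- embed_tsne(Xd, perplexity = 30, restarts = 1, seed = 1, max_iter = 400)
  d_dup <- sqrt(sum((embd$coords[1, ] - embd$coords[241, ])^2))
  d_typ <- median(dist(embd$coords[sample(241, 40), ]))
  expect_lt(d_dup, d_typ / 4)
  expect_error(embed_tsne(X[1:20, ], perplexity = 30), "perplexity")
})

test_that("density-peak assignment equals the brute-force rule", {
  set.seed(7)
  for (rep in 1:5) {
    X <- rbind(matrix(rnorm(60 * 2, 0, .5), 60),
               matrix(rnorm(60 * 2, 5, .5), 60),
               cbind(rnorm(60, 0, .5), rnorm(60, 5, .5)))
    dp <- density_peak_cluster(X, n_centers = 3)
    oracle <- dp_assign_oracle(X, dp$rho, dp$centers)
    expect_equal(dp$labels, oracle)
  }
})

test_that("density-peak clustering recovers well-separated blobs", {
  set.seed(5)
  X <- rbind(matrix(rnorm(100 * 2, 0, 0.4), 100),
             matrix(rnorm(100 * 2, 6, 0.4), 100),
             cbind(rnorm(100, 6, 0.4), rnorm(100, -6, 0.4)))
  truth <- rep(1:3, each = 100)
  dp <- density_peak_cluster(X)      # auto gamma-gap selection
  expect_equal(length(dp$centers), 3)
  expect_gte(adjusted_rand(dp$labels, truth), 0.95)
  # single blob: one cluster
  dp1 <- density_peak_cluster(matrix(rnorm(150 * 2), 150))
  expect_equal(length(dp1$centers), 1)
  # every point its own cluster when n_centers = n
  Xs <- matrix(rnorm(20 * 2), 20)
  dpn <- density_peak_cluster(Xs, n_centers = 20)
  expect_equal(sort(unique(dpn$labels)), 1:20)
  # identical points warn and collapse
  expect_warning(dp0 <- density_peak_cluster(matrix(1, 12, 2)), "identical")
  expect_equal(unique(dp0$labels), 1L)
})

test_that("cluster merging is greedy on mean-profile correlation", {
  set.seed(9)
  base <- sin(seq(0, 4 * pi, length.out = 40))
  base2 <- cos(seq(0, 4 * pi, length.out = 40))
  M <- rbind(matrix(rep(base, 10), 10, byrow = TRUE) + rnorm(400, sd = 0.01),
             matrix(rep(base2, 10), 10, byrow = TRUE) + rnorm(400, sd = 0.01))
  pm <- list(matrix = M)
  res <- list(labels = rep(1:4, each = 5))  # split each group into two clusters
  merged <- merge_similar_clusters(res, pm$matrix, r_threshold = 0.97)
  expect_equal(length(unique(merged$labels)), 2)
  expect_equal(merged$n_merged, 2)
  # unattainable threshold: no merges
  none <- merge_similar_clusters(res, pm$matrix, r_threshold = 1.01)
  expect_equal(none$n_merged, 0)
  expect_equal(length(unique(none$labels)), 4)
})

test_that("cluster matching is greedy best-correlation with conflicts resolved", {
  set.seed(11)
  A <- matrix(rnorm(5 * 30), 5)
  rownames(A) <- paste0("a", 1:5)
  # B = permuted A: expect the inverse permutation
  perm <- c(3, 1, 5, 2, 4)
  B <- A[perm, ]
  rownames(B) <- paste0("b", 1:5)
  m <- match_clusters(A, B)
  expect_equal(m$cluster_a, paste0("a", perm))
  expect_true(all(m$r > 0.999))
  # extra cluster in B stays unmatched
  B2 <- rbind(B, b6 = rnorm(30))
  m2 <- match_clusters(A, B2)
  expect_equal(sum(is.na(m2$cluster_a)), 1)
  expect_error(match_clusters(A[0, ], B), "empty")
  expect_error(match_clusters(A, B[, 1:10]), "common grid")
})

test_that("reproducibility scoring follows the strict >50% two-way rule", {
  l1 <- rep(1:4, each = 50)
  # identical labelings: all reproducible, full coverage
  r <- coclustering_reproducibility(l1, l1)
  expect_true(all(r$table$reproducible))
  expect_equal(r$coverage, 1)
  # one cluster split exactly in half: not reproducible (strict inequality)
  l2 <- l1
  l2[l1 == 4] <- rep(c(4, 5), 25)
  r2 <- coclustering_reproducibility(l1, l2)
  expect_false(r2$table$reproducible[r2$table$cluster1 == "4"])
  expect_equal(r2$coverage, 0.75)
  # random permutation of many labels destroys coverage
  set.seed(13)
  n <- 1000
  la <- sample(1:20, n, replace = TRUE)
  cov <- vapply(1:20, function(s) {
    coclustering_reproducibility(la, sample(la))$coverage
  }, numeric(1))
  expect_lt(mean(cov), 0.2)
  expect_error(coclustering_reproducibility(l1, l1[-1]), "length")
})

test_that("Louvain-Jaccard clustering recovers separated groups", {
  set.seed(17)
  X <- rbind(matrix(rnorm(60 * 3, 0, 0.4), 60),
             matrix(rnorm(60 * 3, 5, 0.4), 60))
  truth <- rep(1:2, each = 60)
  labs <- louvain_jaccard_cluster(X, k_nn = 10, seed = 1)
  # communities nest within the planted groups: no community spans both
  # (Louvain at small k_nn may split a group into several pure communities)
  tab <- table(labs, truth)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) >= 1))
})

test_that("cluster count saturates at the planted prototype count", {
  gs <- generate_session(test_config(n_units = 150,
                                     n_trials = c(CR = 50, CL = 50),
                                     n_prototypes = 2, prototype_modes = c(1, 2),
                                     mode_amplitude_hz = 10, seed = 31))
  pm <- build_response_matrix(gs$session, dt_ms = 10,
                              consistency_threshold = NA)
  cc <- cluster_count_vs_samplesize(pm, fractions = c(0.6, 1), seeds = 1,
                                    n_pcs = 10, perplexity = 20, restarts = 2)
  expect_true(all(cc$n_clusters == 2))
})
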