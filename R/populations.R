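#' Joint coding angles for a pair of activity modes
#'
#' Each neuron's weights on two modes form a 2-D coding vector; because weight
#' signs encode trial-type preference, angles are folded into `[0, 90]`
#' degrees via `atan2(|w_b|, |w_a|)`. The analysis keeps the top fraction of
#' neurons by 2-D vector length (weakly weighted neurons scatter uniformly
#' regardless of geometry). When a reference angle set is given (the matched
#' random-mixture population), a one-sided two-sample Kolmogorov-Smirnov test
#' is run on the angles folded about 45 degrees, where segregated 0/90-degree
#' geometry shows up as stochastically smaller values than the reference.
#'
#' @param weights n x 7 mode-weight matrix (see [mode_weights()]).
#' @param mode_a,mode_b Mode names or column indices.
#' @param top_fraction Fraction of neurons kept, ranked by vector length.
#' @param reference Optional reference angle vector (degrees) for the test.
#' @return `list(angles, n, p_value, statistic)` (`p_value` NULL without a
#'   reference).
#' @export
pair_angle_distribution <- function(weights, mode_a, mode_b,
                                    top_fraction = 0.2, reference = NULL) {
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must be in (0, 1]")
  }
  wa <- weights[, mode_a]; wb <- weights[, mode_b]
  len <- sqrt(wa^2 + wb^2)
  keep <- len >= quantile(len, 1 - top_fraction)
  ang <- atan2(abs(wb[keep]), abs(wa[keep])) * 180 / pi
  out <- list(angles = ang, n = sum(keep), p_value = NULL, statistic = NULL)
  if (!is.null(reference)) {
    fold45 <- function(a) pmin(a, 90 - a)
    ks <- suppressWarnings(ks.test(fold45(ang), fold45(reference),
                                   alternative = "greater"))
    out$p_value <- ks$p.value
    out$statistic <- unname(ks$statistic)
  }
  out
}

#' Functional populations by k-means on absolute mode weights
#'
#' Clusters neurons on the absolute values of their activity-mode weights
#' (sign encodes trial-type preference, not functional identity). The cluster
#' count is chosen by the maximum mean silhouette (Euclidean) over `k_range`.
#' Populations are provisionally named after the mode for which they carry
#' the largest share of total squared weight (ties broken by population
#' size); [population_variance_carried()] gives the projection-variance
#' naming criterion.
#'
#' @param weights n x 7 mode-weight matrix (rows filtered upstream to neurons
#'   meeting the error-trial minimums).
#' @param k_range Candidate cluster counts.
#' @param restarts k-means restarts per k.
#' @param seed Seed.
#' @return Object of class `functional_populations`: `list(labels, k,
#'   silhouette, names, centers)`; `silhouette` is a data.frame over
#'   `k_range`.
#' @export
kmeans_populations <- function(weights, k_range = 2:12, restarts = 50, seed = 1) {
  X <- abs(as.matrix(weights))
  n <- nrow(X)
  if (n < max(k_range) + 1) stop("too few neurons for the requested k range")
  if (all(apply(X, 2, function(c) diff(range(c))) == 0)) {
    stop("all coding vectors identical; silhouette undefined")
  }
  D <- stats::dist(X)
  sil <- data.frame(k = k_range, silhouette = NA_real_)
  fits <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- with_seed(substream_seed(seed, 16, k),
                     kmeans(X, centers = k, nstart = restarts, iter.max = 50))
    sw <- cluster::silhouette(fit$cluster, D)
    sil$silhouette[i] <- mean(sw[, "sil_width"])
    fits[[as.character(k)]] <- fit
  }
  kstar <- sil$k[which.max(sil$silhouette)]
  fit <- fits[[as.character(kstar)]]
  labels <- fit$cluster
  # provisional naming: a population is named for a mode when it carries the
  # majority (> 0.5) of that mode's squared weight; otherwise "other"
  sq <- rowsum(X^2, labels)
  share <- sweep(sq, 2, colSums(sq), "/")
  pop_names <- rep("other", kstar)
  for (m in colnames(X)) {
    best <- which.max(share[, m])
    if (share[best, m] > 0.5) {
      pop_names[best] <- if (pop_names[best] == "other") m else
        paste(pop_names[best], m, sep = "+")
    }
  }
  structure(list(labels = labels, k = kstar, silhouette = sil,
                 names = pop_names, centers = fit$centers),
            class = "functional_populations")
}

#' Fraction of each mode's projection variance carried by each population
#'
#' Re-projects the population activity with the weights of all neurons
#' outside a functional population set to zero; the fraction carried is the
#' variance of this restricted projection over time divided by the variance of
#' the full-population projection. (Restricted-projection variances need not
#' sum to 1 across populations when activity is correlated between them.)
#'
#' @param populations A `functional_populations` (or integer label vector).
#' @param ms An orthogonalized `mode_set`.
#' @param R n x T population activity matrix on the projection trials (e.g. a
#'   concatenation of the condition averages, rows matching `ms$unit_ids`).
#' @return matrix populations x modes of variance fractions.
#' @export
population_variance_carried <- function(populations, ms, R) {
  labels <- if (inherits(populations, "functional_populations"))
    populations$labels else populations
  M <- ms$modes
  stopifnot(nrow(M) == nrow(R), length(labels) == nrow(M))
  full <- crossprod(M, R)           # 7 x T
  vfull <- apply(full, 1, var)
  pops <- sort(unique(labels))
  out <- matrix(NA_real_, length(pops), ncol(M),
                dimnames = list(as.character(pops), colnames(M)))
  for (p in seq_along(pops)) {
    Mr <- M
    Mr[labels != pops[p], ] <- 0
    restricted <- crossprod(Mr, R)
    out[p, ] <- apply(restricted, 1, var) / vfull
  }
  out
}

#' Classify functional population identity from embedding neighborhoods
#'
#' Leave-one-out majority vote over each neuron's `k_nn` nearest neighbors in
#' the 2-D embedding; ties are broken toward the class with the smaller
#' summed neighbor distance. Per-class accuracy with optional
#' bootstrap-over-neurons standard errors.
#'
#' @param labels Class labels per neuron.
#' @param embedding `embedding2d` or coordinate matrix.
#' @param k_nn Neighborhood size.
#' @param bootstrap_n Bootstrap resamples (0 disables).
#' @param seed Bootstrap seed.
#' @return `list(predicted, accuracy, per_class, se)`.
#' @export
classify_by_embedding <- function(labels, embedding, k_nn = 10,
                                  bootstrap_n = 0, seed = 1) {
  X <- if (inherits(embedding, "embedding2d")) embedding$coords else as.matrix(embedding)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  small <- names(which(table(labels) < k_nn))
  if (length(small)) warning("classes with fewer than k_nn members: ",
                             paste(small, collapse = ", "))
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  pred <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k_nn)]
    votes <- table(labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      dist_sum <- vapply(top, function(cl)
        sum(D[i, nb[labels[nb] == cl]]), numeric(1))
      top <- top[which.min(dist_sum)]
    }
    top
  }, character(1))
  correct <- pred == as.character(labels)
  per_class <- tapply(correct, labels, mean)
  se <- NULL
  if (bootstrap_n > 0) {
    boots <- with_seed(substream_seed(seed, 17), {
      replicate(bootstrap_n, {
        idx <- sample.int(n, n, replace = TRUE)
        tapply(correct[idx], labels[idx], mean)[names(per_class)]
      })
    })
    se <- apply(boots, 1, sd, na.rm = TRUE)
  }
  list(predicted = pred, accuracy = mean(correct),
       per_class = per_class, se = se)
}

#' Depth distribution of functional populations
#'
#' Per-population histogram of recording depth, normalized within population
#' (fractions sum to 1 in each population); when multiple mice are present the
#' mean and s.e.m. of the per-mouse fractions are also returned.
#'
#' @param populations `functional_populations` or label vector.
#' @param units Units data.frame with `depth_um` (and optionally `mouse_id`).
#' @param breaks Histogram breaks in micrometers.
#' @return `list(fractions, mids, by_mouse)`; `fractions` is populations x
#'   bins.
#' @export
depth_distribution <- function(populations, units,
                               breaks = seq(0, 1000, by = 100)) {
  labels <- if (inherits(populations, "functional_populations"))
    populations$labels else populations
  stopifnot(length(labels) == nrow(units))
  depth <- pmin(pmax(units$depth_um, min(breaks)), max(breaks) - 1e-9)
  bin <- cut(depth, breaks, include.lowest = TRUE, right = FALSE)
  pops <- sort(unique(labels))
  frac <- t(vapply(pops, function(p) {
    h <- table(bin[labels == p])
    as.numeric(h) / max(1, sum(h))
  }, numeric(length(levels(bin)))))
  dimnames(frac) <- list(as.character(pops), levels(bin))
  by_mouse <- NULL
  if (!is.null(units$mouse_id) && length(unique(units$mouse_id)) > 1) {
    mice <- unique(units$mouse_id)
    arr <- vapply(mice, function(m) {
      sel <- units$mouse_id == m
      t(vapply(pops, function(p) {
        h <- table(bin[sel & labels == p])
        as.numeric(h) / max(1, sum(h))
      }, numeric(length(levels(bin)))))
    }, frac)
    by_mouse <- list(mean = apply(arr, 1:2, mean),
                     sem = apply(arr, 1:2, sd) / sqrt(length(mice)))
  }
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  list(fractions = frac, mids = mids, by_mouse = by_mouse)
}
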