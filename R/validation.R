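# End-to-end validation studies with planted ground truth. Each study is a
# self-contained experiment at a stated problem size; the acceptance script
# and the test suite both call these.

#' ePAIRS type-I error calibration under its own null
#'
#' Draws datasets from the variance-matched Gaussian null (a decaying
#' per-dimension variance spectrum, as PCA loadings have), runs the test on
#' each, and reports the rejection rate at `alpha`.
#'
#' @param n_seeds_per_d Datasets per dimensionality.
#' @param n Vectors per dataset.
#' @param dims Dimensionalities studied (loading- and mode-weight-sized).
#' @param n_null Null replicates per test.
#' @param alpha Nominal level.
#' @param oracle Use the true generating variances for the null instead of
#'   re-estimating them from each dataset. The estimating (plug-in) test is
#'   the published procedure and is conservative — the tested dataset's
#'   realized variances match the null parameters exactly while null
#'   replicates scatter around them, widening the null median distribution;
#'   the oracle variant isolates that effect and is nominally calibrated.
#' @param seed Study seed.
#' @return `list(type1, n_tests, p_values)`.
#' @export
study_epairs_calibration <- function(n_seeds_per_d = 200, n = 500,
                                     dims = c(7, 26), n_null = 1000,
                                     alpha = 0.05, oracle = FALSE, seed = 1) {
  ps <- numeric(0)
  for (d in dims) {
    sds <- (seq_len(d))^(-0.5)
    for (s in seq_len(n_seeds_per_d)) {
      X <- with_seed(substream_seed(seed, 30, d, s),
                     matrix(rnorm(n * d), n) %*% diag(sds))
      p <- if (oracle) {
        ang <- nn_angles(X, k = 3)
        nulls <- with_seed(substream_seed(seed, 31, d, s),
                           epairs_null_medians_cpp(n, sds, 3L,
                                                   as.integer(n_null), TRUE)) *
          180 / pi
        mean(nulls <= median(ang))
      } else {
        epairs_test(X, k = 3, n_null = n_null,
                    seed = substream_seed(seed, 31, d, s))$p_value
      }
      ps <- c(ps, p)
    }
  }
  list(type1 = mean(ps < alpha), n_tests = length(ps), p_values = ps)
}

#' ePAIRS power on planted two-cluster geometry
#'
#' Two tight antipodal clusters along one axis (folded together by the angle
#' metric) plus isotropic spread; reports the rejection rate at `alpha`.
#'
#' @param n_seeds Number of datasets.
#' @param n,d Dataset size.
#' @param spread Isotropic noise s.d. around the cluster axis (cluster
#'   centers at +/-1); the configured separation of the study.
#' @param n_null,alpha,seed As in [study_epairs_calibration()].
#' @return `list(power, p_values)`.
#' @export
study_epairs_power <- function(n_seeds = 50, n = 500, d = 7, spread = 0.3,
                               n_null = 1000, alpha = 0.05, seed = 1) {
  ps <- vapply(seq_len(n_seeds), function(s) {
    X <- with_seed(substream_seed(seed, 32, s), {
      X <- matrix(rnorm(n * d, sd = spread), n)
      X[, 1] <- X[, 1] + sample(c(-1, 1), n, replace = TRUE)
      X
    })
    epairs_test(X, k = 3, n_null = n_null,
                seed = substream_seed(seed, 33, s))$p_value
  }, numeric(1))
  list(power = mean(ps < alpha), p_values = ps)
}

# study-scale generator: all seven modes planted as one-hot prototypes.
# The response component is given twice the amplitude so the leading
# eigenvector of the response matrix is the response-epoch pattern, as in the
# recorded population.
recovery_config <- function(seed, n_units = 140,
                            n_trials = c(CR = 100, CL = 100, ER = 16, EL = 16)) {
  generator_config(n_units = n_units, n_trials = n_trials,
                   n_prototypes = 7, prototype_modes = 1:7,
                   mode_amplitude_hz = 9,
                   mode_amplitude_scale = c(1, 1, 1, 1, 1, 1, 2),
                   bin_ms = 5, seed = seed)
}

#' Activity-mode recovery study
#'
#' Generates sessions with all seven modes planted in disjoint prototype
#' populations, runs the full define/orthogonalize pipeline on the definition
#' half of the trials, and reports the worst absolute cosine similarity
#' between recovered and planted mode directions, plus the worst
#' Gram-matrix off-diagonal after orthogonalization.
#'
#' @param n_seeds Number of sessions.
#' @param seed Study seed.
#' @return `list(min_cosine, gram_max_offdiag, per_seed)`.
#' @export
study_mode_recovery <- function(n_seeds = 20, seed = 1) {
  per <- matrix(NA_real_, n_seeds, 7,
                dimnames = list(NULL, mode_names()))
  gmax <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    gs <- generate_session(recovery_config(substream_seed(seed, 34, s)))
    sp <- split_trials(gs$session, seed = substream_seed(seed, 35, s))
    ms <- orthogonalize_modes(define_modes(gs$session, trials = sp$definition))
    W <- gs$truth$mode_weights
    for (m in mode_names()) {
      tv <- W[, m] / sqrt(sum(W[, m]^2))
      per[s, m] <- abs(sum(ms$modes[, m] * tv))
    }
    gmax[s] <- max(abs(crossprod(ms$modes) - diag(7)))
  }
  list(min_cosine = min(per), gram_max_offdiag = max(gmax), per_seed = per)
}

# shared pipeline for the mixture-population studies: generate a clustered
# session, derive modes, synthesize the random-mixture population, re-derive
# modes on it, and return everything needed downstream.
mixture_run <- function(seed, n_units = 120,
                        n_trials = c(CR = 60, CL = 60, ER = 14, EL = 14)) {
  cfg <- generator_config(n_units = n_units, n_trials = n_trials,
                          n_prototypes = 4, prototype_modes = c(1, 2, 4, 5),
                          mode_amplitude_hz = 9, bin_ms = 5, seed = seed)
  gs <- generate_session(cfg)
  sp <- split_trials(gs$session, seed = substream_seed(seed, 36))
  inputs <- collect_mode_inputs(gs$session, trials = sp$definition,
                                svd_dt_ms = 10)
  ms <- orthogonalize_modes(modes_from_inputs(inputs))
  pm <- build_response_matrix(gs$session, trials = sp$definition, dt_ms = 10,
                              cell_classes = NULL, consistency_threshold = NA,
                              normalize = FALSE)
  syn <- synthesize_mixture_population(ms, pm, inputs = inputs,
                                       seed = substream_seed(seed, 37))
  ms_syn <- orthogonalize_modes(modes_from_inputs(syn$inputs))
  list(gs = gs, ms = ms, pm = pm, syn = syn, ms_syn = ms_syn)
}

#' Demixing-contrast study: segregated versus random-mixture geometry
#'
#' For each seed, a clustered session with segregated stimulus/choice/outcome/
#' ramping populations is analyzed end to end; the 7-D mode weights of the
#' real (segregated) population are ePAIRS-tested, and the matched
#' random-mixture population built by [synthesize_mixture_population()] is
#' re-analyzed the same way. Pair-angle distributions (stimulus vs choice)
#' are tested against uniformity on `[0, 90]` degrees.
#'
#' @param n_seeds_mixture Seeds for the mixture (null-geometry) arm.
#' @param n_seeds_segregated Seeds for the segregated arm.
#' @param n_null ePAIRS null replicates.
#' @param seed Study seed.
#' @return list with rejection/nonrejection rates, KS-uniformity rate and
#'   angle summaries.
#' @export
study_demixing_contrast <- function(n_seeds_mixture = 50,
                                    n_seeds_segregated = 10,
                                    n_null = 1000, seed = 1) {
  seg_p <- numeric(n_seeds_segregated)
  seg_extreme <- numeric(n_seeds_segregated)
  mix_p <- numeric(n_seeds_mixture)
  mix_ks <- numeric(n_seeds_mixture)
  comp_relerr_mean <- comp_relerr_max <- rep(NA_real_, n_seeds_mixture)
  proj_ratio <- numeric(n_seeds_mixture)
  for (s in seq_len(n_seeds_mixture)) {
    run <- mixture_run(substream_seed(seed, 38, s))
    W_syn <- mode_weights(run$ms_syn)
    mix_p[s] <- epairs_test(W_syn, k = 3, n_null = n_null,
                            seed = substream_seed(seed, 39, s))$p_value
    pa <- pair_angle_distribution(W_syn, "stimulus", "choice")
    mix_ks[s] <- suppressWarnings(
      ks.test(pa$angles, "punif", 0, 90)$p.value)
    if (s <= 20) {
      # variance contract measured on a 2,000-row synthesis, where the
      # chi-square fluctuation of a component's weight mass is ~3%
      syn_big <- synthesize_mixture_population(run$ms, run$pm, n_rows = 2000,
                                               seed = substream_seed(seed, 58, s))
      cv <- syn_big$component_variance
      big <- cv$original > 1e-4 * max(cv$original)
      relerr <- abs(cv$synthetic[big] / cv$original[big] - 1)
      comp_relerr_mean[s] <- mean(relerr)
      comp_relerr_max[s] <- max(relerr)
    }
    p_o <- crossprod(run$ms$modes, run$pm$matrix)
    p_s <- crossprod(run$ms_syn$modes, run$syn$matrix)
    proj_ratio[s] <- sqrt(sum(p_s^2) / sum(p_o^2))
    if (s <= n_seeds_segregated) {
      W <- mode_weights(run$ms)
      seg_p[s] <- epairs_test(W, k = 3, n_null = n_null,
                              seed = substream_seed(seed, 40, s))$p_value
      ang <- pair_angle_distribution(W, "stimulus", "choice")$angles
      seg_extreme[s] <- mean(ang < 15 | ang > 75)
    }
  }
  list(segregated_reject_rate = mean(seg_p < 0.05),
       segregated_extreme_fraction = mean(seg_extreme),
       mixture_nonreject_rate = mean(mix_p > 0.05),
       mixture_ks_uniform_rate = mean(mix_ks > 0.05),
       component_variance_mean_relerr = max(comp_relerr_mean, na.rm = TRUE),
       component_variance_max_relerr = max(comp_relerr_max, na.rm = TRUE),
       projection_rms_ratio_range = range(proj_ratio[seq_len(min(20, n_seeds_mixture))]),
       mixture_p = mix_p, segregated_p = seg_p)
}

#' Decoding sanity study
#'
#' Three planted conditions: a strongly separable choice signal (late-delay
#' accuracy must reach 1), a no-signal population (binary and four-way
#' accuracy at chance), and a choice-only population (stimulus decoding stays
#' at chance while choice decoding succeeds).
#'
#' @param repeats Decoder repeat runs.
#' @param seed Study seed.
#' @return list of accuracies.
#' @export
study_decoding_sanity <- function(repeats = 20, seed = 1) {
  mk <- function(s, ...) generate_session(generator_config(
    bin_ms = 2, seed = substream_seed(seed, 41, s), ...))
  # separable: huge choice amplitude relative to baseline
  gs1 <- mk(1, n_units = 24, n_trials = c(CR = 40, CL = 40, ER = 14, EL = 14),
            n_prototypes = 1, prototype_modes = 2, mode_amplitude_hz = 30,
            baseline_range_hz = c(4, 6))
  dec1 <- decode_timecourse(gs1$session, "choice", repeats = repeats,
                            seed = substream_seed(seed, 42))
  late <- dec1$time > -0.4 & dec1$time < 0
  sep_acc <- mean(dec1$accuracy[late])
  # chance: no planted signal
  gs0 <- mk(2, n_units = 16, n_trials = c(CR = 40, CL = 40, ER = 12, EL = 12),
            mode_amplitude_hz = 0, baseline_range_hz = c(4, 10))
  dec0 <- decode_timecourse(gs0$session, "choice", repeats = repeats,
                            seed = substream_seed(seed, 43))
  dec4 <- decode_timecourse(gs0$session, "epoch4", repeats = repeats,
                            seed = substream_seed(seed, 44))
  # demixing: choice-only coding
  gs2 <- mk(3, n_units = 20, n_trials = c(CR = 40, CL = 40, ER = 14, EL = 14),
            n_prototypes = 1, prototype_modes = 2, mode_amplitude_hz = 15)
  decc <- decode_timecourse(gs2$session, "choice", repeats = repeats,
                            seed = substream_seed(seed, 45))
  decs <- decode_timecourse(gs2$session, "stimulus", repeats = repeats,
                            seed = substream_seed(seed, 45))
  late2 <- decc$time > -0.4 & decc$time < 0
  list(separable_accuracy = sep_acc,
       chance_accuracy = mean(dec0$accuracy, na.rm = TRUE),
       chance_accuracy_sd = sd(tapply(dec0$accuracy, seq_along(dec0$accuracy) %/% 8, mean)),
       epoch4_accuracy = dec4$accuracy,
       epoch4_sd = dec4$sd,
       demix_choice_accuracy = mean(decc$accuracy[late2]),
       demix_stimulus_accuracy = mean(decs$accuracy[late2]))
}

#' Noise-correlation study
#'
#' Independent-unit sessions give mean pairwise correlation 0 within
#' Monte-Carlo error; shared-gain subnetworks give within > across cluster
#' correlations (rank-sum test).
#'
#' @param seed Study seed.
#' @return list of summaries.
#' @export
study_noise_correlation <- function(seed = 1) {
  gs0 <- generate_session(generator_config(
    n_units = 60, n_trials = c(CR = 40, CL = 40), mode_amplitude_hz = 0,
    gain_sd = 0, baseline_range_hz = c(8, 12), bin_ms = 5,
    seed = substream_seed(seed, 46)))
  labs0 <- setNames(rep(1:2, 30), gs0$session$units$unit_id)
  nc0 <- noise_correlation(gs0$session, labs0, epochs = "delay",
                           seed = substream_seed(seed, 47))
  se0 <- sd(nc0$pairs$r) / sqrt(nrow(nc0$pairs))
  gs1 <- generate_session(generator_config(
    n_units = 60, n_trials = c(CR = 40, CL = 40), mode_amplitude_hz = 0,
    gain_sd = 0.4, n_subnetworks = 2, baseline_range_hz = c(8, 12), bin_ms = 5,
    seed = substream_seed(seed, 48)))
  labs1 <- setNames(gs1$truth$subnetwork_id, gs1$session$units$unit_id)
  nc1 <- noise_correlation(gs1$session, labs1, epochs = "delay",
                           seed = substream_seed(seed, 49))
  list(independent_mean = mean(nc0$pairs$r), independent_se = se0,
       within_minus_across = nc1$summary$mean_within - nc1$summary$mean_across,
       ranksum_p = nc1$summary$p_ranksum)
}

#' Clustering-recovery study
#'
#' For each seed: generate a clustered session (prototypes on sustained
#' templates), build the filtered response matrix, embed (PCA + t-SNE) and
#' density-peak cluster with automatic center selection; report the adjusted
#' Rand index against the planted prototypes and whether the cluster count
#' matches. Also runs the label-permutation control for
#' [coclustering_reproducibility()].
#'
#' @param n_seeds Sessions.
#' @param n_prototypes Planted prototype count.
#' @param restarts t-SNE restarts per embedding.
#' @param seed Study seed.
#' @return list with mean ARI, count-match rate and permuted coverage.
#' @export
study_clustering_recovery <- function(n_seeds = 20, n_prototypes = 3,
                                      restarts = 5, seed = 1) {
  ari <- count_ok <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    gs <- generate_session(generator_config(
      n_units = 240, n_trials = c(CR = 60, CL = 60),
      n_prototypes = n_prototypes, prototype_modes = c(1, 2, 5),
      mode_amplitude_hz = 10, bin_ms = 5,
      seed = substream_seed(seed, 50, s)))
    pm <- build_response_matrix(gs$session, dt_ms = 5)
    ld <- pca_reduce(pm, n_components = 20)
    emb <- embed_tsne(ld, perplexity = 40, restarts = restarts,
                      seed = substream_seed(seed, 51, s))
    dp <- density_peak_cluster(emb)
    truth <- gs$truth$prototype_id[match(pm$unit_ids,
                                         rownames(gs$truth$mode_weights))]
    ari[s] <- mclust_ari(dp$labels, truth)
    count_ok[s] <- as.numeric(length(dp$centers) == n_prototypes)
  }
  # permutation control for reproducibility coverage
  cov <- with_seed(substream_seed(seed, 52), {
    la <- sample(1:20, 1000, replace = TRUE)
    mean(vapply(1:20, function(i)
      coclustering_reproducibility(la, sample(la))$coverage, numeric(1)))
  })
  list(mean_ari = mean(ari), count_match_rate = mean(count_ok),
       permuted_coverage = cov, ari = ari)
}

# adjusted Rand index (Hubert-Arabie); kept internal so the validation
# studies do not depend on a clustering package
mclust_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Nested-bootstrap calibration study
#'
#' Simulates null behavioral datasets (photostim trials drawn from the same
#' per-session performance as control trials) and reports the false-positive
#' rate of [nested_bootstrap_performance()] at `alpha`.
#'
#' @param n_datasets Simulated datasets.
#' @param n_boot Bootstrap replicates per dataset.
#' @param n_mice,n_sessions,n_trials Hierarchy sizes.
#' @param alpha Level.
#' @param seed Study seed.
#' @return `list(fpr, p_values)`.
#' @export
study_nested_bootstrap_calibration <- function(n_datasets = 400, n_boot = 1000,
                                               n_mice = 3, n_sessions = 2,
                                               n_trials = 100, alpha = 0.05,
                                               seed = 1) {
  ps <- vapply(seq_len(n_datasets), function(i) {
    b <- with_seed(substream_seed(seed, 53, i), {
      p0 <- runif(1, 0.6, 0.9)
      do.call(rbind, lapply(seq_len(n_mice), function(m) {
        pm <- min(0.99, max(0.3, p0 + rnorm(1, 0, 0.03)))
        do.call(rbind, lapply(seq_len(n_sessions), function(ss) {
          n2 <- n_trials / 2
          data.frame(mouse_id = paste0("m", m), session_id = paste0("s", ss),
                     photostim = rep(c(FALSE, TRUE), each = n2),
                     correct = runif(n_trials) < pm)
        }))
      }))
    })
    nested_bootstrap_performance(b, n_boot = n_boot,
                                 seed = substream_seed(seed, 54, i))$p_value
  }, numeric(1))
  list(fpr = mean(ps < alpha), p_values = ps)
}

#' Perturbation-pipeline study
#'
#' Plants segregated stimulus/choice/ramping populations aligned with
#' shared-gain subnetworks, selectively silences the choice population during
#' the delay on photostim trials, and checks that the choice mode carries the
#' largest standardized projection change.
#'
#' @param n_seeds Sessions.
#' @param factor Multiplicative silencing factor on the targeted population.
#' @param seed Study seed.
#' @return `list(argmax_rate, deltas)`.
#' @export
study_perturbation_recovery <- function(n_seeds = 20, factor = 0.15, seed = 1) {
  hits <- logical(n_seeds)
  deltas <- matrix(NA_real_, n_seeds, 7, dimnames = list(NULL, mode_names()))
  for (s in seq_len(n_seeds)) {
    cfg <- generator_config(
      n_units = 90, n_trials = c(CR = 80, CL = 80, ER = 30, EL = 30),
      n_prototypes = 3, prototype_modes = c(1, 2, 5), n_subnetworks = 3,
      mode_amplitude_hz = 10, bin_ms = 5,
      photostim = list(target = "thal", epoch = "delay", fraction = 0.3),
      seed = substream_seed(seed, 55, s))
    gs <- generate_session(cfg)
    # subnetwork 2 is the choice-coding prototype population
    em <- data.frame(subnetwork = 2, target = "thal", epoch = "delay",
                     factor = factor)
    pert <- apply_perturbation(gs$session, em, seed = substream_seed(seed, 56, s))
    tr <- pert$trials
    stim_ids <- tr$trial_id[!is.na(tr$photostim_target)]
    ctrl_ids <- setdiff(tr$trial_id[tr$condition_label %in%
                                      c("CR", "CL", "ER", "EL")], stim_ids)
    sp <- split_trials(gs$session, seed = substream_seed(seed, 57, s))
    defs <- intersect(sp$definition, ctrl_ids)
    ms <- orthogonalize_modes(define_modes(pert, trials = defs))
    avc <- condition_averages(pert, trials = setdiff(ctrl_ids, defs),
                              step_ms = 25, min_error_trials = NA)
    avs <- condition_averages(pert, trials = stim_ids, step_ms = 25,
                              min_error_trials = NA)
    mc <- mode_change_under_perturbation(ms, avc, avs, c(-1.3, 0),
                                         n_boot = 0, seed = 1)
    deltas[s, ] <- mc$delta
    hits[s] <- names(which.max(mc$delta)) == "choice"
  }
  list(argmax_rate = mean(hits), deltas = deltas)
}
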