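# spike counts of one unit in sliding windows (centers `tc`), one row per trial
unit_window_counts <- function(session, unit_id, trial_ids, tc, window_s) {
  out <- matrix(0, length(trial_ids), length(tc))
  half <- window_s / 2
  for (k in seq_along(trial_ids)) {
    st <- spikes_of(session, unit_id, trial_ids[k])
    if (length(st)) {
      lo <- findInterval(st, tc - half, left.open = FALSE)
      hi <- findInterval(st, tc + half, left.open = TRUE)
      # spike in window j iff (tc[j]-half) <= t < (tc[j]+half)
      for (sp in seq_along(st)) {
        if (lo[sp] > hi[sp]) out[k, (hi[sp] + 1):lo[sp]] <-
            out[k, (hi[sp] + 1):lo[sp]] + 1
      }
    }
  }
  out
}

decode_grid <- function(delay_duration_s, window_ms, step_ms) {
  ep <- epoch_windows(delay_duration_s)
  w <- window_ms / 1000
  seq(ep$presample[1] + w / 2, ep$response[2] - w / 2, by = step_ms / 1000)
}

contrast_pools <- function(session, contrast, min_error_trials, min_trials) {
  tr <- session$trials
  cond_ids <- function(lab) tr$trial_id[tr$condition_label == lab]
  switch(contrast,
    stimulus = ,
    choice = ,
    outcome = {
      pools <- lapply(setNames(c("CR", "CL", "ER", "EL"),
                               c("CR", "CL", "ER", "EL")), cond_ids)
      if (length(pools$ER) <= min_error_trials ||
          length(pools$EL) <= min_error_trials) return(NULL)
      pools
    },
    epoch4 = {
      ids <- c(cond_ids("CR"), cond_ids("CL"))
      if (length(ids) < min_trials) return(NULL)
      list(correct = ids)
    },
    reaction_time = {
      ids <- c(cond_ids("CR"), cond_ids("CL"))
      rt <- tr$reaction_time_ms[match(ids, tr$trial_id)]
      ids <- ids[order(rt)]
      third <- floor(length(ids) / 3)
      if (third < min_trials) return(NULL)
      list(fast = ids[seq_len(third)],
           slow = ids[(length(ids) - third + 1):length(ids)])
    },
    ignore = {
      resp <- tr$trial_id[tr$condition_label %in% c("CR", "CL", "ER", "EL")]
      ign <- tr$trial_id[tr$condition_label == "ignore"]
      if (length(ign) < min_trials || length(resp) < min_trials) return(NULL)
      list(respond = resp, ignore = ign)
    })
}

pool_class_map <- function(contrast) {
  switch(contrast,
    stimulus = c(CR = "R", ER = "R", CL = "L", EL = "L"),
    choice = c(CR = "R", EL = "R", CL = "L", ER = "L"),
    outcome = c(CR = "C", CL = "C", ER = "E", EL = "E"),
    reaction_time = c(fast = "fast", slow = "slow"),
    ignore = c(respond = "respond", ignore = "ignore"))
}

#' Time-resolved pseudo-population decoding of task variables
#'
#' Linear maximum-margin decoding (support vector machine, linear kernel,
#' C = 1) from pseudo-population response vectors: spike counts in sliding
#' windows (default 200 ms, 50-ms steps), with trials of different units
#' randomly matched. For the stimulus/choice/outcome contrasts pseudo-trials
#' draw equally from all four trial conditions so the other two task
#' variables are balanced across classes. Per-unit trials are split into
#' train/test pools (default 70/30) before matching, so test vectors never
#' share underlying trials with training. The whole procedure is repeated
#' with fresh random matchings; the mean and s.d. of accuracy across repeats
#' are reported. The `epoch4` contrast classifies vectors drawn from the four
#' task epochs (four-way, not time-resolved).
#'
#' @param sessions A `trial_aligned_session` or list of them (units pooled).
#' @param contrast One of `"stimulus"`, `"choice"`, `"outcome"`, `"epoch4"`,
#'   `"reaction_time"`, `"ignore"`.
#' @param repeats Number of repeat runs.
#' @param window_ms,step_ms Counting-window parameters.
#' @param train_frac Fraction of each unit's trials used for training.
#' @param min_error_trials Strict minimum error trials per type for the
#'   trial-type contrasts (units below are excluded with a log).
#' @param min_trials Minimum pool size for the other contrasts.
#' @param cost SVM regularization constant.
#' @param seed Seed.
#' @return data.frame (`time`, `accuracy`, `sd`, `n_units`, `n_test`); for
#'   `epoch4` a single row with `time = NA`.
#' @export
decode_timecourse <- function(sessions, contrast = c("stimulus", "choice",
                                                     "outcome", "epoch4",
                                                     "reaction_time", "ignore"),
                              repeats = 20, window_ms = 200, step_ms = 50,
                              train_frac = 0.7, min_error_trials = 10,
                              min_trials = 5, cost = 1, seed = 1) {
  contrast <- match.arg(contrast)
  if (inherits(sessions, "trial_aligned_session")) sessions <- list(sessions)
  w <- window_ms / 1000
  tc <- decode_grid(sessions[[1]]$delay_duration_s, window_ms, step_ms)
  units <- list()   # per unit: list(session index, unit_id, pools)
  for (si in seq_along(sessions)) {
    pools <- contrast_pools(sessions[[si]], contrast, min_error_trials, min_trials)
    if (is.null(pools)) next
    for (uid in sessions[[si]]$units$unit_id) {
      units[[length(units) + 1L]] <- list(si = si, uid = uid, pools = pools)
    }
  }
  if (length(units) < 2) stop("no units satisfy the contrast's trial minimums")
  # precompute counts: per unit, per pool, trials x windows
  counts <- lapply(units, function(u) {
    lapply(u$pools, function(ids)
      unit_window_counts(sessions[[u$si]], u$uid, ids, tc, w))
  })
  pool_names <- names(units[[1]]$pools)
  cls_map <- if (contrast == "epoch4") NULL else pool_class_map(contrast)
  ep <- epoch_windows(sessions[[1]]$delay_duration_s)
  run_repeat <- function(r) {
    # per unit: permute each pool, split into train/test trial indices
    perms <- lapply(seq_along(units), function(ui) {
      lapply(pool_names, function(p) {
        np <- nrow(counts[[ui]][[p]])
        idx <- with_seed(substream_seed(seed, 18, r, ui), sample.int(np))
        ntrain <- floor(train_frac * np)
        list(train = idx[seq_len(ntrain)], test = idx[-seq_len(ntrain)])
      }) |> setNames(pool_names)
    })
    if (contrast == "epoch4") {
      win_sets <- lapply(ep, function(wnd)
        which(tc - w / 2 >= wnd[1] & tc + w / 2 <= wnd[2]))
      n_tr <- min(vapply(perms, function(pp) length(pp$correct$train), 1L))
      n_te <- min(vapply(perms, function(pp) length(pp$correct$test), 1L))
      build <- function(part, npt) {
        X <- NULL; y <- NULL
        for (epn in names(win_sets)) {
          Xe <- vapply(seq_along(units), function(ui) {
            rows <- perms[[ui]]$correct[[part]][seq_len(npt)]
            wins <- with_seed(substream_seed(seed, 19, r, ui, match(epn, names(win_sets))),
                              sample(win_sets[[epn]], npt, replace = TRUE))
            counts[[ui]]$correct[cbind(rows, wins)]
          }, numeric(npt))
          X <- rbind(X, Xe); y <- c(y, rep(epn, npt))
        }
        list(X = X, y = factor(y))
      }
      trn <- build("train", n_tr); tst <- build("test", n_te)
      fit <- e1071::svm(trn$X, trn$y, kernel = "linear", cost = cost,
                        scale = FALSE)
      return(data.frame(time = NA_real_,
                        accuracy = mean(predict(fit, tst$X) == tst$y),
                        n_test = length(tst$y)))
    }
    n_tr <- min(vapply(seq_along(units), function(ui)
      min(vapply(pool_names, function(p) length(perms[[ui]][[p]]$train), 1L)), 1L))
    n_te <- min(vapply(seq_along(units), function(ui)
      min(vapply(pool_names, function(p) length(perms[[ui]][[p]]$test), 1L)), 1L))
    # assemble per pool: array pseudo x unit x time
    assemble <- function(part, npt) {
      lapply(setNames(pool_names, pool_names), function(p) {
        arr <- vapply(seq_along(units), function(ui) {
          rows <- perms[[ui]][[p]][[part]][seq_len(npt)]
          counts[[ui]][[p]][rows, , drop = FALSE]
        }, matrix(0, npt, length(tc)))
        aperm(arr, c(1, 3, 2))  # pseudo x unit x time
      })
    }
    trn <- assemble("train", n_tr); tst <- assemble("test", n_te)
    y_tr <- factor(rep(cls_map[pool_names], each = n_tr))
    y_te <- factor(rep(cls_map[pool_names], each = n_te))
    acc <- vapply(seq_along(tc), function(ti) {
      Xtr <- do.call(rbind, lapply(trn, function(a) a[, , ti]))
      Xte <- do.call(rbind, lapply(tst, function(a) a[, , ti]))
      if (all(Xtr == Xtr[1])) return(NA_real_)
      fit <- e1071::svm(Xtr, y_tr, kernel = "linear", cost = cost, scale = FALSE)
      mean(predict(fit, Xte) == y_te)
    }, numeric(1))
    data.frame(time = tc, accuracy = acc, n_test = length(y_te))
  }
  reps <- lapply(seq_len(repeats), run_repeat)
  accs <- vapply(reps, function(d) d$accuracy, numeric(nrow(reps[[1]])))
  accs <- matrix(accs, nrow = nrow(reps[[1]]))
  data.frame(time = reps[[1]]$time,
             accuracy = rowMeans(accs, na.rm = TRUE),
             sd = apply(accs, 1, sd, na.rm = TRUE),
             n_units = length(units),
             n_test = reps[[1]]$n_test[1])
}

#' Greedy unique pairing of simultaneously recorded units
#'
#' Maximal matching in randomized order with a fixed seed: each unit appears
#' in at most one retained pair.
#'
#' @param candidates data.frame with columns `unit_a`, `unit_b`.
#' @param seed Seed for the randomized order.
#' @return The retained subset of `candidates`.
#' @export
select_unique_pairs <- function(candidates, seed = 1) {
  if (nrow(candidates) == 0) return(candidates)
  ord <- with_seed(substream_seed(seed, 20), sample.int(nrow(candidates)))
  used <- character(0)
  keep <- logical(nrow(candidates))
  for (i in ord) {
    a <- candidates$unit_a[i]; b <- candidates$unit_b[i]
    if (!(a %in% used) && !(b %in% used)) {
      keep[i] <- TRUE
      used <- c(used, a, b)
    }
  }
  candidates[keep, , drop = FALSE]
}

#' Pairwise noise correlations within and across clusters
#'
#' Pearson correlation of mean-subtracted spike counts (100-ms windows,
#' correct trials, per trial type, per epoch) between simultaneously recorded
#' unit pairs. Pairs must be more than `min_distance_um` apart, both units
#' must have more than `min_trials` trials of each trial type, and each unit
#' is used in at most one pair ([select_unique_pairs()]). The per-window
#' trial-type mean is subtracted before correlating across trials and
#' windows. Within-cluster and across-cluster distributions are compared with
#' a two-sided Wilcoxon rank-sum test per epoch.
#'
#' @param session A `trial_aligned_session` (one recording session).
#' @param labels Cluster label per unit, named by unit id (units without a
#'   label are skipped).
#' @param epochs Epoch names (`baseline` = 500-ms presample window).
#' @param window_ms Counting-window width.
#' @param min_trials Strict minimum trials per trial type.
#' @param min_distance_um Minimum inter-unit distance.
#' @param seed Pairing seed.
#' @return `list(pairs, summary)`: `pairs` has one row per pair x trial type x
#'   epoch with the correlation and a `within` flag; `summary` one row per
#'   epoch with means and the rank-sum p-value.
#' @export
noise_correlation <- function(session, labels,
                              epochs = c("baseline", "sample", "delay", "response"),
                              window_ms = 100, min_trials = 10,
                              min_distance_um = 100, seed = 1) {
  u <- session$units
  uids <- intersect(u$unit_id, names(labels))
  tr <- session$trials
  tt_ids <- list(CR = tr$trial_id[tr$condition_label == "CR"],
                 CL = tr$trial_id[tr$condition_label == "CL"])
  if (any(vapply(tt_ids, length, 1L) <= min_trials)) {
    stop("session has too few correct trials per type")
  }
  cand <- list()
  for (i in seq_along(uids)) {
    for (j in seq_len(i - 1L)) {
      a <- uids[i]; b <- uids[j]
      if (u$session_id[u$unit_id == a] != u$session_id[u$unit_id == b]) next
      d <- abs(u$depth_um[u$unit_id == a] - u$depth_um[u$unit_id == b])
      if (d > min_distance_um) {
        cand[[length(cand) + 1L]] <- data.frame(unit_a = a, unit_b = b,
                                                distance_um = d)
      }
    }
  }
  if (length(cand) == 0) stop("no candidate pairs satisfy the constraints")
  pairs <- select_unique_pairs(do.call(rbind, cand), seed = seed)
  ep <- epoch_windows(session$delay_duration_s)
  ep$baseline <- ep$presample
  w <- window_ms / 1000
  rows <- list()
  for (pi in seq_len(nrow(pairs))) {
    a <- pairs$unit_a[pi]; b <- pairs$unit_b[pi]
    for (tt in names(tt_ids)) {
      ids <- tt_ids[[tt]]
      for (epn in epochs) {
        wnd <- ep[[epn]]
        tcs <- seq(wnd[1] + w / 2, wnd[2] - w / 2 + 1e-9, by = w)
        Ca <- unit_window_counts(session, a, ids, tcs, w)
        Cb <- unit_window_counts(session, b, ids, tcs, w)
        Ca <- sweep(Ca, 2, colMeans(Ca))
        Cb <- sweep(Cb, 2, colMeans(Cb))
        if (sd(Ca) == 0 || sd(Cb) == 0) next  # zero-variance unit in epoch
        rows[[length(rows) + 1L]] <- data.frame(
          unit_a = a, unit_b = b, trial_type = tt, epoch = epn,
          r = cor(as.vector(Ca), as.vector(Cb)),
          within = labels[[a]] == labels[[b]])
      }
    }
  }
  pr <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(pr$epoch), function(epn) {
    d <- pr[pr$epoch == epn, ]
    wtn <- d$r[d$within]; acr <- d$r[!d$within]
    p <- if (length(wtn) && length(acr))
      suppressWarnings(wilcox.test(wtn, acr)$p.value) else NA_real_
    data.frame(epoch = epn, mean_within = mean(wtn), mean_across = mean(acr),
               n_within = length(wtn), n_across = length(acr), p_ranksum = p)
  }))
  list(pairs = pr, summary = summ)
}
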