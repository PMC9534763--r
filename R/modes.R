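#' Split trials into mode-definition and projection halves
#'
#' Random 50/50 split within each condition label, so the trials that define
#' the activity modes are disjoint from (and balanced with) the trials used
#' for activity projections.
#'
#' @param session A `trial_aligned_session`.
#' @param fraction Fraction assigned to the definition half.
#' @param seed Split seed.
#' @return `list(definition, projection)` of trial-id vectors.
#' @export
split_trials <- function(session, fraction = 0.5, seed = 1) {
  tr <- session$trials
  def <- integer(0)
  with_seed(substream_seed(seed, 12), {
    for (lab in unique(tr$condition_label)) {
      ids <- tr$trial_id[tr$condition_label == lab]
      take <- ids[sample.int(length(ids), round(fraction * length(ids)))]
      def <- c(def, take)
    }
  })
  list(definition = sort(def), projection = sort(setdiff(tr$trial_id, def)))
}

# mean rate (spikes/s) of each unit in [a, b), averaged over the given trials
epoch_mean_rates <- function(session, unit_ids, trial_ids, window) {
  a <- window[1]; b <- window[2]
  ntr <- length(trial_ids)
  if (ntr == 0) return(setNames(rep(NA_real_, length(unit_ids)), unit_ids))
  out <- vapply(unit_ids, function(uid) {
    tot <- 0
    for (tid in trial_ids) {
      st <- spikes_of(session, uid, tid)
      tot <- tot + sum(st >= a & st < b)
    }
    tot / (ntr * (b - a))
  }, numeric(1))
  setNames(out, unit_ids)
}

#' Trial-averaged condition response time series
#'
#' Per-condition population response vectors over sliding analysis windows
#' (default 100 ms wide, centered on the grid points).
#'
#' @param session A `trial_aligned_session`.
#' @param units Unit ids (default all).
#' @param trials Optional trial-id subset (intersected per condition).
#' @param conditions Condition labels to average.
#' @param window_ms Analysis-window width.
#' @param step_ms Grid step.
#' @param min_error_trials Units are only meaningful when the session holds
#'   more than this many error trials of each type; set `NA` to skip the check.
#' @param align `"go"` or `"first_lick"` (spike times shifted by each trial's
#'   reaction time before averaging).
#' @return Object of class `condition_averages`: `list(time, avg, n_trials,
#'   unit_ids, window_s, delay_duration_s)` with `avg[[cond]]` an n x T matrix.
#' @export
condition_averages <- function(session, units = NULL, trials = NULL,
                               conditions = c("CR", "CL", "ER", "EL"),
                               window_ms = 100, step_ms = 10,
                               min_error_trials = 5, align = c("go", "first_lick")) {
  align <- match.arg(align)
  units <- units %||% session$units$unit_id
  w <- window_ms / 1000; s <- step_ms / 1000
  ep <- epoch_windows(session$delay_duration_s)
  tc <- seq(ep$presample[1] + w / 2, ep$response[2] - w / 2, by = s)
  edges <- seq(ep$presample[1], ep$response[2], by = s)
  nbin <- length(edges) - 1
  wb <- round(w / s)
  tr <- session$trials
  avg <- list(); ntr_used <- c()
  for (cond in conditions) {
    ids <- tr$trial_id[tr$condition_label == cond]
    if (!is.null(trials)) ids <- intersect(ids, trials)
    if (length(ids) == 0) next
    R <- matrix(0, length(units), length(tc),
                dimnames = list(units, NULL))
    for (ui in seq_along(units)) {
      counts <- numeric(nbin)
      for (tid in ids) {
        st <- spikes_of(session, units[ui], tid)
        if (align == "first_lick") {
          rt <- tr$reaction_time_ms[tr$trial_id == tid] / 1000
          if (!is.na(rt)) st <- st - rt
        }
        if (length(st)) {
          h <- findInterval(st, edges, left.open = FALSE)
          h <- h[h >= 1 & h <= nbin]
          if (length(h)) counts <- counts + tabulate(h, nbins = nbin)
        }
      }
      cs <- cumsum(c(0, counts))
      wsum <- cs[(wb + 1):(nbin + 1)] - cs[1:(nbin - wb + 1)]
      R[ui, ] <- wsum[seq_along(tc)] / (length(ids) * w)
    }
    avg[[cond]] <- R
    ntr_used[cond] <- length(ids)
  }
  if (!is.na(min_error_trials)) {
    for (e in intersect(c("ER", "EL"), conditions)) {
      if ((ntr_used[e] %||% 0) <= min_error_trials || is.na(ntr_used[e])) {
        warning(sprintf("only %d %s trials (need > %d for error-dependent modes)",
                        ntr_used[e] %||% 0, e, min_error_trials))
      }
    }
  }
  structure(list(time = tc, avg = avg, n_trials = ntr_used, unit_ids = units,
                 window_s = w, delay_duration_s = session$delay_duration_s),
            class = "condition_averages")
}

#' Population selectivity vectors
#'
#' From the four condition averages (CR, CL, ER, EL), per time point:
#' \deqn{\mathrm{stimulus} = ((\bar{CR}-\bar{EL}) + (\bar{ER}-\bar{CL}))/2}
#' \deqn{\mathrm{choice} = ((\bar{CR}-\bar{ER}) + (\bar{EL}-\bar{CL}))/2}
#' \deqn{\mathrm{outcome} = ((\bar{CR}-\bar{ER}) + (\bar{CL}-\bar{EL}))/2}
#' Stimulus contrasts the instructed pole positions, choice the executed lick
#' directions, outcome correct versus error trials.
#'
#' @param avgs A `condition_averages` with all four conditions.
#' @return `list(stimulus, choice, outcome, time)`, each an n x T matrix.
#' @export
selectivity_vectors <- function(avgs) {
  a <- avgs$avg
  need <- c("CR", "CL", "ER", "EL")
  if (!all(need %in% names(a))) {
    stop("need all four condition averages: ", paste(setdiff(need, names(a)), collapse = ", "))
  }
  list(stimulus = ((a$CR - a$EL) + (a$ER - a$CL)) / 2,
       choice = ((a$CR - a$ER) + (a$EL - a$CL)) / 2,
       outcome = ((a$CR - a$ER) + (a$CL - a$EL)) / 2,
       time = avgs$time)
}

#' Time-by-time correlation map of a selectivity vector series
#'
#' Pearson correlation of the population selectivity vector between every pair
#' of time points; when split-half series are supplied, the diagonal holds the
#' split-half correlation at each time (an estimate of the selectivity
#' reliability), otherwise it is left at 1.
#'
#' @param sel n x T selectivity matrix (one of the [selectivity_vectors()]
#'   outputs).
#' @param sel_half1,sel_half2 Optional n x T matrices from disjoint trial
#'   halves for the diagonal.
#' @return T x T correlation matrix; cells with a zero-variance vector are NA.
#' @export
selectivity_correlation_map <- function(sel, sel_half1 = NULL, sel_half2 = NULL) {
  if (ncol(sel) < 2) stop("need at least 2 time points")
  cc <- suppressWarnings(cor(sel))
  if (!is.null(sel_half1) && !is.null(sel_half2)) {
    dg <- vapply(seq_len(ncol(sel)), function(t) {
      suppressWarnings(cor(sel_half1[, t], sel_half2[, t]))
    }, numeric(1))
    diag(cc) <- dg
  }
  cc
}

# Everything define_modes needs, as linear functionals of the population data;
# kept separate so a synthetic (mixture) population can reuse the same mode
# constructor on transformed inputs.
collect_mode_inputs <- function(session, units = NULL, trials = NULL,
                                min_error_trials = 5, svd_dt_ms = 5,
                                svd_width_ms = 100) {
  units <- units %||% session$units$unit_id
  tr <- session$trials
  trials <- trials %||% tr$trial_id
  ep <- epoch_windows(session$delay_duration_s)
  ids <- function(conds) intersect(tr$trial_id[tr$condition_label %in% conds], trials)
  n_er <- length(ids("ER")); n_el <- length(ids("EL"))
  missing <- character(0)
  if (n_er <= min_error_trials || n_el <= min_error_trials) {
    missing <- c("stimulus", "choice", "outcome")
  }
  win_means <- function(window, conds) {
    lapply(setNames(conds, conds), function(cond)
      epoch_mean_rates(session, units, ids(cond), window))
  }
  four <- c("CR", "CL", "ER", "EL")
  go_pre <- c(-0.1, 0); go_post <- c(0, 0.1)
  delay_late <- c(-0.5, 0)
  action_win <- c(0.1, 0.3)
  inputs <- list(
    sample = win_means(ep$sample, four),
    delay = win_means(ep$delay, four),
    action = win_means(action_win, c("CR", "CL")),
    response = win_means(ep$response, four),
    presample_cc = epoch_mean_rates(session, units, ids(c("CR", "CL")), ep$presample),
    delay_late_cc = epoch_mean_rates(session, units, ids(c("CR", "CL")), delay_late),
    go_pre_cc = epoch_mean_rates(session, units, ids(c("CR", "CL")), go_pre),
    go_post_cc = epoch_mean_rates(session, units, ids(c("CR", "CL")), go_post),
    unit_ids = units, missing = missing,
    delay_duration_s = session$delay_duration_s
  )
  pm <- build_response_matrix(session, units = units, trials = trials,
                              cell_classes = NULL, consistency_threshold = NA,
                              dt_ms = svd_dt_ms, width_ms = svd_width_ms,
                              normalize = FALSE)
  inputs$psth <- pm$matrix[units, , drop = FALSE]
  inputs$psth_time <- pm$time
  inputs
}

modes_from_inputs <- function(inputs, trial_subset = NULL) {
  sel3 <- function(m) {
    list(stimulus = ((m$CR - m$EL) + (m$ER - m$CL)) / 2,
         choice = ((m$CR - m$ER) + (m$EL - m$CL)) / 2,
         outcome = ((m$CR - m$ER) + (m$CL - m$EL)) / 2)
  }
  if (length(inputs$missing)) {
    stop("insufficient error trials; undefined modes: ",
         paste(inputs$missing, collapse = ", "))
  }
  n <- length(inputs$unit_ids)
  raw <- matrix(0, n, 7, dimnames = list(inputs$unit_ids, mode_names()))
  raw[, "stimulus"] <- sel3(inputs$sample)$stimulus
  raw[, "choice"] <- sel3(inputs$delay)$choice
  raw[, "action"] <- inputs$action$CR - inputs$action$CL
  raw[, "outcome"] <- sel3(inputs$response)$outcome
  raw[, "ramping"] <- inputs$delay_late_cc - inputs$presample_cc
  raw[, "go"] <- inputs$go_post_cc - inputs$go_pre_cc
  sv <- svd(inputs$psth, nu = 1, nv = 1)
  u1 <- sv$u[, 1]
  # orient the response mode so the mean response-epoch projection is positive
  nt <- length(inputs$psth_time)
  resp_cols <- which(rep(inputs$psth_time, ncol(inputs$psth) / nt) >= 0)
  if (sum(crossprod(u1, inputs$psth[, resp_cols, drop = FALSE])) < 0) u1 <- -u1
  raw[, "response"] <- u1
  degenerate <- character(0)
  M <- raw
  for (m in colnames(M)) {
    nrm <- sqrt(sum(M[, m]^2))
    if (nrm < 1e-12) {
      degenerate <- c(degenerate, m)
    } else {
      M[, m] <- M[, m] / nrm
    }
  }
  structure(list(modes = M, raw = raw, unit_ids = inputs$unit_ids,
                 orthogonalized = FALSE, degenerate = degenerate,
                 definition_trials = trial_subset,
                 delay_duration_s = inputs$delay_duration_s),
            class = "mode_set")
}

#' Define the seven activity modes
#'
#' Computes the raw (unit-norm) activity-mode directions from trial-averaged
#' condition responses on the definition trials:
#' stimulus (stimulus selectivity averaged over the sample epoch), choice
#' (choice selectivity over the delay epoch), action (`CR - CL` during
#' movement initiation, 0.1-0.3 s after the go cue), outcome (outcome
#' selectivity over the response epoch), ramping (late-delay minus presample
#' response, correct trials pooled), go (100 ms after minus 100 ms before the
#' go cue, correct trials pooled), and response (the leading left singular
#' vector of the baseline-subtracted concatenated PSTH matrix).
#'
#' @param session A `trial_aligned_session`.
#' @param units Unit ids (default all).
#' @param trials Definition-trial ids (use [split_trials()]; projections must
#'   use the complementary set).
#' @param min_error_trials Error trials of each type required (strictly more
#'   than this) for the error-dependent modes.
#' @param svd_dt_ms PSTH grid step for the response-mode SVD.
#' @return Object of class `mode_set` (`$modes` is the n x 7 matrix; not yet
#'   orthogonalized).
#' @export
define_modes <- function(session, units = NULL, trials = NULL,
                         min_error_trials = 5, svd_dt_ms = 5) {
  inputs <- collect_mode_inputs(session, units, trials,
                                min_error_trials = min_error_trials,
                                svd_dt_ms = svd_dt_ms)
  modes_from_inputs(inputs, trial_subset = trials)
}

#' Gram-Schmidt orthogonalization of a mode set
#'
#' Sequentially orthogonalizes the raw modes in the given order (default
#' stimulus, choice, action, outcome, ramping, go, response — earlier modes
#' keep their direction, later modes lose their components along earlier
#' ones), normalizing each to unit length. Raw modes flagged degenerate stay
#' zero; a non-degenerate mode whose residual norm collapses signals
#' collinearity and raises an error naming it.
#'
#' @param ms A `mode_set`.
#' @param order Character vector of mode names.
#' @param tol Residual-norm tolerance for the collinearity error.
#' @return The `mode_set` with orthonormal `modes`, `orthogonalized = TRUE`.
#' @export
orthogonalize_modes <- function(ms, order = mode_names(), tol = 1e-8) {
  stopifnot(inherits(ms, "mode_set"))
  M <- ms$modes[, order, drop = FALSE]
  Q <- matrix(0, nrow(M), 0)
  out <- M
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (colnames(M)[j] %in% ms$degenerate) { out[, j] <- 0; next }
    if (ncol(Q)) v <- v - Q %*% crossprod(Q, v)
    nrm <- sqrt(sum(v^2))
    if (nrm < tol) {
      stop(sprintf("mode '%s' is collinear with the preceding modes", colnames(M)[j]))
    }
    v <- v / nrm
    Q <- cbind(Q, v)
    out[, j] <- v
  }
  ms$modes <- out[, mode_names(), drop = FALSE]
  ms$orthogonalized <- TRUE
  ms$order <- order
  ms
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d units x %d modes (%s)%s\n", nrow(x$modes),
              ncol(x$modes),
              if (x$orthogonalized) "orthogonalized" else "raw",
              if (length(x$degenerate)) paste0("; degenerate: ",
                                               paste(x$degenerate, collapse = ",")) else ""))
  invisible(x)
}

#' Per-neuron activity-mode weights
#'
#' Each neuron's weights across the seven (orthogonalized) modes — its
#' seven-dimensional coding vector.
#'
#' @param ms A `mode_set`.
#' @return n x 7 numeric matrix (rows = neurons, columns = modes).
#' @export
mode_weights <- function(ms) {
  stopifnot(inherits(ms, "mode_set"))
  ms$modes
}

#' Activity projections onto the modes
#'
#' Projects trial-group-averaged population activity onto each mode:
#' `Mode' r(t)` per group and time point, with bootstrap-over-neurons standard
#' errors. Projection trials must be disjoint from the mode-definition trials.
#'
#' @param ms An orthogonalized `mode_set`.
#' @param session The session.
#' @param trial_groups Named list of trial-id vectors (e.g. the projection
#'   half split by condition); empty groups are dropped with a message.
#' @param window_ms,step_ms Analysis-window parameters.
#' @param bootstrap_n Bootstrap resamples over neurons (0 disables).
#' @param seed Bootstrap seed.
#' @param align `"go"` or `"first_lick"`.
#' @return Object of class `mode_projection`: `list(time, proj, se)` where
#'   `proj[[group]]` is a 7 x T matrix.
#' @export
project_modes <- function(ms, session, trial_groups, window_ms = 100,
                          step_ms = 10, bootstrap_n = 1000, seed = 1,
                          align = "go") {
  stopifnot(inherits(ms, "mode_set"))
  M <- ms$modes
  n <- nrow(M)
  proj <- list(); se <- list()
  cnt <- NULL
  if (bootstrap_n > 0) {
    cnt <- with_seed(substream_seed(seed, 13),
                     rmultinom(bootstrap_n, n, rep(1 / n, n)))  # n x B
  }
  for (g in names(trial_groups)) {
    ids <- trial_groups[[g]]
    if (length(ids) == 0) { message("empty trial group ", g, " omitted"); next }
    av <- condition_averages(session, units = ms$unit_ids, trials = ids,
                             conditions = unique(session$trials$condition_label[
                               session$trials$trial_id %in% ids]),
                             window_ms = window_ms, step_ms = step_ms,
                             min_error_trials = NA, align = align)
    # pooled average over the group's conditions weighted by trial counts
    tot <- sum(av$n_trials[names(av$avg)])
    R <- Reduce(`+`, Map(function(m, k) m * k, av$avg,
                         as.list(av$n_trials[names(av$avg)]))) / tot
    proj[[g]] <- crossprod(M, R)  # 7 x T
    if (!is.null(cnt)) {
      se_g <- matrix(0, ncol(M), ncol(R), dimnames = dimnames(proj[[g]]))
      for (m in seq_len(ncol(M))) {
        contrib <- M[, m] * R            # n x T
        boots <- crossprod(cnt, contrib) # B x T
        se_g[m, ] <- apply(boots, 2, sd)
      }
      se[[g]] <- se_g
    }
  }
  structure(list(time = if (length(proj)) av$time else numeric(0),
                 proj = proj, se = se, modes = colnames(M)),
            class = "mode_projection")
}

#' Fraction of activity and selectivity captured by the mode subspace
#'
#' Activity: the r.m.s. of the baseline-subtracted population activity over
#' the sample, delay and response epochs, comparing the projection onto the
#' 7-mode subspace with the full activity. Stimulus and choice selectivity are
#' assessed over sample + delay, outcome selectivity over the response epoch.
#' All fractions are r.m.s. ratios in `[0, 1]`.
#'
#' @param ms An orthogonalized `mode_set`.
#' @param pm A `psth_matrix` on the same units (rows are matched by unit id).
#' @param sel Optional [selectivity_vectors()] output with its `time`.
#' @return Named list of fractions: `activity`, and when `sel` is given,
#'   `stimulus`, `choice`, `outcome`.
#' @export
variance_captured <- function(ms, pm, sel = NULL) {
  stopifnot(inherits(ms, "mode_set"))
  M <- ms$modes
  A <- pm$matrix[ms$unit_ids, , drop = FALSE]
  ep <- epoch_windows(pm$delay_duration_s)
  nt <- length(pm$time)
  in_task <- rep(pm$time >= ep$sample[1], ncol(A) / nt)
  A <- A[, in_task, drop = FALSE]
  P <- M %*% crossprod(M, A)
  out <- list(activity = sqrt(sum(P^2) / sum(A^2)))
  if (!is.null(sel)) {
    sd_win <- sel$time >= ep$sample[1] & sel$time < 0
    resp_win <- sel$time >= 0
    cap <- function(S, win) {
      S <- S[ms$unit_ids, win, drop = FALSE]
      PS <- M %*% crossprod(M, S)
      sqrt(sum(PS^2) / sum(S^2))
    }
    out$stimulus <- cap(sel$stimulus, sd_win)
    out$choice <- cap(sel$choice, sd_win)
    out$outcome <- cap(sel$outcome, resp_win)
  }
  out
}

#' Pooled mode projections across simultaneously recorded sessions
#'
#' Runs the define/project split per session, removes each session's global
#' projection offset (the mean projection over the definition trials and all
#' time points), and averages the offset-corrected projections across
#' qualifying sessions (at least `min_units` units and `min_trials` trials per
#' condition).
#'
#' @param sessions List of `trial_aligned_session`.
#' @param min_units,min_trials Qualification thresholds.
#' @param split_seed Seed for the per-session definition/projection split.
#' @param groups Condition labels to project.
#' @param ... Passed to [project_modes()].
#' @return `list(time, proj, n_sessions)`; `proj[[group]]` is the 7 x T mean.
#' @export
session_offset_project <- function(sessions, min_units = 10, min_trials = 10,
                                   split_seed = 1, groups = c("CR", "CL"),
                                   ...) {
  acc <- list(); nt_used <- 0
  for (si in seq_along(sessions)) {
    ses <- sessions[[si]]
    cnt <- table(ses$trials$condition_label)
    if (nrow(ses$units) < min_units ||
        any(cnt[groups] < min_trials) || any(is.na(cnt[groups]))) next
    sp <- split_trials(ses, seed = substream_seed(split_seed, 14, si))
    ms <- orthogonalize_modes(define_modes(ses, trials = sp$definition))
    tg_def <- lapply(setNames(groups, groups), function(g)
      intersect(sp$definition, ses$trials$trial_id[ses$trials$condition_label == g]))
    tg_prj <- lapply(setNames(groups, groups), function(g)
      intersect(sp$projection, ses$trials$trial_id[ses$trials$condition_label == g]))
    pr_def <- project_modes(ms, ses, tg_def, bootstrap_n = 0, ...)
    pr <- project_modes(ms, ses, tg_prj, bootstrap_n = 0, ...)
    offset <- rowMeans(do.call(cbind, pr_def$proj))  # per mode, over trials+time
    for (g in names(pr$proj)) {
      corr <- pr$proj[[g]] - offset
      acc[[g]] <- if (is.null(acc[[g]])) corr else acc[[g]] + corr
    }
    nt_used <- nt_used + 1
    time <- pr$time
  }
  if (nt_used == 0) stop("no session meets the simultaneity thresholds")
  list(time = time, proj = lapply(acc, function(m) m / nt_used),
       n_sessions = nt_used)
}

#' Synthesize a population coding random mixtures of the activity modes
#'
#' Decomposes the population response matrix into the seven orthonormal
#' activity modes plus the leading eigenvectors of the residual (orthogonal to
#' the modes by construction), then rebuilds every synthetic neuron as a
#' random combination of the components' temporal profiles with i.i.d.
#' zero-mean Gaussian weights of variance `1/n`. This preserves each
#' component's share of the population activity variance and the
#' population-level mode projections, while scrambling the per-neuron weight
#' geometry — the uniform-mixing reference population.
#'
#' @param ms An orthogonalized `mode_set`.
#' @param pm The `psth_matrix` the modes were derived from (same units).
#' @param n_components Total number of components (7 modes + eigenvectors);
#'   default keeps eigenvectors carrying 99% of the residual variance, capped
#'   at the matrix rank.
#' @param inputs Optional `collect_mode_inputs()` output from the same
#'   population; when given, the synthetic counterparts of all mode-defining
#'   condition averages are returned so the modes can be recomputed on the
#'   synthetic population.
#' @param n_rows Number of synthetic neurons (default: the original
#'   population size). Weight variance is `1/n_rows`, so each component's
#'   total variance is preserved regardless of the synthetic population size.
#' @param seed Weight seed.
#' @return `list(matrix, weights, components, temporal, component_variance,
#'   inputs)`; `component_variance` has columns `original`/`synthetic`.
#' @export
synthesize_mixture_population <- function(ms, pm, n_components = NULL,
                                          inputs = NULL, n_rows = NULL,
                                          seed = 1) {
  stopifnot(inherits(ms, "mode_set"), ms$orthogonalized)
  A <- pm$matrix[ms$unit_ids, , drop = FALSE]
  M <- ms$modes
  keep_modes <- colnames(M)[colSums(M^2) > 0]
  M <- M[, keep_modes, drop = FALSE]
  Res <- A - M %*% crossprod(M, A)
  sv <- svd(Res)
  pos <- sv$d > max(sv$d) * 1e-10
  q_avail <- sum(pos)
  q <- if (is.null(n_components)) {
    ev <- sv$d[pos]^2
    min(q_avail, which(cumsum(ev) / sum(ev) >= 0.99)[1])
  } else {
    q_req <- n_components - ncol(M)
    if (q_req > q_avail) {
      message(sprintf("component count truncated to matrix rank (%d eigenvectors)", q_avail))
    }
    min(q_req, q_avail)
  }
  U <- cbind(M, sv$u[, seq_len(q), drop = FALSE])
  colnames(U) <- c(keep_modes, paste0("ev", seq_len(q)))
  Tm <- crossprod(U, A)  # C x t temporal profiles
  n <- n_rows %||% nrow(A); C <- ncol(U)
  syn_ids <- sprintf("syn%04d", seq_len(n))
  W <- with_seed(substream_seed(seed, 15),
                 matrix(rnorm(n * C, sd = 1 / sqrt(n)), n, C,
                        dimnames = list(syn_ids, colnames(U))))
  A_syn <- W %*% Tm
  comp_var <- data.frame(component = colnames(U),
                         original = rowSums(Tm^2),
                         synthetic = colSums(W^2) * rowSums(Tm^2))
  syn_inputs <- NULL
  if (!is.null(inputs)) {
    tf_vec <- function(v) as.numeric(W %*% crossprod(U, v[ms$unit_ids]))
    tf_grp <- function(lst) lapply(lst, tf_vec)
    syn_inputs <- list(
      sample = tf_grp(inputs$sample), delay = tf_grp(inputs$delay),
      action = tf_grp(inputs$action), response = tf_grp(inputs$response),
      presample_cc = tf_vec(inputs$presample_cc),
      delay_late_cc = tf_vec(inputs$delay_late_cc),
      go_pre_cc = tf_vec(inputs$go_pre_cc),
      go_post_cc = tf_vec(inputs$go_post_cc),
      unit_ids = syn_ids, missing = inputs$missing,
      delay_duration_s = inputs$delay_duration_s,
      psth = W %*% crossprod(U, inputs$psth[ms$unit_ids, , drop = FALSE]),
      psth_time = inputs$psth_time
    )
    for (g in c("sample", "delay", "action", "response")) {
      syn_inputs[[g]] <- lapply(syn_inputs[[g]], function(v)
        setNames(v, syn_ids))
    }
  }
  list(matrix = A_syn, weights = W, components = U, temporal = Tm,
       component_variance = comp_var, inputs = syn_inputs)
}
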