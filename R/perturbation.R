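#' Nested bootstrap test of a photoinhibition behavioral effect
#'
#' Task performance is the fraction of correct choices excluding early-lick
#' and ignore trials. The change caused by photostimulation is tested against
#' normal behavioral variability by a hierarchical bootstrap: each replicate
#' resamples (1) mice with replacement, (2) sessions within each sampled
#' mouse, (3) trials within each sampled session, and recomputes the
#' performance change. The one-sided p-value is the fraction of replicates
#' whose change has the opposite sign to the observed change.
#'
#' Trial-level resampling uses the exact multinomial equivalence: resampling a
#' session's trials with replacement is distributed as a multinomial over its
#' (photostim x correct) category counts.
#'
#' @param behavior data.frame with columns `mouse_id`, `session_id`,
#'   `photostim` (logical), `correctness` (`correct`/`error`/`ignore`/
#'   `early_lick`) — or `correct` (logical) for pre-filtered tables.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed.
#' @return `list(delta, p_value, perf_control, perf_stim, boots, n_mice)`.
#' @export
nested_bootstrap_performance <- function(behavior, n_boot = 10000, seed = 1) {
  b <- as.data.frame(behavior)
  if (is.null(b[["correct"]])) {
    b <- b[!(b$correctness %in% c("ignore", "early_lick")), ]
    b$correct <- b$correctness == "correct"
  }
  perf_cols <- c("mouse_id", "session_id", "photostim", "correct")
  b <- b[, perf_cols]
  stopifnot(is.logical(b$photostim) || all(b$photostim %in% c(0, 1)))
  b$photostim <- as.logical(b$photostim)
  has_stim <- tapply(b$photostim, b$mouse_id, any)
  dropped <- names(has_stim)[!has_stim]
  if (length(dropped)) {
    message("dropping mice with no photostim trials: ",
            paste(dropped, collapse = ", "))
    b <- b[!(b$mouse_id %in% dropped), ]
  }
  mice <- unique(b$mouse_id)
  if (length(mice) < 2) stop("need at least 2 mice with photostim trials")
  perf <- function(d) {
    c(control = mean(d$correct[!d$photostim]), stim = mean(d$correct[d$photostim]))
  }
  obs <- perf(b)
  delta <- unname(obs["stim"] - obs["control"])
  # per-session category counts: (control/stim) x (error/correct)
  sess_key <- interaction(b$mouse_id, b$session_id, drop = TRUE)
  cats <- table(sess_key, interaction(b$photostim, b$correct))
  cats <- cats[, intersect(c("FALSE.FALSE", "FALSE.TRUE", "TRUE.FALSE", "TRUE.TRUE"),
                           colnames(cats)), drop = FALSE]
  sess_mouse <- tapply(as.character(b$mouse_id), sess_key, `[`, 1)
  sess_by_mouse <- split(rownames(cats), sess_mouse[rownames(cats)])
  col_stim <- grepl("^TRUE", colnames(cats))
  col_corr <- grepl("TRUE$", colnames(cats))
  boots <- with_seed(substream_seed(seed, 21), {
    vapply(seq_len(n_boot), function(bi) {
      m_draw <- sample(mice, length(mice), replace = TRUE)
      tot <- numeric(ncol(cats))
      for (m in m_draw) {
        ss <- sess_by_mouse[[as.character(m)]]
        s_draw <- ss[sample.int(length(ss), length(ss), replace = TRUE)]
        for (s in s_draw) {
          n_s <- sum(cats[s, ])
          if (n_s == 0) next
          tot <- tot + as.numeric(rmultinom(1, n_s, cats[s, ] / n_s))
        }
      }
      ps <- sum(tot[col_stim & col_corr]) / max(1, sum(tot[col_stim]))
      pc <- sum(tot[!col_stim & col_corr]) / max(1, sum(tot[!col_stim]))
      ps - pc
    }, numeric(1))
  })
  p <- if (delta == 0) 1 else if (delta < 0) mean(boots > 0) else mean(boots < 0)
  list(delta = delta, p_value = p, perf_control = unname(obs["control"]),
       perf_stim = unname(obs["stim"]), boots = boots, n_mice = length(mice))
}

#' Photoinhibition effect on single-unit spike rates
#'
#' Compares spike counts inside the photostimulation window between
#' photostim and control trials (trial types pooled; sample- and delay-epoch
#' stimulation pooled upstream) with a two-tailed t-test, labeling each unit
#' `silenced`, `excited` or `unchanged` at the given alpha. Units whose
#' control rate is below `min_rate_hz` are flagged and excluded from the
#' labels.
#'
#' @param session A `trial_aligned_session`.
#' @param stim_window `c(start, end)` seconds.
#' @param stim_trials,control_trials Trial-id vectors (default: photostim
#'   labeling in the trials table, with control trials matched by condition).
#' @param alpha Significance level.
#' @param min_trials Minimum trials per arm.
#' @param min_rate_hz Control-rate inclusion threshold.
#' @return data.frame per unit: `unit_id`, `rate_control`, `rate_stim`,
#'   `ratio`, `p_value`, `label`, `included`.
#' @export
photoinhibition_rate_change <- function(session, stim_window,
                                        stim_trials = NULL,
                                        control_trials = NULL,
                                        alpha = 0.01, min_trials = 5,
                                        min_rate_hz = 0.5) {
  tr <- session$trials
  if (is.null(stim_trials)) stim_trials <- tr$trial_id[!is.na(tr$photostim_target)]
  if (is.null(control_trials)) {
    control_trials <- tr$trial_id[is.na(tr$photostim_target) &
                                    !(tr$condition_label %in% c("ignore", "early_lick"))]
  }
  if (length(stim_trials) < min_trials || length(control_trials) < min_trials) {
    stop(sprintf("need >= %d trials in both arms", min_trials))
  }
  dur <- diff(stim_window)
  count_in <- function(uid, ids) vapply(ids, function(tid) {
    st <- spikes_of(session, uid, tid)
    sum(st >= stim_window[1] & st < stim_window[2])
  }, numeric(1))
  rows <- lapply(session$units$unit_id, function(uid) {
    cs <- count_in(uid, stim_trials); cc <- count_in(uid, control_trials)
    rc <- mean(cc) / dur; rs <- mean(cs) / dur
    if (sum(cs) == 0 && sum(cc) == 0) {
      return(data.frame(unit_id = uid, rate_control = 0, rate_stim = 0,
                        ratio = NA_real_, p_value = NA_real_,
                        label = "unchanged", included = FALSE))
    }
    p <- if (sd(c(cs, cc)) == 0) 1 else
      suppressWarnings(t.test(cs, cc)$p.value)
    lab <- if (is.na(p) || p >= alpha) "unchanged" else
      if (rs < rc) "silenced" else "excited"
    data.frame(unit_id = uid, rate_control = rc, rate_stim = rs,
               ratio = if (rc > 0) rs / rc else NA_real_, p_value = p,
               label = lab, included = rc >= min_rate_hz)
  })
  do.call(rbind, rows)
}

#' Standardized activity-mode change under perturbation
#'
#' Projects control and photostimulation condition averages on the modes,
#' pools the two instructed trial types, takes the absolute projection
#' difference averaged over the stimulation window, and standardizes each
#' mode's change by the s.d. of its control projection across time. Bootstrap
#' draws over neurons quantify sampling variability and feed
#' [compare_mode_changes()].
#'
#' @param ms An orthogonalized `mode_set`.
#' @param avg_control,avg_stim `condition_averages` on the same units and
#'   grid (control and photostim trials respectively).
#' @param stim_window `c(start, end)` seconds.
#' @param n_boot Neuron-bootstrap replicates.
#' @param seed Seed.
#' @return `list(delta, se, boots)`; `delta` is the named per-mode
#'   standardized |change|. Modes whose control projection has zero temporal
#'   s.d. are NA.
#' @export
mode_change_under_perturbation <- function(ms, avg_control, avg_stim,
                                           stim_window, n_boot = 10000,
                                           seed = 1) {
  M <- ms$modes
  n <- nrow(M)
  pool <- function(av) {
    keep <- intersect(c("CR", "CL", "ER", "EL"), names(av$avg))
    Reduce(`+`, Map(function(m, k) m * k, av$avg[keep],
                    as.list(av$n_trials[keep]))) / sum(av$n_trials[keep])
  }
  Rc <- pool(avg_control)[ms$unit_ids, , drop = FALSE]
  Rs <- pool(avg_stim)[ms$unit_ids, , drop = FALSE]
  tm <- avg_control$time
  win <- tm >= stim_window[1] & tm < stim_window[2]
  stat <- function(idx_w) {
    # idx_w: per-neuron multiplicity weights (bootstrap); all-ones = observed
    Mw <- M * idx_w
    pc <- crossprod(Mw, Rc); ps <- crossprod(Mw, Rs)
    sdc <- apply(pc, 1, sd)
    d <- rowMeans(abs(ps - pc)[, win, drop = FALSE]) / sdc
    d[sdc == 0] <- NA_real_
    d
  }
  delta <- stat(rep(1, n))
  if (n_boot == 0) {
    return(list(delta = delta, se = NULL, boots = NULL))
  }
  boots <- with_seed(substream_seed(seed, 22), {
    cnt <- rmultinom(n_boot, n, rep(1 / n, n))
    t(vapply(seq_len(n_boot), function(b) stat(cnt[, b]), numeric(ncol(M))))
  })
  list(delta = delta, se = apply(boots, 2, sd, na.rm = TRUE), boots = boots)
}

#' Compare mode changes between two manipulations
#'
#' One-sided bootstrap comparison of the standardized mode changes of two
#' perturbations (neurons resampled independently in each): the p-value per
#' mode is the fraction of bootstrap pairs whose difference has the opposite
#' sign to the observed difference.
#'
#' @param a,b Results of [mode_change_under_perturbation()].
#' @return data.frame (`mode`, `delta_a`, `delta_b`, `diff`, `p_value`).
#' @export
compare_mode_changes <- function(a, b) {
  modes <- names(a$delta)
  nb <- min(nrow(a$boots), nrow(b$boots))
  rows <- lapply(modes, function(m) {
    d <- a$delta[m] - b$delta[m]
    db <- a$boots[seq_len(nb), m] - b$boots[seq_len(nb), m]
    p <- if (is.na(d) || d == 0) 1 else
      if (d > 0) mean(db < 0, na.rm = TRUE) else mean(db > 0, na.rm = TRUE)
    data.frame(mode = m, delta_a = unname(a$delta[m]), delta_b = unname(b$delta[m]),
               diff = unname(d), p_value = p)
  })
  do.call(rbind, rows)
}

#' Identify optogenetically tagged (putatively connected) units
#'
#' For each unit, spike counts in 20-ms windows before and after each light
#' pulse are compared (one-sided excitation test); among significantly
#' excited units the evoked spikes per pulse (baseline-subtracted) and the
#' response latency (first 0.5-ms bin where the baseline-subtracted rate
#' reaches half its peak) are measured. A unit is tagged iff excitation is
#' significant at `alpha`, latency is strictly below `latency_ms` and evoked
#' spikes exceed `min_evoked` per pulse.
#'
#' @param session A `trial_aligned_session`; spike times are interpreted
#'   relative to the same clock as `pulse_times`.
#' @param pulse_times Light-pulse onset times (s), at least 20.
#' @param window_ms Pre/post comparison window.
#' @param bin_ms Latency bin width.
#' @param alpha Excitation significance level.
#' @param latency_ms Latency criterion (strict).
#' @param min_evoked Evoked spikes-per-pulse criterion (strict).
#' @return data.frame per unit: `unit_id`, `evoked_per_pulse`, `latency_ms`,
#'   `p_value`, `tagged`.
#' @export
tag_units <- function(session, pulse_times, window_ms = 20, bin_ms = 0.5,
                      alpha = 0.01, latency_ms = 5, min_evoked = 0.2) {
  if (length(pulse_times) < 20) stop("need at least 20 light pulses")
  w <- window_ms / 1000
  nb <- round(window_ms / bin_ms)
  rows <- lapply(session$units$unit_id, function(uid) {
    st <- sort(unlist(session$spikes[[uid]], use.names = FALSE))
    pre <- post <- numeric(length(pulse_times))
    hist_post <- numeric(nb)
    for (k in seq_along(pulse_times)) {
      p0 <- pulse_times[k]
      pre[k] <- sum(st >= p0 - w & st < p0)
      sel <- st >= p0 & st < p0 + w
      post[k] <- sum(sel)
      if (post[k]) {
        bins <- floor((st[sel] - p0) / (bin_ms / 1000)) + 1
        hist_post <- hist_post + tabulate(bins, nbins = nb)
      }
    }
    if (sum(pre) + sum(post) == 0) {
      return(data.frame(unit_id = uid, evoked_per_pulse = 0,
                        latency_ms = NA_real_, p_value = NA_real_,
                        tagged = FALSE))
    }
    p <- if (sd(post - pre) == 0) 1 else
      suppressWarnings(t.test(post, pre, alternative = "greater",
                              paired = TRUE)$p.value)
    evoked <- mean(post) - mean(pre)
    base_rate <- mean(pre) / nb   # baseline counts per latency bin
    resp <- hist_post / length(pulse_times) - base_rate
    lat <- NA_real_
    if (max(resp) > 0) {
      lat <- (which(resp >= max(resp) / 2)[1] - 1) * bin_ms
    }
    data.frame(unit_id = uid, evoked_per_pulse = evoked, latency_ms = lat,
               p_value = p,
               tagged = !is.na(p) && p < alpha && !is.na(lat) &&
                 lat < latency_ms && evoked > min_evoked)
  })
  do.call(rbind, rows)
}

#' EPSP features from a whole-cell membrane-potential trace
#'
#' Clips spikes by linear interpolation of V_m from 1 ms before to 4 ms after
#' each spike, subtracts the baseline (mean over the 10 ms before stimulation
#' onset), and extracts the light-evoked EPSP: its mean over the 20-ms
#' post-onset window, the peak within that window, and the latency at which
#' the EPSP first reaches 10% of its peak. The latency is defined only when
#' the peak exceeds the noise floor (3 baseline s.d.); a neuron is flagged
#' connected when the latency is at most `latency_ms`.
#'
#' @param time_s Sample times (s), uniform, >= 10 kHz.
#' @param vm_mv Membrane potential (mV).
#' @param stim_onset_s Photostimulation onset.
#' @param spike_times Optional spike times; detected as upward crossings of
#'   `spike_threshold_mv` when NULL.
#' @param spike_threshold_mv Detection threshold.
#' @param latency_ms Connection criterion on the EPSP latency.
#' @return `list(baseline_mv, mean_epsp_mv, peak_mv, latency_ms, connected)`.
#' @export
epsp_features <- function(time_s, vm_mv, stim_onset_s, spike_times = NULL,
                          spike_threshold_mv = -20, latency_ms = 5) {
  dt <- median(diff(time_s))
  if (dt > 1e-4 + 1e-12) stop("V_m must be sampled at >= 10 kHz")
  vm <- vm_mv
  if (is.null(spike_times)) {
    up <- which(vm[-1] >= spike_threshold_mv & vm[-length(vm)] < spike_threshold_mv)
    spike_times <- time_s[up]
  }
  for (s in spike_times) {
    a <- s - 0.001; b <- s + 0.004
    ia <- max(1, findInterval(a, time_s)); ib <- min(length(vm), findInterval(b, time_s) + 1)
    vm[ia:ib] <- seq(vm[ia], vm[ib], length.out = ib - ia + 1)
  }
  base_sel <- time_s >= stim_onset_s - 0.010 & time_s < stim_onset_s
  baseline <- mean(vm[base_sel])
  noise <- sd(vm[base_sel])
  post_sel <- time_s >= stim_onset_s & time_s < stim_onset_s + 0.020
  epsp <- vm[post_sel] - baseline
  peak <- max(epsp)
  mean_epsp <- mean(epsp)
  lat <- NA_real_
  if (peak > 3 * noise && peak > 0) {
    i10 <- which(epsp >= 0.1 * peak)[1]
    lat <- (time_s[post_sel][i10] - stim_onset_s) * 1000
  }
  list(baseline_mv = baseline, mean_epsp_mv = mean_epsp, peak_mv = peak,
       latency_ms = lat, connected = !is.na(lat) && lat <= latency_ms)
}

#' Connected fraction per functional population
#'
#' Fraction of connectivity-tested units that are connected, per population,
#' with standard errors from bootstrapping the entire dataset (all units,
#' tested or not) and a chi-squared comparison of connection counts across
#' populations.
#'
#' @param labels Population label per unit.
#' @param tested Logical: was the unit tested for connectivity?
#' @param connected Logical: connected (only meaningful where `tested`).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed.
#' @return `list(table, chisq_p)`: `table` has `population`, `n_tested`,
#'   `n_connected`, `fraction`, `se`.
#' @export
connection_fraction <- function(labels, tested, connected, n_boot = 1000,
                                seed = 1) {
  n <- length(labels)
  stopifnot(length(tested) == n, length(connected) == n)
  pops <- sort(unique(labels[tested]))
  frac <- function(idx) {
    vapply(pops, function(p) {
      sel <- idx[labels[idx] == p & tested[idx]]
      if (length(sel) == 0) NA_real_ else mean(connected[sel])
    }, numeric(1))
  }
  obs <- frac(seq_len(n))
  boots <- with_seed(substream_seed(seed, 23), {
    t(vapply(seq_len(n_boot), function(b) frac(sample.int(n, n, replace = TRUE)),
             numeric(length(pops))))
  })
  tab <- data.frame(population = as.character(pops),
                    n_tested = vapply(pops, function(p) sum(tested & labels == p), 1L),
                    n_connected = vapply(pops, function(p)
                      sum(tested & connected & labels == p), 1L),
                    fraction = obs,
                    se = apply(boots, 2, sd, na.rm = TRUE))
  cs <- if (nrow(tab) > 1) {
    m <- cbind(tab$n_connected, tab$n_tested - tab$n_connected)
    suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
  } else NA_real_
  list(table = tab, chisq_p = cs)
}

#' Membrane time constant from a double-exponential decay fit
#'
#' Least-squares fit of `a1*exp(-t/tau1) + a2*exp(-t/tau2)` to an averaged
#' V_m decay (e.g. following brief current pulses); returns the slow
#' component.
#'
#' @param time_ms Time from decay onset (ms, increasing).
#' @param vm Baseline-subtracted V_m decay.
#' @return `list(tau_slow_ms, tau_fast_ms, fit)`.
#' @export
membrane_time_constant <- function(time_ms, vm) {
  stopifnot(length(time_ms) == length(vm))
  d <- data.frame(t = time_ms, v = vm)
  amp <- vm[1]
  try_fit <- function(form, start, lower) tryCatch(
    minpack.lm::nlsLM(form, data = d, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- try_fit(v ~ a1 * exp(-t / t1) + a2 * exp(-t / t2),
                 list(a1 = amp * 0.5, t1 = 2, a2 = amp * 0.5, t2 = 15),
                 c(-Inf, 0.05, -Inf, 0.05))
  if (is.null(fit)) {
    # a mono-exponential decay makes the two-component model singular; fall
    # back to the single-exponential special case (t1 = t2)
    fit <- try_fit(v ~ a1 * exp(-t / t1), list(a1 = amp, t1 = 10),
                   c(-Inf, 0.05))
  }
  ok <- !is.null(fit)
  if (ok) {
    cf <- coef(fit)
    # reject fits that explain no variance (e.g. pure noise input)
    r2 <- 1 - sum(residuals(fit)^2) / sum((vm - mean(vm))^2)
    if (!is.finite(r2) || r2 < 0.5) ok <- FALSE
  }
  if (!ok) {
    stop("double-exponential fit did not converge on this trace ",
         "(residual variance too high or optimizer failure)")
  }
  taus <- if ("t2" %in% names(cf)) sort(c(cf[["t1"]], cf[["t2"]])) else
    rep(cf[["t1"]], 2)
  list(tau_slow_ms = taus[2], tau_fast_ms = taus[1], fit = fit)
}
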