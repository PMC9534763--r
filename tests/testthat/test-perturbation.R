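make_behavior <- function(p_control, p_stim, n_mice = 3, n_sessions = 2,
                          n_trials = 100, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_mice), function(m) {
    do.call(rbind, lapply(seq_len(n_sessions), function(s) {
      n2 <- n_trials / 2
      data.frame(mouse_id = paste0("m", m), session_id = paste0("s", s),
                 photostim = rep(c(FALSE, TRUE), each = n2),
                 correct = c(runif(n2) < p_control, runif(n2) < p_stim))
    }))
  }))
}

test_that("nested bootstrap: zero effect on identical tables, detects large drops", {
  b <- make_behavior(0.8, 0.8, seed = 3)
  b$correct[b$photostim] <- b$correct[!b$photostim]  # identical arms
  r0 <- nested_bootstrap_performance(b, n_boot = 500, seed = 1)
  expect_equal(r0$delta, 0)
  expect_equal(r0$p_value, 1)
  # deterministic large drop
  r1 <- nested_bootstrap_performance(make_behavior(0.9, 0.5, seed = 4),
                                     n_boot = 2000, seed = 1)
  expect_lt(r1$delta, -0.3)
  expect_lt(r1$p_value, 0.01)
  # early-lick and ignore trials excluded from performance
  b2 <- make_behavior(0.9, 0.9, seed = 5)
  b2$correctness <- ifelse(b2$correct, "correct", "error")
  b2$correct <- NULL
  extra <- b2[1:40, ]; extra$correctness <- rep(c("ignore", "early_lick"), 20)
  r2 <- nested_bootstrap_performance(rbind(b2, extra), n_boot = 200, seed = 1)
  expect_gt(r2$perf_control, 0.8)
  # mice without photostim are dropped with a message
  b3 <- make_behavior(0.8, 0.7, seed = 6)
  b3$photostim[b3$mouse_id == "m1"] <- FALSE
  expect_message(nested_bootstrap_performance(b3, n_boot = 100, seed = 1),
                 "dropping mice")
})

test_that("nested bootstrap p-values are calibrated under the null", {
  # small calibration run; the acceptance suite runs the full study
  set.seed(11)
  ps <- vapply(1:60, function(i) {
    p0 <- runif(1, 0.6, 0.9)
    nested_bootstrap_performance(make_behavior(p0, p0, seed = 1000 + i),
                                 n_boot = 300, seed = i)$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.12)
})

test_that("photoinhibition rate change labels silencing correctly", {
  cfg <- test_config(n_units = 16, n_trials = c(CR = 60, CL = 60),
                     baseline_range_hz = c(15, 25), mode_amplitude_hz = 0,
                     photostim = list(target = "thal", epoch = "delay",
                                      fraction = 0.5), seed = 31)
  gs <- generate_session(cfg)
  em <- data.frame(subnetwork = 1:2, target = "thal", epoch = "delay", factor = 0)
  pert <- apply_perturbation(gs$session, em, seed = 2)
  prc <- photoinhibition_rate_change(pert, c(-1.3, 0))
  expect_true(all(prc$label == "silenced"))
  expect_true(all(prc$p_value < 1e-6))
  # null factor: almost all unchanged at alpha = 0.01
  prc1 <- photoinhibition_rate_change(gs$session, c(-1.3, 0))
  expect_gte(mean(prc1$label == "unchanged"), 0.9)
  # low-rate units flagged out
  expect_true(all(prc$included == (prc$rate_control >= 0.5)))
})

test_that("mode change under perturbation finds the silenced mode", {
  cfg <- test_config(n_units = 90, n_trials = c(CR = 80, CL = 80, ER = 20, EL = 20),
                     n_prototypes = 3, prototype_modes = c(1, 2, 5),
                     n_subnetworks = 3, mode_amplitude_hz = 10,
                     photostim = list(target = "thal", epoch = "delay",
                                      fraction = 0.3), seed = 33)
  gs <- generate_session(cfg)
  # subnetworks align with prototypes (both cycle with the same stride):
  # silence subnetwork 1 = the stimulus-coding population
  em <- data.frame(subnetwork = 1, target = "thal", epoch = "delay", factor = 0.1)
  pert <- apply_perturbation(gs$session, em, seed = 3)
  tr <- pert$trials
  stim_ids <- tr$trial_id[!is.na(tr$photostim_target)]
  ctrl_ids <- setdiff(tr$trial_id[tr$condition_label %in% c("CR", "CL", "ER", "EL")],
                      stim_ids)
  sp <- split_trials(gs$session, seed = 2)
  defs <- intersect(sp$definition, ctrl_ids)
  ms <- orthogonalize_modes(define_modes(pert, trials = defs))
  avc <- condition_averages(pert, trials = setdiff(ctrl_ids, defs),
                            step_ms = 25, min_error_trials = NA)
  avs <- condition_averages(pert, trials = stim_ids, step_ms = 25,
                            min_error_trials = NA)
  mc <- mode_change_under_perturbation(ms, avc, avs, c(-1.3, 0),
                                       n_boot = 200, seed = 4)
  expect_equal(names(which.max(mc$delta[c("stimulus", "choice", "ramping")])),
               "stimulus")
  # identical trial sets: near-zero change
  mc0 <- mode_change_under_perturbation(ms, avc, avc, c(-1.3, 0),
                                        n_boot = 50, seed = 4)
  expect_true(all(mc0$delta < 1e-9, na.rm = TRUE))
  # equal effects: comparison p is non-extreme
  cmp <- compare_mode_changes(mc, mc)
  expect_true(all(cmp$p_value >= 0.4))
})

test_that("tagging applies the latency/evoked/significance predicate exactly", {
  set.seed(41)
  pulses <- seq(10, 10 + 0.2 * 59, by = 0.2)
  mk_unit <- function(evoked, latency_ms, base_hz = 5) {
    st <- sort(runif(round(base_hz * 25), 0, 25))
    if (evoked > 0) {
      resp <- pulses[runif(length(pulses)) < evoked] + latency_ms / 1000
      st <- sort(c(st, resp))
    }
    st
  }
  units <- data.frame(unit_id = c("conn", "weak", "supp"), mouse_id = "m",
                      session_id = "s", depth_um = 300, spike_width_ms = 0.6)
  trials <- data.frame(trial_id = 1L, instructed_type = "lick_right",
                       correctness = "correct")
  spikes <- list(conn = list(`1` = mk_unit(0.5, 2)),
                 weak = list(`1` = mk_unit(0.15, 2)),
                 supp = list(`1` = mk_unit(0, 0)))
  ses <- suppressWarnings(trial_aligned_session(units, trials, spikes,
                                                validate = FALSE))
  tg <- tag_units(ses, pulses)
  expect_true(tg$tagged[tg$unit_id == "conn"])
  expect_lt(abs(tg$latency_ms[tg$unit_id == "conn"] - 2), 1)
  expect_false(tg$tagged[tg$unit_id == "weak"])   # fails > 0.2 evoked criterion
  expect_false(tg$tagged[tg$unit_id == "supp"])
  expect_error(tag_units(ses, pulses[1:10]), "at least 20")
})

test_that("EPSP features recover an analytic waveform, with spike clipping", {
  dt <- 5e-5
  tt <- seq(0, 0.2, by = dt)
  onset <- 0.1
  epsp_wave <- function(t) ifelse(t < onset + 0.003, 0,
                                  5 * (1 - exp(-(t - onset - 0.003) / 0.004)))
  vm <- -65 + epsp_wave(tt)
  f <- epsp_features(tt, vm, onset)
  expect_equal(f$baseline_mv, -65, tolerance = 1e-9)
  expect_true(f$connected)
  expect_gt(f$latency_ms, 3)
  expect_lt(f$latency_ms, 4.5)
  expect_gt(f$peak_mv, 4.5)
  # flat trace: unconnected, no latency
  f0 <- epsp_features(tt, rep(-65, length(tt)), onset)
  expect_false(f0$connected)
  expect_true(is.na(f0$latency_ms))
  # spike at +2 ms is clipped; features stay within 10% of spike-free values
  vm_sp <- vm
  sp_idx <- which(tt >= onset + 0.002 & tt < onset + 0.0024)
  vm_sp[sp_idx] <- 20
  f_sp <- epsp_features(tt, vm_sp, onset)
  expect_lt(abs(f_sp$mean_epsp_mv - f$mean_epsp_mv) / abs(f$mean_epsp_mv), 0.1)
  expect_true(f_sp$connected)
})

test_that("membrane time constant fits single and double exponentials", {
  tt <- seq(0, 80, by = 0.05)
  v1 <- 8 * exp(-tt / 15)
  r1 <- membrane_time_constant(tt, v1)
  expect_equal(r1$tau_slow_ms, 15, tolerance = 0.07)
  v2 <- 5 * exp(-tt / 2) + 3 * exp(-tt / 20)
  r2 <- membrane_time_constant(tt, v2)
  expect_equal(r2$tau_slow_ms, 20, tolerance = 0.05)
  expect_equal(r2$tau_fast_ms, 2, tolerance = 0.05)
  set.seed(5)
  expect_error(membrane_time_constant(tt, rnorm(length(tt))), "fit")
})

test_that("connection fractions, bootstrap s.e. and chi-squared comparison", {
  set.seed(21)
  n <- 300
  labels <- rep(c("stimulus", "choice", "action"), each = n / 3)
  tested <- runif(n) < 0.5
  connected <- runif(n) < 0.4   # equal probability everywhere
  cf <- connection_fraction(labels, tested, connected, n_boot = 200, seed = 2)
  expect_equal(nrow(cf$table), 3)
  expect_true(all(cf$table$fraction >= 0 & cf$table$fraction <= 1))
  expect_gt(cf$chisq_p, 0.001)
  # all connected: fraction 1, small s.e.
  cf1 <- connection_fraction(labels, rep(TRUE, n), rep(TRUE, n),
                             n_boot = 100, seed = 3)
  expect_true(all(cf1$table$fraction == 1))
  expect_true(all(cf1$table$se < 0.01))
  # planted 2x difference is detected
  conn2 <- ifelse(labels == "choice", runif(n) < 0.6, runif(n) < 0.3)
  cf2 <- connection_fraction(labels, rep(TRUE, n), conn2, n_boot = 100, seed = 4)
  expect_lt(cf2$chisq_p, 0.05)
})
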