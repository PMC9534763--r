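fake_averages <- function(CR, CL, ER, EL, time = 1) {
  structure(list(time = seq_len(time), n_trials = c(CR = 10, CL = 10, ER = 10, EL = 10),
                 avg = list(CR = cbind(CR), CL = cbind(CL),
                            ER = cbind(ER), EL = cbind(EL)),
                 unit_ids = as.character(seq_along(CR)), window_s = 0.1,
                 delay_duration_s = 1.3),
            class = "condition_averages")
}

test_that("selectivity formulas satisfy their algebraic identities", {
  # hand-arithmetic oracle
  av <- fake_averages(CR = c(2, 0), CL = c(0, 2), ER = c(1, 1), EL = c(1, 1))
  sel <- selectivity_vectors(av)
  expect_equal(as.vector(sel$stimulus), c(1, -1))
  expect_equal(as.vector(sel$choice), c(1, -1))
  expect_equal(as.vector(sel$outcome), c(0, 0))
  # stimulus-only coding (response tracks the instructed type on errors too)
  set.seed(1)
  a <- runif(6); b <- runif(6)
  av_s <- fake_averages(CR = a, CL = b, ER = a, EL = b)
  sel_s <- selectivity_vectors(av_s)
  expect_equal(as.vector(sel_s$choice), rep(0, 6))
  expect_equal(as.vector(sel_s$outcome), rep(0, 6))
  expect_equal(as.vector(sel_s$stimulus), a - b)
  # choice-only coding
  av_c <- fake_averages(CR = a, CL = b, ER = b, EL = a)
  sel_c <- selectivity_vectors(av_c)
  expect_equal(as.vector(sel_c$stimulus), rep(0, 6))
  expect_equal(as.vector(sel_c$choice), a - b)
  av_bad <- fake_averages(a, b, a, b); av_bad$avg$ER <- NULL
  expect_error(selectivity_vectors(av_bad), "ER")
})

test_that("selectivity correlation map has the expected structure", {
  set.seed(2)
  v <- rnorm(30); v <- v - mean(v)
  sel_const <- cbind(v, v * 2, v * 1.5)   # time-constant direction
  cc <- selectivity_correlation_map(sel_const)
  expect_true(all(abs(cc - 1) < 1e-9))
  # orthogonal (centered) regimes before/after a switch
  w <- rnorm(30); w <- w - mean(w); w <- w - v * sum(v * w) / sum(v^2)
  sel_sw <- cbind(v, v, w, w)
  cc2 <- selectivity_correlation_map(sel_sw)
  expect_lt(abs(cc2[1, 3]), 1e-9)
  expect_equal(cc2[1, 2], 1, tolerance = 1e-9)
  # noiseless split halves give a unit diagonal
  cc3 <- selectivity_correlation_map(sel_sw, sel_sw, sel_sw)
  expect_equal(unname(diag(cc3)), rep(1, 4), tolerance = 1e-9)
})

test_that("condition averages recover planted template rates", {
  cfg <- test_config(n_units = 6, n_trials = c(CR = 150, CL = 150, ER = 30, EL = 30),
                     n_prototypes = 1, prototype_modes = 2,
                     mode_amplitude_hz = 10, weight_jitter = 0, seed = 11)
  gs <- generate_session(cfg)
  av <- condition_averages(gs$session, step_ms = 50)
  for (cond in c("CR", "CL")) {
    lam <- planted_rate(gs$truth, 1, cond)
    lam_i <- approx(lam$time, lam$rate, xout = av$time, rule = 2)$y
    se <- sqrt(pmax(lam_i, 1) / (150 * 0.1))
    frac_ok <- mean(abs(av$avg[[cond]][1, ] - lam_i) < 4 * se)
    expect_gt(frac_ok, 0.95)
  }
  # constant-rate unit: all four averages equal the baseline everywhere
  cfg0 <- test_config(n_units = 3, n_trials = c(CR = 200, CL = 200, ER = 40, EL = 40),
                      baseline_range_hz = c(10, 10), mode_amplitude_hz = 0, seed = 12)
  gs0 <- generate_session(cfg0)
  av0 <- condition_averages(gs0$session, step_ms = 100)
  for (cond in names(av0$avg)) {
    se <- sqrt(10 / (av0$n_trials[cond] * 0.1))
    expect_lt(max(abs(av0$avg[[cond]] - 10)), 4.5 * se)
  }
})

test_that("planted modes are recovered with high cosine similarity", {
  cfg <- test_config(n_units = 100, n_trials = c(CR = 80, CL = 80, ER = 16, EL = 16),
                     n_prototypes = 4, prototype_modes = c(1, 2, 4, 5),
                     mode_amplitude_hz = 8, seed = 17)
  gs <- generate_session(cfg)
  sp <- split_trials(gs$session, seed = 1)
  ms <- define_modes(gs$session, trials = sp$definition)
  W_true <- gs$truth$mode_weights
  for (m in c("stimulus", "choice", "outcome", "ramping")) {
    tv <- W_true[, m]
    cs <- abs(sum(ms$modes[, m] * tv)) / sqrt(sum(tv^2))
    expect_gt(cs, 0.8)
  }
})

test_that("Gram-Schmidt orthogonalization yields an exact orthonormal set", {
  set.seed(3)
  raw <- matrix(rnorm(50 * 7), 50, 7, dimnames = list(NULL, popmodes:::mode_names()))
  ms <- structure(list(modes = raw, raw = raw, unit_ids = as.character(1:50),
                       orthogonalized = FALSE, degenerate = character(0)),
                  class = "mode_set")
  og <- orthogonalize_modes(ms)
  G <- crossprod(og$modes)
  expect_lt(max(abs(G - diag(7))), 1e-9)
  # an already-orthogonal set is unchanged up to normalization
  Q <- qr.Q(qr(matrix(rnorm(50 * 7), 50)))
  colnames(Q) <- popmodes:::mode_names()
  msq <- structure(list(modes = Q, raw = Q, unit_ids = as.character(1:50),
                        orthogonalized = FALSE, degenerate = character(0)),
                   class = "mode_set")
  expect_equal(abs(colSums(orthogonalize_modes(msq)$modes * Q)), rep(1, 7),
               tolerance = 1e-9, ignore_attr = TRUE)
  # duplicated mode triggers a collinearity error naming the mode
  dup <- raw; dup[, "choice"] <- dup[, "stimulus"] * 2
  msd <- structure(list(modes = dup, raw = dup, unit_ids = as.character(1:50),
                        orthogonalized = FALSE, degenerate = character(0)),
                   class = "mode_set")
  expect_error(orthogonalize_modes(msd), "choice")
})

test_that("projections behave: zero modes, sign convention, bootstrap scaling", {
  cfg <- test_config(n_units = 60, n_trials = c(CR = 40, CL = 40, ER = 16, EL = 16),
                     n_prototypes = 2, prototype_modes = c(1, 2), seed = 23)
  gs <- generate_session(cfg)
  sp <- split_trials(gs$session, seed = 2)
  ms <- orthogonalize_modes(define_modes(gs$session, trials = sp$definition))
  grp <- list(CR = intersect(sp$projection, gs$session$trials$trial_id[
    gs$session$trials$condition_label == "CR"]),
    empty = integer(0))
  expect_message(pr <- project_modes(ms, gs$session, grp, step_ms = 50,
                                     bootstrap_n = 100, seed = 1), "empty")
  expect_named(pr$proj, "CR")
  # choice mode: lick-right condition projects positively late in the delay
  late <- pr$time > -0.4 & pr$time < 0
  expect_gt(mean(pr$proj$CR["choice", late]), 0)
  # zero mode projects to zero
  ms0 <- ms; ms0$modes[, "go"] <- 0
  pr0 <- project_modes(ms0, gs$session, grp["CR"], step_ms = 50, bootstrap_n = 0)
  expect_true(all(pr0$proj$CR["go", ] == 0))
  # bootstrap s.e. present and positive where projections fluctuate
  expect_true(all(pr$se$CR[, late] > 0))
})

test_that("variance captured is 1 inside the subspace and 0 orthogonal to it", {
  set.seed(5)
  n <- 40; nt <- 120
  Q <- qr.Q(qr(matrix(rnorm(n * 10), n)))
  modes <- Q[, 1:7]; colnames(modes) <- popmodes:::mode_names()
  ms <- structure(list(modes = modes, unit_ids = as.character(1:n),
                       orthogonalized = TRUE, degenerate = character(0)),
                  class = "mode_set")
  tb <- popmodes:::psth_time_grid(1.3, 0.04)
  mk_pm <- function(M) structure(list(matrix = M, unit_ids = as.character(1:n),
                                      time = tb, segments = c("CR", "CL"),
                                      dt_s = 0.04, delay_duration_s = 1.3,
                                      normalized = FALSE,
                                      filter_log = data.frame()),
                                 class = "psth_matrix")
  inside <- modes %*% matrix(rnorm(7 * 2 * length(tb)), 7)
  rownames(inside) <- as.character(1:n)
  expect_equal(variance_captured(ms, mk_pm(inside))$activity, 1, tolerance = 1e-6)
  outside <- Q[, 8:10] %*% matrix(rnorm(3 * 2 * length(tb)), 3)
  rownames(outside) <- as.character(1:n)
  expect_lt(variance_captured(ms, mk_pm(outside))$activity, 1e-9)
  # selectivity fractions: in-subspace selectivity is fully captured,
  # out-of-subspace selectivity not at all
  sel_in <- lapply(1:3, function(i) {
    S <- modes %*% matrix(rnorm(7 * length(tb)), 7)
    rownames(S) <- as.character(1:n); S
  })
  sel <- list(stimulus = sel_in[[1]], choice = sel_in[[2]],
              outcome = sel_in[[3]], time = tb)
  vc <- variance_captured(ms, mk_pm(inside), sel)
  expect_equal(unname(c(vc$stimulus, vc$choice, vc$outcome)), rep(1, 3),
               tolerance = 1e-6)
  S_out <- Q[, 8:10] %*% matrix(rnorm(3 * length(tb)), 3)
  rownames(S_out) <- as.character(1:n)
  sel0 <- list(stimulus = S_out, choice = S_out, outcome = S_out, time = tb)
  vc0 <- variance_captured(ms, mk_pm(inside), sel0)
  expect_lt(vc0$stimulus, 1e-9)
})

test_that("the mixture population preserves variances and projections", {
  cfg <- test_config(n_units = 120, n_trials = c(CR = 60, CL = 60, ER = 12, EL = 12),
                     n_prototypes = 4, prototype_modes = c(1, 2, 4, 5),
                     seed = 29)
  gs <- generate_session(cfg)
  sp <- split_trials(gs$session, seed = 1)
  inputs <- popmodes:::collect_mode_inputs(gs$session, trials = sp$definition)
  ms <- orthogonalize_modes(popmodes:::modes_from_inputs(inputs))
  pm <- build_response_matrix(gs$session, trials = sp$definition, dt_ms = 10,
                              cell_classes = NULL, consistency_threshold = NA,
                              normalize = FALSE)
  syn <- synthesize_mixture_population(ms, pm, inputs = inputs,
                                       n_rows = 2000, seed = 4)
  cv <- syn$component_variance
  big <- cv$original > 1e-4 * max(cv$original)
  expect_lt(max(abs(cv$synthetic[big] / cv$original[big] - 1)), 0.1)
  # population-level projection r.m.s. (aggregate over modes) preserved after
  # re-deriving the modes on the synthetic population
  ms_syn <- orthogonalize_modes(popmodes:::modes_from_inputs(syn$inputs))
  p_orig <- crossprod(ms$modes, pm$matrix)
  p_syn <- crossprod(ms_syn$modes, syn$matrix)
  ratio <- sqrt(sum(p_syn^2) / sum(p_orig^2))
  expect_lt(abs(ratio - 1), 0.1)
  # per-mode for the planted (signal-carrying) modes
  per <- sqrt(rowSums(p_syn^2) / rowSums(p_orig^2))
  expect_lt(max(abs(per[c("stimulus", "choice", "outcome", "ramping")] - 1)), 0.15)
})

test_that("session offsets cancel when pooling simultaneous sessions", {
  mk <- function(seed) generate_session(test_config(
    n_units = 40, n_trials = c(CR = 40, CL = 40, ER = 16, EL = 16),
    n_prototypes = 2, prototype_modes = c(1, 2),
    baseline_range_hz = c(2, 10) + (seed %% 2) * 4, seed = seed))$session
  sessions <- list(mk(41), mk(42))
  pooled <- session_offset_project(sessions, min_units = 10, min_trials = 10,
                                   split_seed = 3, step_ms = 50)
  expect_equal(pooled$n_sessions, 2)
  # offset removal: the global mean across groups is small relative to the
  # projection scale (per-group means carry the signal and need not vanish)
  allp <- unlist(pooled$proj)
  expect_lt(abs(mean(allp)), 0.1 * sqrt(mean(allp^2)))
  expect_error(session_offset_project(sessions, min_units = 1000),
               "no session")
})
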