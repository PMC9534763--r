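# Shared fixtures: tiny sessions built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal hand-built session: 2 units, 4 trials (one per condition).
tiny_session <- function() {
  units <- data.frame(unit_id = c("a", "b"), mouse_id = "m1", session_id = "s1",
                      depth_um = c(200, 600), spike_width_ms = c(0.6, 0.3))
  trials <- data.frame(trial_id = 1:4,
                       instructed_type = c("lick_right", "lick_left",
                                           "lick_right", "lick_left"),
                       correctness = c("correct", "correct", "error", "error"))
  spikes <- list(
    a = list(`1` = c(-2.0, -1.0, 0.5), `2` = c(-0.25), `3` = numeric(0),
             `4` = c(0.1, 0.2)),
    b = list(`1` = c(-3.0), `2` = numeric(0), `3` = c(-0.5, 0.9),
             `4` = numeric(0)))
  trial_aligned_session(units, trials, spikes)
}

# A deterministic-rate session via the generator (cheap defaults for tests).
test_config <- function(...) {
  args <- list(...)
  defaults <- list(n_units = 30, n_trials = c(CR = 30, CL = 30, ER = 8, EL = 8),
                   n_prototypes = 2, bin_ms = 5, seed = 1)
  defaults[names(args)] <- args
  do.call(generator_config, defaults)
}

# Independent density-peak assignment oracle: brute-force re-implementation
# of the published rule (centers keep their label; every other point joins
# its nearest neighbor of higher density, resolved in density order).
dp_assign_oracle <- function(coords, rho, centers) {
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  ord <- order(rho, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  labels <- integer(n)
  labels[centers] <- seq_along(centers)
  for (r in seq_len(n)) {
    i <- ord[r]
    if (labels[i] != 0L) next
    higher <- ord[seq_len(r - 1)]
    j <- higher[which.min(D[i, higher])]
    labels[i] <- labels[j]
  }
  labels
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
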