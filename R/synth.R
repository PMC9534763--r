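#' Default activity-mode temporal templates
#'
#' Seven unit-amplitude temporal profiles mimicking the canonical task-epoch
#' dynamics: stimulus (sample-epoch transient decaying in early delay), choice
#' (late-sample-to-go ramp, persisting into the response), action (phasic burst
#' at movement initiation), outcome (sustained response-epoch signal signed by
#' correctness), ramping (condition-independent delay ramp), go (phasic go-cue
#' transient) and response (condition-independent response-epoch plateau).
#' Trial-type selective templates are multiplied by a sign carried by the
#' condition: stimulus follows the instructed pole position, choice/action the
#' lick direction, outcome the correctness.
#'
#' @param delay_duration_s Delay duration (s).
#' @return Named list of 7 elements, each `list(shape = function(t), sign =
#'   function(cond))` with `cond` a list holding `stim_sign`, `choice_sign`,
#'   `outcome_sign`.
#' @export
default_mode_templates <- function(delay_duration_s = 1.3) {
  ep <- epoch_windows(delay_duration_s)
  ss <- ep$sample[1]; ds <- ep$delay[1]
  ramp01 <- function(t, a, b) pmin(1, pmax(0, (t - a) / (b - a)))
  bump <- function(t, mu, sd) exp(-0.5 * ((t - mu) / sd)^2)
  list(
    stimulus = list(
      shape = function(t) ramp01(t, ss, ss + 0.3) * ifelse(t < ds, 1, exp(-(t - ds) / 0.3)) * (t < 0),
      sign = function(cond) cond$stim_sign),
    choice = list(
      shape = function(t) ramp01(t, ds - 0.4, 0) * ifelse(t < 0, 1, exp(-t / 0.6)),
      sign = function(cond) cond$choice_sign),
    action = list(
      shape = function(t) bump(t, 0.2, 0.06) * (t > 0),
      sign = function(cond) cond$choice_sign),
    outcome = list(
      shape = function(t) ramp01(t, 0.05, 0.25) * (t > 0),
      sign = function(cond) cond$outcome_sign),
    ramping = list(
      shape = function(t) ramp01(t, ss, 0) * (t < 0),
      sign = function(cond) 1),
    go = list(
      shape = function(t) bump(t, 0.05, 0.04) * (t > 0),
      sign = function(cond) 1),
    response = list(
      shape = function(t) ramp01(t, 0.1, 0.3) * exp(-pmax(0, t - 0.3) / 1.5) * (t > 0),
      sign = function(cond) 1)
  )
}

condition_signs <- function(label, instructed_type = NULL) {
  stim <- switch(label,
                 CR = 1, ER = 1, CL = -1, EL = -1,
                 if (identical(instructed_type, "lick_right")) 1 else -1)
  choice <- switch(label, CR = 1, EL = 1, CL = -1, ER = -1, ignore = 0,
                   early_lick = stim)
  outcome <- switch(label, CR = 1, CL = 1, ER = -1, EL = -1, 0)
  list(stim_sign = stim, choice_sign = choice, outcome_sign = outcome)
}

#' Configuration for the synthetic-session generator
#'
#' Defaults describe the emulated study conditions: a few hundred units, ~100
#' correct trials per instructed type with a smaller complement of error,
#' ignore and early-lick trials, a 1.3-s delay, baseline rates of a few
#' spikes/s and mode amplitudes of order the baseline.
#'
#' @param n_units Number of units.
#' @param n_trials Named vector of trial counts per condition label
#'   (`CR`, `CL`, `ER`, `EL`, `ignore`, `early_lick`).
#' @param delay_duration_s Delay duration, 1.3 or 1.7 s.
#' @param n_prototypes Number of prototype coding patterns (clustered regime).
#' @param baseline_range_hz Range of per-unit baseline rates (uniform draw).
#' @param mode_amplitude_hz Rate amplitude (Hz) of a planted unit-norm template.
#' @param mode_amplitude_scale Per-mode multiplier on the amplitude (length
#'   7); lets one component (e.g. the condition-independent response pattern,
#'   which dominates the variance of recorded populations) carry more
#'   variance than the others.
#' @param mixing `"clustered"` (each unit loads on the few modes of its
#'   prototype) or `"random_mixed"` (i.i.d. zero-mean Gaussian weights on all
#'   modes).
#' @param modes_per_unit Active modes per prototype in the clustered regime.
#' @param prototype_modes Mode indices the prototypes cycle through (default
#'   `1:7`); prototypes loading on sustained templates (stimulus, choice,
#'   outcome, ramping) give stronger PSTH clusters than the brief action/go
#'   transients.
#' @param weight_jitter Relative s.d. of per-unit jitter on prototype weights.
#' @param n_subnetworks Number of shared-gain subnetworks.
#' @param gain_sd S.d. of the per-trial shared gain (multiplies the baseline).
#' @param inconsistent_fraction Fraction of units planted with no task signal
#'   (they must fail the split-half consistency filter downstream).
#' @param bin_ms Bin width for inhomogeneous-Poisson spike generation.
#' @param photostim Optional `list(target=, epoch=, fraction=, power_mW=)`
#'   marking a random fraction of trials as photostimulation trials.
#' @param templates Mode temporal templates; see [default_mode_templates()].
#' @param seed Integer seed; the generator is deterministic given it.
#' @return `generator_config` object.
#' @export
generator_config <- function(n_units = 200,
                             n_trials = c(CR = 100, CL = 100, ER = 16, EL = 16,
                                          ignore = 4, early_lick = 4),
                             delay_duration_s = 1.3,
                             n_prototypes = 5,
                             baseline_range_hz = c(2, 10),
                             mode_amplitude_hz = 8,
                             mode_amplitude_scale = rep(1, 7),
                             mixing = c("clustered", "random_mixed"),
                             modes_per_unit = 1,
                             prototype_modes = 1:7,
                             weight_jitter = 0.1,
                             n_subnetworks = 2,
                             gain_sd = 0,
                             inconsistent_fraction = 0,
                             bin_ms = 1,
                             photostim = NULL,
                             templates = NULL,
                             seed = 1) {
  mixing <- match.arg(mixing)
  stopifnot(n_units >= 2, all(n_trials >= 0), delay_duration_s > 0,
            bin_ms > 0, gain_sd >= 0, inconsistent_fraction >= 0,
            inconsistent_fraction < 1)
  full <- c(CR = 0, CL = 0, ER = 0, EL = 0, ignore = 0, early_lick = 0)
  full[names(n_trials)] <- n_trials
  structure(list(n_units = n_units, n_trials = full,
                 delay_duration_s = delay_duration_s,
                 n_prototypes = n_prototypes,
                 baseline_range_hz = baseline_range_hz,
                 mode_amplitude_hz = mode_amplitude_hz,
                 mode_amplitude_scale = mode_amplitude_scale, mixing = mixing,
                 modes_per_unit = modes_per_unit,
                 prototype_modes = prototype_modes,
                 weight_jitter = weight_jitter,
                 n_subnetworks = n_subnetworks, gain_sd = gain_sd,
                 inconsistent_fraction = inconsistent_fraction,
                 bin_ms = bin_ms, photostim = photostim,
                 templates = templates %||% default_mode_templates(delay_duration_s),
                 seed = seed),
            class = "generator_config")
}

mode_names <- function() c("stimulus", "choice", "action", "outcome",
                           "ramping", "go", "response")

# 7 x n_bins signed template matrix for one condition label
template_matrix <- function(templates, t, label, instructed_type) {
  cs <- condition_signs(label, instructed_type)
  out <- matrix(0, length(templates), length(t),
                dimnames = list(names(templates), NULL))
  for (m in seq_along(templates)) {
    sh <- templates[[m]]$shape(t)
    if (length(sh) != length(t)) stop("template shorter than trial window")
    out[m, ] <- templates[[m]]$sign(cs) * sh
  }
  out
}

#' Generate a synthetic trial-aligned session with known ground truth
#'
#' Each unit's trial-type-conditional rate is
#' \deqn{\lambda_i(t) = \max(0,\; b_i + \sum_m w_{im} f_m(t, \mathrm{cond}) + g_k b_i)}
#' with baseline \eqn{b_i}, planted mode weights \eqn{w_{im}}, signed temporal
#' templates \eqn{f_m} and a per-trial gain \eqn{g_k} shared by units of the
#' same subnetwork (inducing positive noise correlations within subnetworks).
#' Spikes are drawn as an inhomogeneous Poisson process on the configured bin
#' grid. Deterministic given `config$seed`; spike draws use per-(unit, trial)
#' substreams so subsets of units or trials regenerate identically.
#'
#' @param config A [generator_config()].
#' @return `list(session = trial_aligned_session, truth = ground_truth)`. The
#'   truth holds `prototype_id`, `mode_weights` (n x 7), `subnetwork_id`,
#'   `baseline_hz`, the per-condition signed template matrices and the bin
#'   time grid.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  ep <- epoch_windows(cf$delay_duration_s)
  dt <- cf$bin_ms / 1000
  t0 <- ep$presample[1]; t1 <- ep$response[2]
  edges <- seq(t0, t1, by = dt)
  tb <- edges[-length(edges)] + dt / 2
  nb <- length(tb)

  n <- cf$n_units
  units <- with_seed(substream_seed(cf$seed, 1), {
    data.frame(unit_id = sprintf("u%04d", seq_len(n)),
               mouse_id = "m01", session_id = "s01",
               depth_um = runif(n, 80, 900),
               spike_width_ms = 0.6,
               stringsAsFactors = FALSE)
  })
  subnet <- rep_len(seq_len(cf$n_subnetworks), n)
  units$subnetwork <- subnet

  amp <- cf$mode_amplitude_hz
  W <- matrix(0, n, 7, dimnames = list(units$unit_id, mode_names()))
  proto <- rep(NA_integer_, n)
  n_bad <- floor(cf$inconsistent_fraction * n)
  good <- seq_len(n - n_bad)
  with_seed(substream_seed(cf$seed, 2), {
    if (cf$mixing == "clustered") {
      proto[good] <- rep_len(seq_len(cf$n_prototypes), length(good))
      P <- matrix(0, cf$n_prototypes, 7)
      pmods <- cf$prototype_modes
      for (p in seq_len(cf$n_prototypes)) {
        act <- pmods[((p - 1 + seq_len(cf$modes_per_unit) - 1) %% length(pmods)) + 1]
        P[p, act] <- amp * cf$mode_amplitude_scale[act]
      }
      for (i in good) {
        w <- P[proto[i], ]
        jit <- 1 + cf$weight_jitter * rnorm(7)
        W[i, ] <- w * jit
      }
    } else {
      W[good, ] <- matrix(rnorm(length(good) * 7, sd = amp / 2),
                          length(good), 7) %*% diag(cf$mode_amplitude_scale)
    }
  })
  base <- with_seed(substream_seed(cf$seed, 3),
                    runif(n, cf$baseline_range_hz[1], cf$baseline_range_hz[2]))

  counts <- cf$n_trials[cf$n_trials > 0]
  labels <- rep(names(counts), counts)
  ntr <- length(labels)
  instructed <- ifelse(labels %in% c("CR", "ER"), "lick_right",
                ifelse(labels %in% c("CL", "EL"), "lick_left", NA))
  # ignore / early-lick trials get instructed types alternately
  with_seed(substream_seed(cf$seed, 4), {
    na_idx <- which(is.na(instructed))
    instructed[na_idx] <- sample(c("lick_right", "lick_left"), length(na_idx),
                                 replace = TRUE)
  })
  correctness <- ifelse(labels %in% c("CR", "CL"), "correct",
                 ifelse(labels %in% c("ER", "EL"), "error", labels))
  trials <- data.frame(trial_id = seq_len(ntr), instructed_type = instructed,
                       correctness = correctness, stringsAsFactors = FALSE)
  trials$reaction_time_ms <- with_seed(substream_seed(cf$seed, 5),
    ifelse(correctness == "ignore", NA_real_,
           ifelse(correctness == "early_lick", 100 + 50 * runif(ntr),
                  exp(rnorm(ntr, log(250), 0.25)))))
  trials$photostim_target <- NA_character_
  trials$photostim_epoch <- NA_character_
  trials$photostim_power_mW <- NA_real_
  if (!is.null(cf$photostim)) {
    eligible <- which(!(correctness %in% c("ignore", "early_lick")))
    pick <- with_seed(substream_seed(cf$seed, 6),
                      sample(eligible, round(cf$photostim$fraction * length(eligible))))
    trials$photostim_target[pick] <- cf$photostim$target
    trials$photostim_epoch[pick] <- cf$photostim$epoch
    trials$photostim_power_mW[pick] <- cf$photostim$power_mW %||% 3
  }

  # condition-wise deterministic rate component, n x nb
  cond_keys <- unique(data.frame(label = labels, instructed, stringsAsFactors = FALSE))
  lam0 <- list()
  for (r in seq_len(nrow(cond_keys))) {
    Tm <- template_matrix(cf$templates, tb, cond_keys$label[r], cond_keys$instructed[r])
    lam0[[paste(cond_keys$label[r], cond_keys$instructed[r])]] <- base + W %*% Tm
  }

  spikes <- vector("list", n)
  names(spikes) <- units$unit_id
  for (i in seq_len(n)) spikes[[i]] <- vector("list", ntr)
  for (k in seq_len(ntr)) {
    g <- if (cf$gain_sd > 0) {
      with_seed(substream_seed(cf$seed, 7, k), rnorm(cf$n_subnetworks, 0, cf$gain_sd))
    } else rep(0, cf$n_subnetworks)
    L <- lam0[[paste(labels[k], instructed[k])]]
    for (i in seq_len(n)) {
      lam <- pmax(0, L[i, ] + g[subnet[i]] * base[i])
      st <- with_seed(substream_seed(cf$seed, 8, k, i), {
        cts <- rpois(nb, lam * dt)
        tot <- sum(cts)
        if (tot == 0) numeric(0) else
          sort(rep(tb, cts) + (runif(tot) - 0.5) * dt)
      })
      spikes[[i]][[k]] <- st
    }
    for (i in seq_len(n)) names(spikes[[i]])[k] <- as.character(k)
  }

  session <- trial_aligned_session(units, trials, spikes,
                                   delay_duration_s = cf$delay_duration_s)
  truth <- structure(list(prototype_id = proto, mode_weights = W,
                          mixing_regime = cf$mixing, subnetwork_id = subnet,
                          gain_sd = cf$gain_sd, baseline_hz = base,
                          time = tb, bin_s = dt,
                          templates = lam0, config = cf, seed = cf$seed),
                     class = "ground_truth")
  list(session = session, truth = truth)
}

#' Planted firing rate of a synthetic unit
#'
#' The noiseless rate \eqn{\lambda_i(t)} (gain term excluded) for a unit and
#' condition, evaluated on the generator's bin grid.
#'
#' @param truth `ground_truth` from [generate_session()].
#' @param unit Unit index or id.
#' @param label Condition label (`CR`, `CL`, `ER`, `EL`, ...).
#' @param instructed_type Needed only for ignore/early-lick labels.
#' @return `list(time, rate)` in spikes/s.
#' @export
planted_rate <- function(truth, unit, label, instructed_type = NULL) {
  if (is.character(unit)) unit <- match(unit, rownames(truth$mode_weights))
  key <- paste(label, switch(label, CR = "lick_right", ER = "lick_right",
                             CL = "lick_left", EL = "lick_left", instructed_type))
  L <- truth$templates[[key]]
  if (is.null(L)) stop("condition not present in generated session: ", key)
  list(time = truth$time, rate = pmax(0, L[unit, ]))
}

#' Apply a multiplicative photoinhibition effect to a session
#'
#' Rescales firing on photostimulation trials inside the stimulation epoch by a
#' per-(subnetwork, target) factor; control trials are untouched. Factors
#' \eqn{\le 1} are applied by exact Poisson thinning of the existing spikes;
#' factors \eqn{> 1} superpose additional Poisson spikes and therefore require
#' the generator `truth`.
#'
#' @param session A `trial_aligned_session` with photostim-labeled trials.
#' @param effect_map data.frame with columns `subnetwork`, `target`, `epoch`,
#'   `factor` (multiplicative rate factor, `>= 0`).
#' @param truth Optional `ground_truth`; required when any `factor > 1`.
#' @param seed Seed for the thinning/superposition draws.
#' @return The perturbed session.
#' @export
apply_perturbation <- function(session, effect_map, truth = NULL, seed = 1) {
  effect_map <- as.data.frame(effect_map)
  stopifnot(all(c("subnetwork", "target", "epoch", "factor") %in% names(effect_map)))
  if (any(effect_map$factor < 0)) stop("perturbation factor must be >= 0")
  if (any(effect_map$factor > 1) && is.null(truth)) {
    stop("factor > 1 requires the generator truth to superpose spikes")
  }
  ep <- epoch_windows(session$delay_duration_s)
  subnet <- session$units$subnetwork
  if (is.null(subnet)) stop("session units lack a 'subnetwork' column")
  tr <- session$trials
  for (r in seq_len(nrow(effect_map))) {
    f <- effect_map$factor[r]
    if (f == 1) next
    win <- ep[[effect_map$epoch[r]]]
    ks <- which(!is.na(tr$photostim_target) &
                  tr$photostim_target == effect_map$target[r] &
                  tr$photostim_epoch == effect_map$epoch[r])
    uidx <- which(subnet == effect_map$subnetwork[r])
    for (k in ks) {
      tid <- as.character(tr$trial_id[k])
      for (i in uidx) {
        uid <- session$units$unit_id[i]
        st <- session$spikes[[uid]][[tid]] %||% numeric(0)
        sel <- st >= win[1] & st < win[2]
        st_new <- with_seed(substream_seed(seed, 9, k, i), {
          kept <- if (f <= 1) {
            c(st[!sel], st[sel][runif(sum(sel)) < f])
          } else {
            lam <- planted_rate(truth, i, tr$condition_label[k],
                                tr$instructed_type[k])
            bsel <- lam$time >= win[1] & lam$time < win[2]
            extra_cts <- rpois(sum(bsel), (f - 1) * lam$rate[bsel] * truth$bin_s)
            extra <- rep(lam$time[bsel], extra_cts) +
              (runif(sum(extra_cts)) - 0.5) * truth$bin_s
            c(st, extra)
          }
          sort(kept)
        })
        session$spikes[[uid]][[tid]] <- st_new
      }
    }
  }
  session
}
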