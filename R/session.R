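#' Spike-width classification of units
#'
#' Classifies units by the trough-to-peak interval of the mean spike waveform:
#' narrow-spiking units (< 0.35 ms) are putative fast-spiking interneurons,
#' broad-spiking units (> 0.45 ms) putative pyramidal neurons, and units with
#' intermediate widths (0.35--0.45 ms, inclusive) are excluded from analysis.
#'
#' @param spike_width_ms Trough-to-peak interval in milliseconds (vectorized).
#' @return Character vector with levels `"fast_spiking"`, `"pyramidal"`,
#'   `"excluded_intermediate"`.
#' @export
classify_cell_type <- function(spike_width_ms) {
  if (any(!is.finite(spike_width_ms)) || any(spike_width_ms <= 0)) {
    stop("spike_width_ms must be positive and finite")
  }
  ifelse(spike_width_ms < 0.35, "fast_spiking",
         ifelse(spike_width_ms > 0.45, "pyramidal", "excluded_intermediate"))
}

#' Default cortical layer boundaries (micrometers below pia)
#'
#' Mean depths of the L1/L2-3, L2-3/L5 and L5/L6 boundaries reconstructed from
#' probe-track registration to the Allen CCFv3.
#' @export
default_layer_boundaries <- function() c(110, 378.3, 771.7)

#' Assign cortical layer from recording depth
#'
#' Piecewise-constant lookup against the layer boundaries; intervals are
#' half-open `[lower, upper)`.
#'
#' @param depth_um Depth below pia in micrometers (vectorized).
#' @param boundaries Three increasing boundary depths; defaults to
#'   [default_layer_boundaries()].
#' @return Character vector with levels `"L1"`, `"L2/3"`, `"L5"`, `"L6"`.
#' @export
assign_layer <- function(depth_um, boundaries = default_layer_boundaries()) {
  if (any(depth_um < 0)) stop("depth_um must be >= 0")
  stopifnot(length(boundaries) == 3, !is.unsorted(boundaries))
  layers <- c("L1", "L2/3", "L5", "L6")
  layers[findInterval(depth_um, boundaries, left.open = FALSE) + 1L]
}

#' Task epoch windows on the go-cue-aligned time axis
#'
#' Time zero is the go cue. The sample epoch (default 1.3 s) precedes the
#' delay epoch (1.3 s in the primary configuration, 1.7 s in the long-delay
#' configuration); the presample (baseline) window is the 500 ms before the
#' sample epoch; the response window is the 1.3 s after the go cue.
#'
#' @param delay_duration_s Delay-epoch duration in seconds (1.3 or 1.7).
#' @param sample_duration_s Sample-epoch duration in seconds.
#' @param response_duration_s Response-window duration in seconds.
#' @param presample_duration_s Baseline-window duration in seconds.
#' @return Named list of `c(start, end)` windows: `presample`, `sample`,
#'   `delay`, `response`.
#' @export
epoch_windows <- function(delay_duration_s = 1.3, sample_duration_s = 1.3,
                          response_duration_s = 1.3, presample_duration_s = 0.5) {
  delay_start <- -delay_duration_s
  sample_start <- delay_start - sample_duration_s
  list(
    presample = c(sample_start - presample_duration_s, sample_start),
    sample = c(sample_start, delay_start),
    delay = c(delay_start, 0),
    response = c(0, response_duration_s)
  )
}

condition_label_for <- function(instructed_type, correctness) {
  ifelse(correctness %in% c("ignore", "early_lick"), correctness,
  ifelse(correctness == "correct",
         ifelse(instructed_type == "lick_right", "CR", "CL"),
         ifelse(instructed_type == "lick_right", "ER", "EL")))
}

#' Construct a trial-aligned session
#'
#' The universal input container of the pipeline: a table of units, a table of
#' trials, and per-(unit, trial) spike times in seconds relative to the go cue.
#'
#' @param units data.frame with columns `unit_id`, `mouse_id`, `session_id`,
#'   `depth_um`, `spike_width_ms`; `cell_class` and `layer` are derived if
#'   absent.
#' @param trials data.frame with columns `trial_id`, `instructed_type`
#'   (`lick_right`/`lick_left`), `correctness` (`correct`/`error`/`ignore`/
#'   `early_lick`), and optionally `response`, `reaction_time_ms`,
#'   `photostim_target`, `photostim_epoch`, `photostim_power_mW`.
#'   `condition_label` is derived. `sample_start_s`/`delay_start_s` are filled
#'   from `delay_duration_s` if absent.
#' @param spikes Nested list: `spikes[[unit_id]][[as.character(trial_id)]]` is
#'   a sorted numeric vector of spike times (s, go-cue aligned).
#' @param delay_duration_s Delay duration shared by all trials.
#' @param validate Run [validate_session()]?
#' @return Object of class `trial_aligned_session`.
#' @export
trial_aligned_session <- function(units, trials, spikes, delay_duration_s = 1.3,
                                  validate = TRUE) {
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  if (is.null(units$cell_class)) units$cell_class <- classify_cell_type(units$spike_width_ms)
  if (is.null(units$layer)) units$layer <- assign_layer(units$depth_um)
  ep <- epoch_windows(delay_duration_s)
  if (is.null(trials$sample_start_s)) trials$sample_start_s <- ep$sample[1]
  if (is.null(trials$delay_start_s)) trials$delay_start_s <- ep$delay[1]
  if (is.null(trials$go_cue_time_s)) trials$go_cue_time_s <- 0
  if (is.null(trials$response)) {
    trials$response <- ifelse(trials$correctness == "ignore", "none",
      ifelse(xor(trials$instructed_type == "lick_right",
                 trials$correctness == "error"), "right", "left"))
  }
  if (is.null(trials$reaction_time_ms)) trials$reaction_time_ms <- NA_real_
  trials$condition_label <- condition_label_for(trials$instructed_type, trials$correctness)
  ses <- structure(list(units = units, trials = trials, spikes = spikes,
                        delay_duration_s = delay_duration_s),
                   class = "trial_aligned_session")
  if (validate) ses <- validate_session(ses)
  ses
}

#' Validate a trial-aligned session
#'
#' Checks the container invariants: required columns present, epoch ordering
#' `sample_start_s < delay_start_s < 0`, condition labels consistent with
#' instructed type and correctness, spike keys referencing existing units and
#' trials. Unsorted spike-time vectors are repaired with a warning.
#'
#' @param session A `trial_aligned_session`.
#' @return The (possibly repaired) session, invisibly valid.
#' @export
validate_session <- function(session) {
  u <- session$units; tr <- session$trials
  for (f in c("unit_id", "mouse_id", "session_id", "depth_um", "spike_width_ms")) {
    if (is.null(u[[f]])) stop_field(f, "missing from units table")
  }
  for (f in c("trial_id", "instructed_type", "correctness", "sample_start_s",
              "delay_start_s")) {
    if (is.null(tr[[f]])) stop_field(f, "missing from trials table")
  }
  if (anyDuplicated(u$unit_id)) stop_field("unit_id", "duplicated")
  if (anyDuplicated(tr$trial_id)) stop_field("trial_id", "duplicated")
  if (any(!(tr$sample_start_s < tr$delay_start_s & tr$delay_start_s < 0))) {
    stop_field("delay_start_s", "epoch ordering violated (need sample_start_s < delay_start_s < 0)")
  }
  if (any(u$depth_um < 0)) stop_field("depth_um", "negative depth")
  rt <- tr$reaction_time_ms
  if (any(!is.na(rt) & rt <= 0)) stop_field("reaction_time_ms", "must be positive when present")
  bad_inst <- tr$condition_label %in% c("CR", "ER") & tr$instructed_type != "lick_right"
  if (any(bad_inst)) stop_field("condition_label", "CR/ER trials must be instructed lick_right")
  known_t <- as.character(tr$trial_id)
  nrep <- 0L
  for (uid in names(session$spikes)) {
    if (!(uid %in% u$unit_id)) stop_field("spikes", sprintf("unknown unit_id '%s'", uid))
    st <- session$spikes[[uid]]
    unknown <- setdiff(names(st), known_t)
    if (length(unknown)) stop_field("spikes", sprintf("unknown trial_id '%s'", unknown[1]))
    for (tid in names(st)) {
      if (is.unsorted(st[[tid]])) {
        session$spikes[[uid]][[tid]] <- sort(st[[tid]])
        nrep <- nrep + 1L
      }
    }
  }
  if (nrep > 0) warning(sprintf("repaired %d unsorted spike-time vectors", nrep))
  session
}

#' @export
print.trial_aligned_session <- function(x, ...) {
  cat(sprintf("trial_aligned_session: %d units, %d trials, delay %.1f s\n",
              nrow(x$units), nrow(x$trials), x$delay_duration_s))
  cat("  conditions:", paste(sprintf("%s=%d", names(table(x$trials$condition_label)),
                                     table(x$trials$condition_label)), collapse = " "), "\n")
  invisible(x)
}

spikes_of <- function(session, unit_id, trial_id) {
  session$spikes[[as.character(unit_id)]][[as.character(trial_id)]] %||% numeric(0)
}

#' Write a session to a plain-text container
#'
#' Writes a directory holding `units.csv`, `trials.csv`, `spikes.csv`
#' (columns `unit_id`, `trial_id`, `time_s`) and `session.json` (container
#' attributes). Round-trips through [read_session()].
#'
#' @param session A `trial_aligned_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(session$units, file.path(path, "units.csv"), row.names = FALSE)
  write.csv(session$trials, file.path(path, "trials.csv"), row.names = FALSE)
  rows <- list()
  for (uid in names(session$spikes)) {
    for (tid in names(session$spikes[[uid]])) {
      st <- session$spikes[[uid]][[tid]]
      if (length(st)) rows[[length(rows) + 1L]] <-
          data.frame(unit_id = uid, trial_id = tid, time_s = st)
    }
  }
  sp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(0), trial_id = character(0), time_s = numeric(0))
  write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  writeLines(sprintf('{"delay_duration_s": %.17g, "format": "popmodes-csv-v1"}',
                     session$delay_duration_s),
             file.path(path, "session.json"))
  invisible(path)
}

#' Read a session from the plain-text container
#'
#' @param path Directory written by [write_session()].
#' @param dialect Container dialect; only `"csv"` is supported.
#' @return A validated `trial_aligned_session`.
#' @export
read_session <- function(path, dialect = "csv") {
  dialect <- match.arg(dialect)
  for (f in c("units.csv", "trials.csv", "spikes.csv")) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("container at '%s' is missing %s", path, f), call. = FALSE)
    }
  }
  units <- read.csv(file.path(path, "units.csv"), stringsAsFactors = FALSE)
  trials <- read.csv(file.path(path, "trials.csv"), stringsAsFactors = FALSE)
  sp <- read.csv(file.path(path, "spikes.csv"), stringsAsFactors = FALSE)
  for (f in c("unit_id", "mouse_id", "session_id", "depth_um", "spike_width_ms")) {
    if (is.null(units[[f]])) stop_field(f, "missing from units.csv")
  }
  for (f in c("trial_id", "instructed_type", "correctness", "sample_start_s",
              "delay_start_s")) {
    if (is.null(trials[[f]])) stop_field(f, "missing from trials.csv")
  }
  meta_file <- file.path(path, "session.json")
  delay <- if (file.exists(meta_file)) {
    txt <- paste(readLines(meta_file), collapse = "")
    as.numeric(sub('.*"delay_duration_s": *([0-9.eE+-]+).*', "\\1", txt))
  } else {
    stop_field("delay_duration_s", "session.json missing from container")
  }
  units$unit_id <- as.character(units$unit_id)
  spikes <- list()
  if (nrow(sp)) {
    sp$unit_id <- as.character(sp$unit_id)
    sp$trial_id <- as.character(sp$trial_id)
    spikes <- lapply(split(sp, sp$unit_id), function(d) {
      lapply(split(d$time_s, d$trial_id), as.numeric)
    })
  }
  # units with no spikes anywhere still need an (empty) entry
  for (uid in setdiff(units$unit_id, names(spikes))) spikes[[uid]] <- list()
  trial_aligned_session(units, trials, spikes, delay_duration_s = delay)
}
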