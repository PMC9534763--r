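psth_time_grid <- function(delay_duration_s, dt_s) {
  ep <- epoch_windows(delay_duration_s)
  edges <- seq(ep$presample[1], ep$response[2], by = dt_s)
  edges[-length(edges)] + dt_s / 2
}

smooth_rate <- function(raw, kernel, width_bins) {
  if (width_bins <= 1) return(raw)
  if (kernel == "boxcar") {
    # causal boxcar: rate(t) averages the preceding width
    kern <- rep(1 / width_bins, width_bins)
    out <- stats::filter(c(rep(0, width_bins - 1), raw), kern, sides = 1)
    as.numeric(out[width_bins:(length(raw) + width_bins - 1)])
  } else {
    sdb <- width_bins / 4
    half <- ceiling(3 * sdb)
    kern <- exp(-0.5 * ((-half:half) / sdb)^2)
    kern <- kern / sum(kern)
    n <- length(raw)
    padded <- c(rep(0, half), raw, rep(0, half))
    out <- stats::filter(padded, kern, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
}

#' Peri-stimulus time histogram of one unit
#'
#' Trial-averaged spike rate on a uniform go-cue-aligned grid spanning the
#' presample through response epochs, smoothed with a causal boxcar (default
#' 100 ms, matching the analysis windows used elsewhere in the pipeline) or a
#' Gaussian kernel.
#'
#' @param session A `trial_aligned_session`.
#' @param unit_id Unit id.
#' @param condition Condition label (`CR`, `CL`, ...); ignored when `trials`
#'   is given.
#' @param trials Optional explicit vector of trial ids.
#' @param kernel `"boxcar"` (causal) or `"gaussian"`.
#' @param width_ms Kernel width (boxcar length, or 4 s.d. of the Gaussian).
#' @param dt_ms Grid step in ms.
#' @return Object of class `psth`: `list(unit_id, condition, time, rate,
#'   n_trials)` with `rate` in spikes/s.
#' @export
compute_psth <- function(session, unit_id, condition = "CR", trials = NULL,
                         kernel = c("boxcar", "gaussian"), width_ms = 100,
                         dt_ms = 1) {
  kernel <- match.arg(kernel)
  dt <- dt_ms / 1000
  tids <- trials %||% session$trials$trial_id[session$trials$condition_label == condition]
  if (length(tids) == 0) stop("zero trials for condition ", condition)
  tb <- psth_time_grid(session$delay_duration_s, dt)
  edges <- c(tb - dt / 2, tb[length(tb)] + dt / 2)
  counts <- numeric(length(tb))
  all_st <- unlist(lapply(tids, function(tid) spikes_of(session, unit_id, tid)),
                   use.names = FALSE)
  if (length(all_st)) {
    h <- findInterval(all_st, edges, left.open = FALSE)
    h <- h[h >= 1 & h <= length(tb)]
    counts <- tabulate(h, nbins = length(tb))
  }
  raw <- counts / (length(tids) * dt)
  rate <- smooth_rate(raw, kernel, round(width_ms / dt_ms))
  structure(list(unit_id = unit_id, condition = condition, time = tb,
                 rate = rate, n_trials = length(tids)),
            class = "psth")
}

#' Split-half PSTH consistency of a unit
#'
#' Splits each condition's trials into interleaved (odd/even) halves, computes
#' the concatenated PSTH for each half, and returns their Pearson correlation.
#' Units below the threshold (default 0.5; the comparison is inclusive, so
#' exactly 0.5 passes) are flagged for exclusion.
#'
#' @param session A `trial_aligned_session`.
#' @param unit_id Unit id.
#' @param conditions Condition labels to concatenate (default correct trials
#'   of both instructed types).
#' @param threshold Pass threshold on the correlation.
#' @param ... Passed to [compute_psth()] (kernel, widths, `dt_ms`).
#' @return `list(correlation, pass, reason)`.
#' @export
split_half_consistency <- function(session, unit_id, conditions = c("CR", "CL"),
                                   threshold = 0.5, ...) {
  h1 <- h2 <- numeric(0)
  for (cond in conditions) {
    tids <- session$trials$trial_id[session$trials$condition_label == cond]
    if (length(tids) < 2) {
      return(list(correlation = NA_real_, pass = FALSE,
                  reason = sprintf("fewer than 2 trials of %s", cond)))
    }
    odd <- tids[seq_along(tids) %% 2 == 1]
    even <- tids[seq_along(tids) %% 2 == 0]
    h1 <- c(h1, compute_psth(session, unit_id, trials = odd, ...)$rate)
    h2 <- c(h2, compute_psth(session, unit_id, trials = even, ...)$rate)
  }
  if (sd(h1) == 0 || sd(h2) == 0) {
    return(list(correlation = NA_real_, pass = FALSE,
                reason = "constant PSTH (zero variance)"))
  }
  r <- cor(h1, h2)
  list(correlation = r, pass = r >= threshold, reason = NA_character_)
}

#' Build the population response matrix
#'
#' Rows are per-unit concatenated correct-trial PSTHs (lick-right then
#' lick-left), each segment baseline-subtracted by its mean over the 500-ms
#' presample window, and the concatenated row divided by its Euclidean norm.
#' Units failing the cell-class or split-half-consistency filters, or with an
#' all-zero row, are excluded and logged.
#'
#' @param session A `trial_aligned_session`.
#' @param units Unit ids to consider (default all).
#' @param conditions Two condition labels forming the row segments.
#' @param cell_classes Cell classes retained (default putative pyramidal).
#' @param consistency_threshold Split-half threshold; `NA` disables the filter.
#' @param trials Optional trial-id subset (intersected with the conditions).
#' @param kernel,width_ms,dt_ms Passed to [compute_psth()].
#' @param normalize Divide each row by its norm (default TRUE).
#' @return Object of class `psth_matrix`: `list(matrix, unit_ids, time,
#'   segments, dt_s, delay_duration_s, filter_log)`.
#' @export
build_response_matrix <- function(session, units = NULL,
                                  conditions = c("CR", "CL"),
                                  cell_classes = "pyramidal",
                                  consistency_threshold = 0.5,
                                  trials = NULL,
                                  kernel = "boxcar", width_ms = 100, dt_ms = 1,
                                  normalize = TRUE) {
  u <- session$units
  units <- units %||% u$unit_id
  log <- list()
  keep <- character(0)
  for (uid in units) {
    cc <- u$cell_class[u$unit_id == uid]
    if (!is.null(cell_classes) && !(cc %in% cell_classes)) {
      log[[uid]] <- sprintf("cell class %s", cc); next
    }
    if (!is.na(consistency_threshold)) {
      sh <- split_half_consistency(session, uid, conditions,
                                   threshold = consistency_threshold,
                                   kernel = kernel, width_ms = width_ms,
                                   dt_ms = dt_ms)
      if (!sh$pass) {
        log[[uid]] <- sh$reason %||% "inconsistent PSTH"
        if (is.na(log[[uid]])) log[[uid]] <- sprintf("split-half r = %.2f < %.2f",
                                                     sh$correlation,
                                                     consistency_threshold)
        next
      }
    }
    keep <- c(keep, uid)
  }
  ep <- epoch_windows(session$delay_duration_s)
  dt <- dt_ms / 1000
  tb <- psth_time_grid(session$delay_duration_s, dt)
  pre <- tb >= ep$presample[1] & tb < ep$presample[2]
  rows <- list()
  for (uid in keep) {
    segs <- lapply(conditions, function(cond) {
      tids <- session$trials$trial_id[session$trials$condition_label == cond]
      if (!is.null(trials)) tids <- intersect(tids, trials)
      r <- compute_psth(session, uid, trials = tids, kernel = kernel,
                        width_ms = width_ms, dt_ms = dt_ms)$rate
      r - mean(r[pre])
    })
    row <- unlist(segs, use.names = FALSE)
    nrm <- sqrt(sum(row^2))
    if (normalize && nrm == 0) {
      log[[uid]] <- "zero norm"
    } else {
      rows[[uid]] <- if (normalize) row / nrm else row
    }
  }
  if (length(rows) < 2) stop("fewer than 2 units survive the filters")
  M <- do.call(rbind, rows)
  rownames(M) <- names(rows)
  flog <- if (length(log)) {
    data.frame(unit_id = names(log), reason = unlist(log), row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    data.frame(unit_id = character(0), reason = character(0))
  }
  structure(list(matrix = M, unit_ids = rownames(M), time = tb,
                 segments = conditions, dt_s = dt,
                 delay_duration_s = session$delay_duration_s,
                 normalized = normalize, filter_log = flog),
            class = "psth_matrix")
}

#' @export
print.psth_matrix <- function(x, ...) {
  cat(sprintf("psth_matrix: %d units x %d time points (%s; delay %.1f s; %d excluded)\n",
              nrow(x$matrix), ncol(x$matrix), paste(x$segments, collapse = "+"),
              x$delay_duration_s, nrow(x$filter_log)))
  invisible(x)
}

#' Resample the delay segment of a long-delay response matrix
#'
#' Maps a 1.7-s-delay response matrix onto the 1.3-s-delay grid by linearly
#' interpolating the delay segment of each row onto the compressed time base;
#' presample/sample and response segments are untouched and rows are
#' re-normalized. Exact for constant and linear-ramp delay activity and
#' amplitude-faithful for any component smooth on the 100-ms kernel scale.
#'
#' @param pm A `psth_matrix` built with `from_delay`.
#' @param from_delay,to_delay Source and target delay durations (s).
#' @return A `psth_matrix` on the target grid.
#' @export
resample_delay <- function(pm, from_delay = 1.7, to_delay = 1.3) {
  stopifnot(inherits(pm, "psth_matrix"))
  if (!isTRUE(all.equal(pm$delay_duration_s, from_delay))) {
    stop(sprintf("matrix delay is %.2f s, expected %.2f s", pm$delay_duration_s,
                 from_delay))
  }
  tb <- pm$time
  nt <- length(tb)
  in_delay <- tb >= -from_delay & tb < 0
  n_new <- round(sum(in_delay) * to_delay / from_delay)
  # source positions for the new delay grid, linearly compressed
  src <- seq(tb[in_delay][1], tb[in_delay][sum(in_delay)], length.out = n_new)
  tb_new_seg <- src * to_delay / from_delay
  pre_idx <- which(tb < -from_delay)
  post_idx <- which(tb >= 0)
  resample_row <- function(seg_full) {
    d <- seg_full[in_delay]
    stats::approx(tb[in_delay], d, xout = src, rule = 2)$y
  }
  nseg <- length(pm$segments)
  seg_len <- nt
  out_rows <- vector("list", nrow(pm$matrix))
  for (i in seq_len(nrow(pm$matrix))) {
    segs <- lapply(seq_len(nseg), function(s) {
      seg <- pm$matrix[i, ((s - 1) * seg_len + 1):(s * seg_len)]
      c(seg[pre_idx], resample_row(seg), seg[post_idx])
    })
    row <- unlist(segs, use.names = FALSE)
    nrm <- sqrt(sum(row^2))
    out_rows[[i]] <- if (pm$normalized && nrm > 0) row / nrm else row
  }
  M <- do.call(rbind, out_rows)
  rownames(M) <- pm$unit_ids
  tb_new <- c(tb[pre_idx] + (from_delay - to_delay), tb_new_seg, tb[post_idx])
  structure(list(matrix = M, unit_ids = pm$unit_ids, time = tb_new,
                 segments = pm$segments, dt_s = pm$dt_s,
                 delay_duration_s = to_delay, normalized = pm$normalized,
                 filter_log = pm$filter_log),
            class = "psth_matrix")
}
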