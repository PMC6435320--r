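#' Peri-event histogram for one trial
#'
#' Firing rate in 100 ms bins from 10 s before cue onset to 12 s after cue
#' offset — 320 bins for a 10 s cue. Bins are half-open `[t0, t1)`.
#'
#' @param unit A `pag_unit`.
#' @param trial One-row trial (or a session and index via `s`,
#'   `trial_index`).
#' @param bin Bin width in seconds.
#' @param pre Seconds before cue onset.
#' @param post Seconds after cue offset.
#' @param session_span If supplied, error when the histogram span exceeds
#'   the recording.
#' @return List: `bin_start` (seconds relative to cue onset), `counts`,
#'   `rate` (spikes/s).
#' @export
trial_psth <- function(unit, trial, bin = 0.1, pre = 10, post = 12,
                       session_span = NULL) {
  t0 <- trial$cue_on - pre
  t1 <- trial$cue_off + post
  if (!is.null(session_span) && (t0 < 0 || t1 > session_span)) {
    abort(sprintf("PSTH span [%.2f, %.2f] exceeds the recording span.",
                  t0, t1))
  }
  n_bins <- as.integer(round((t1 - t0) / bin))
  edges <- t0 + bin * (0:n_bins)
  counts <- vapply(seq_len(n_bins), function(k) {
    sum(unit$spike_times >= edges[k] & unit$spike_times < edges[k + 1])
  }, numeric(1))
  list(bin_start = edges[-length(edges)] - trial$cue_on,
       counts = counts, rate = counts / bin)
}

#' Mean differential PSTH per trial type
#'
#' Averages the per-trial histograms of all trials of a type, then
#' subtracts that type's mean 2 s pre-cue baseline rate from every bin, so
#' the trace reads as rate change from baseline.
#'
#' @param unit A `pag_unit`.
#' @param trials Trial tibble.
#' @param trial_type Trial type, or a cue name with
#'   `collapse_uncertainty = TRUE`.
#' @param collapse_uncertainty Treat `trial_type` as a cue, pooling the two
#'   uncertainty trial types.
#' @inheritParams trial_psth
#' @return List: `bin_start` (relative to cue onset), `rate` (differential
#'   spikes/s), `baseline_rate`, `n_trials`.
#' @export
differential_mean_psth <- function(unit, trials, trial_type,
                                   collapse_uncertainty = TRUE,
                                   bin = 0.1, pre = 10, post = 12) {
  sel <- if (collapse_uncertainty) {
    cue_of_type(trials$trial_type) == trial_type
  } else trials$trial_type == trial_type
  if (!any(sel)) abort(sprintf("No trials of type '%s'.", trial_type))
  idx <- which(sel)
  first <- trial_psth(unit, trials[idx[1], ], bin = bin, pre = pre,
                      post = post)
  mats <- vapply(idx, function(i) {
    trial_psth(unit, trials[i, ], bin = bin, pre = pre, post = post)$rate
  }, numeric(length(first$rate)))
  mean_rate <- rowMeans(mats)
  bin_start <- first$bin_start
  base_bins <- bin_start >= -2 & bin_start < 0
  baseline <- mean(mean_rate[base_bins])
  list(bin_start = bin_start, rate = mean_rate - baseline,
       baseline_rate = baseline, n_trials = length(idx))
}

#' Whole-epoch Z normalization of a unit's differential PSTHs
#'
#' Stacks the per-cue differential traces and applies a single Z transform
#' over all trial types x bins (population SD, divide by N), so mean
#' normalized firing is exactly 0 and SD exactly 1 across the pooled
#' domain. Normalizing over the whole epoch (not just baseline) means
#' phasic excitation pulls the mean up, which is why baseline-period Z sits
#' below zero in responsive units.
#'
#' @param unit A `pag_unit`.
#' @param trials Trial tibble.
#' @param cues Which cue traces to include (default the three cues,
#'   uncertainty collapsed).
#' @inheritParams trial_psth
#' @return List: `z` (cue x bin matrix), `bin_start`, `mean`, `sd` (the
#'   pooled statistics applied).
#' @export
zscore_unit <- function(unit, trials, cues = CUES, bin = 0.1, pre = 10,
                        post = 12) {
  traces <- lapply(cues, function(cu) {
    differential_mean_psth(unit, trials, cu, collapse_uncertainty = TRUE,
                           bin = bin, pre = pre, post = post)
  })
  m <- do.call(rbind, lapply(traces, `[[`, "rate"))
  rownames(m) <- cues
  mu <- mean(m)
  sdev <- pop_sd(as.numeric(m))
  if (sdev == 0) {
    abort(sprintf("Unit %s: zero pooled SD; cannot Z-normalize (unit excluded).",
                  unit$unit_id))
  }
  list(z = (m - mu) / sdev, bin_start = traces[[1]]$bin_start,
       mean = mu, sd = sdev)
}

#' Per-interval trial-wise Z firing
#'
#' For one analysis window (e.g. the first 1 s cue interval, or a 500 ms
#' post-cue window), computes each trial's differential rate — rate in the
#' window minus that trial's own 2 s pre-cue baseline — and Z-transforms
#' across the session's trials (population SD). Each interval is
#' normalized independently, maximizing the spread of firing within the
#' interval; this is the response variable of the trial-by-trial
#' regressions.
#'
#' @param unit A `pag_unit`.
#' @param trials Trial tibble.
#' @param window Length-2 window in seconds relative to cue onset.
#' @return Numeric vector, one Z value per trial (in trial-table order),
#'   with attributes `mean` and `sd` (pre-transform statistics).
#' @export
interval_trial_z <- function(unit, trials, window) {
  diffs <- vapply(seq_len(nrow(trials)), function(i) {
    on <- trials$cue_on[i]
    poke_rate(unit$spike_times, on + window) -
      poke_rate(unit$spike_times, c(on - 2, on))
  }, numeric(1))
  sdev <- pop_sd(diffs)
  if (sdev == 0) {
    abort(sprintf(
      "Unit %s: identical firing on all trials in window [%.2f, %.2f); cannot Z-transform (unit excluded for this interval).",
      unit$unit_id, window[1], window[2]))
  }
  structure((diffs - mean(diffs)) / sdev, mean = mean(diffs), sd = sdev)
}

#' Smooth a histogram while conserving total mass
#'
#' Centered moving average in which each source bin's mass is spread over
#' the window and the kernel is renormalized at the edges, so the sum over
#' bins is preserved exactly. Width 1 is the identity.
#'
#' @param rate Numeric vector of bin values.
#' @param width Odd window width in bins (default 5).
#' @return Smoothed vector of the same length and sum.
#' @export
smooth_psth <- function(rate, width = 5) {
  if (width < 1 || width %% 2 == 0) abort("`width` must be odd and >= 1.")
  if (width == 1) return(rate)
  n <- length(rate)
  h <- (width - 1L) / 2L
  out <- numeric(n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - h)
    hi <- min(n, j + h)
    out[lo:hi] <- out[lo:hi] + rate[j] / (hi - lo + 1L)
  }
  out
}
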