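#' Describe the fear-discrimination session design
#'
#' A design holds the trial composition and event timing of one recording
#' day: three auditory cues predicting foot shock with probability 1.00
#' (danger), 0.375 (uncertainty) and 0.00 (safety); 10 s cues; a 0.5 s shock
#' delivered 2 s after cue offset on danger and uncertainty-shock trials;
#' and 32 trials (6 danger, 6 uncertainty-shock, 10 uncertainty-omission,
#' 10 safety) separated by cue-free intervals with a 3.5 min mean.
#'
#' The uncertainty shock probability must equal the realized proportion
#' `uncertainty_shock / (uncertainty_shock + uncertainty_omission)` whenever
#' uncertainty trials are present, so the programmed contingency and the
#' delivered contingency agree.
#'
#' @param cue_duration Cue length in seconds.
#' @param trace_to_shock Gap between cue offset and shock onset, seconds.
#' @param shock_duration Shock length in seconds.
#' @param trial_counts Named integer vector with entries `danger`,
#'   `uncertainty_shock`, `uncertainty_omission`, `safety`.
#' @param mean_iti Mean inter-trial interval in seconds (cue-free gap from
#'   the end of one trial's shock window to the next cue onset).
#' @param min_iti Minimum inter-trial interval in seconds.
#' @param shock_probabilities Named vector of cue-wise shock probabilities.
#' @return A `pag_design` list.
#' @export
session_design <- function(cue_duration = 10,
                           trace_to_shock = 2,
                           shock_duration = 0.5,
                           trial_counts = c(danger = 6L,
                                            uncertainty_shock = 6L,
                                            uncertainty_omission = 10L,
                                            safety = 10L),
                           mean_iti = 210,
                           min_iti = 60,
                           shock_probabilities = c(danger = 1.00,
                                                   uncertainty = 0.375,
                                                   safety = 0.00)) {
  if (any(c(cue_duration, trace_to_shock, shock_duration) <= 0)) {
    abort("All durations must be > 0.")
  }
  if (!all(TRIAL_TYPES %in% names(trial_counts))) {
    abort("`trial_counts` must name all four trial types.")
  }
  trial_counts <- vapply(trial_counts[TRIAL_TYPES], as.integer, integer(1))
  if (any(trial_counts < 0)) abort("Trial counts must be >= 0.")
  if (!all(CUES %in% names(shock_probabilities))) {
    abort("`shock_probabilities` must name danger, uncertainty and safety.")
  }
  p <- shock_probabilities[CUES]
  if (any(p < 0 | p > 1)) abort("Shock probabilities must lie in [0, 1].")
  n_unc <- trial_counts[["uncertainty_shock"]] +
    trial_counts[["uncertainty_omission"]]
  if (n_unc > 0) {
    realized <- trial_counts[["uncertainty_shock"]] / n_unc
    if (abs(realized - p[["uncertainty"]]) > 1e-9) {
      abort(sprintf(
        "Realized uncertainty shock proportion %.4f != programmed %.4f.",
        realized, p[["uncertainty"]]))
    }
  }
  if (min_iti <= 0 || mean_iti < min_iti) {
    abort("Need 0 < min_iti <= mean_iti.")
  }
  structure(
    list(cue_duration = cue_duration,
         trace_to_shock = trace_to_shock,
         shock_duration = shock_duration,
         trial_counts = trial_counts,
         mean_iti = mean_iti,
         min_iti = min_iti,
         shock_probabilities = p),
    class = "pag_design")
}

#' Cue-wise shock probability lookup
#'
#' @param design A `pag_design`.
#' @param trial_type Character vector of trial types.
#' @return Numeric vector of programmed shock probabilities for the cue each
#'   trial type belongs to.
#' @export
trial_probability <- function(design, trial_type) {
  unname(design$shock_probabilities[cue_of_type(trial_type)])
}

#' Assemble a recording session
#'
#' Bundles one day's trial schedule, nose-poke record and single units.
#' Component invariants are checked with [validate_session()]; construction
#' fails on any violation.
#'
#' @param design A `pag_design`.
#' @param trials Tibble with columns `index`, `trial_type`, `cue_on`,
#'   `cue_off`, `shock_on` (NA when no shock is delivered). Seconds from
#'   session start.
#' @param pokes Numeric vector of nose-poke timestamps, seconds from
#'   session start, nondecreasing.
#' @param units List of `pag_unit` records (see [unit_record()]).
#' @param session_span Total session length in seconds.
#' @param session_id,subject_id Identifier strings.
#' @return A `pag_session`.
#' @export
session <- function(design, trials, pokes = numeric(), units = list(),
                    session_span, session_id = "session1",
                    subject_id = "subject1") {
  s <- structure(
    list(design = design,
         trials = as_tibble(trials),
         pokes = as.numeric(pokes),
         units = units,
         session_span = session_span,
         session_id = session_id,
         subject_id = subject_id),
    class = "pag_session")
  problems <- validate_session(s)
  if (length(problems) > 0) {
    abort(paste0("Invalid session:\n", paste("-", problems, collapse = "\n")))
  }
  s
}

#' Create a single-unit record
#'
#' @param unit_id Identifier string.
#' @param spike_times Numeric vector of spike timestamps in seconds from
#'   session start, nondecreasing.
#' @param waveform Named list with `half_duration` (ms), `amplitude_ratio`
#'   (dimensionless, in \[-1, 1\]) and `baseline_rate` (spikes/s), as
#'   produced by [waveform_features()] or supplied directly.
#' @param session_id,subject_id Identifier strings.
#' @return A `pag_unit` list.
#' @export
unit_record <- function(unit_id, spike_times, waveform = NULL,
                        session_id = "session1", subject_id = "subject1") {
  structure(
    list(unit_id = as.character(unit_id),
         spike_times = as.numeric(spike_times),
         waveform = waveform,
         session_id = session_id,
         subject_id = subject_id),
    class = "pag_unit")
}

#' Validate a session against its invariants
#'
#' Reports (rather than raises) every violated invariant: trial/design count
#' mismatches, cue durations differing from the design, shocks present on
#' trial types that never receive them (or absent where required), shock
#' timing off the programmed trace interval, overlapping or out-of-order
#' trials, unsorted or out-of-span pokes and spikes.
#'
#' @param s A `pag_session` (checked structurally, not by class, so partially
#'   built objects can be screened).
#' @return Character vector of human-readable violations; empty when valid.
#' @export
validate_session <- function(s) {
  problems <- character()
  d <- s$design
  tr <- s$trials
  need <- c("index", "trial_type", "cue_on", "cue_off", "shock_on")
  if (!all(need %in% names(tr))) {
    return(paste0("trials missing column(s): ",
                  paste(setdiff(need, names(tr)), collapse = ", ")))
  }
  for (ty in TRIAL_TYPES) {
    n <- sum(tr$trial_type == ty)
    if (n != d$trial_counts[[ty]]) {
      problems <- c(problems, sprintf(
        "trial count for %s is %d, design says %d", ty, n,
        d$trial_counts[[ty]]))
    }
  }
  bad_dur <- which(abs(tr$cue_off - tr$cue_on - d$cue_duration) > 1e-9)
  for (i in bad_dur) {
    problems <- c(problems, sprintf(
      "trial %d: cue duration %.6f != design %.6f", tr$index[i],
      tr$cue_off[i] - tr$cue_on[i], d$cue_duration))
  }
  shock_types <- c("danger", "uncertainty_shock")
  for (i in seq_len(nrow(tr))) {
    has_shock <- is.finite(tr$shock_on[i])
    should <- tr$trial_type[i] %in% shock_types
    if (has_shock && !should) {
      problems <- c(problems, sprintf(
        "trial %d: shock_on present on a %s trial", tr$index[i],
        tr$trial_type[i]))
    }
    if (!has_shock && should) {
      problems <- c(problems, sprintf(
        "trial %d: shock_on missing on a %s trial", tr$index[i],
        tr$trial_type[i]))
    }
    if (has_shock && should &&
        abs(tr$shock_on[i] - (tr$cue_off[i] + d$trace_to_shock)) > 1e-9) {
      problems <- c(problems, sprintf(
        "trial %d: shock_on %.6f != cue_off + trace (%.6f)", tr$index[i],
        tr$shock_on[i], tr$cue_off[i] + d$trace_to_shock))
    }
  }
  if (nrow(tr) >= 2) {
    o <- order(tr$cue_on)
    ends <- tr$cue_off[o] + ifelse(
      tr$trial_type[o] %in% shock_types,
      d$trace_to_shock + d$shock_duration, 0)
    overl <- which(tr$cue_on[o][-1] < ends[-length(ends)])
    for (i in overl) {
      problems <- c(problems, sprintf(
        "trials %d and %d overlap", tr$index[o][i], tr$index[o][i + 1]))
    }
    if (is.unsorted(tr$cue_on)) {
      problems <- c(problems, "trials are not time-ordered")
    }
  }
  if (length(s$pokes) > 0) {
    if (is.unsorted(s$pokes)) problems <- c(problems, "pokes are not sorted")
    if (any(s$pokes < 0 | s$pokes > s$session_span)) {
      problems <- c(problems, "pokes outside session span")
    }
  }
  for (u in s$units) {
    if (length(u$spike_times) > 0) {
      if (is.unsorted(u$spike_times)) {
        problems <- c(problems, sprintf("unit %s: spikes not sorted", u$unit_id))
      }
      if (any(u$spike_times < 0 | u$spike_times > s$session_span)) {
        problems <- c(problems, sprintf(
          "unit %s: spikes outside session span", u$unit_id))
      }
    }
    w <- u$waveform
    if (!is.null(w)) {
      if (!is.null(w$half_duration) && w$half_duration <= 0) {
        problems <- c(problems, sprintf(
          "unit %s: half_duration must be > 0", u$unit_id))
      }
      if (!is.null(w$amplitude_ratio) &&
          (w$amplitude_ratio < -1 || w$amplitude_ratio > 1)) {
        problems <- c(problems, sprintf(
          "unit %s: amplitude_ratio outside [-1, 1]", u$unit_id))
      }
    }
  }
  if (nrow(tr) > 0 && max(tr$cue_off) + 1e-9 > s$session_span) {
    problems <- c(problems, "session span ends before the last cue offset")
  }
  problems
}

#' @export
print.pag_session <- function(x, ...) {
  cat(sprintf(
    "<pag_session %s/%s: %d trials, %d pokes, %d units, %.1f s>\n",
    x$subject_id, x$session_id, nrow(x$trials), length(x$pokes),
    length(x$units), x$session_span))
  invisible(x)
}
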