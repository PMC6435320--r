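#' Behavioral generator settings
#'
#' Targets for the nose-poke simulator. Default target suppression ratios
#' are the cue-wise means observed in well-discriminating animals: strong
#' to danger (0.80), intermediate to uncertainty (0.53), near zero to
#' safety (0.03) — the nonlinear fear profile the regression analyses rely
#' on. Per-trial Gaussian noise on the target ratio injects within-cue
#' behavioral variance so the fear and probability regressors are not
#' collinear.
#'
#' @param baseline_poke_rate Poke rate outside cues, pokes/s.
#' @param target_suppression Named vector of target ratios per cue, each in
#'   \[-1, 1\].
#' @param trial_noise_sd SD of per-trial noise added to the target ratio
#'   (ratio units; noisy targets are clipped back to \[-1, 1\]).
#' @param within_cue_profile Optional length-10 multiplier on the
#'   cue-period poke rate, one value per 1 s cue interval (1 = flat).
#' @return A `pag_behavior_spec` list.
#' @export
behavior_spec <- function(baseline_poke_rate = 1.0,
                          target_suppression = c(danger = 0.80,
                                                 uncertainty = 0.53,
                                                 safety = 0.03),
                          trial_noise_sd = 0.15,
                          within_cue_profile = NULL) {
  if (baseline_poke_rate <= 0) abort("`baseline_poke_rate` must be > 0.")
  if (!all(CUES %in% names(target_suppression))) {
    abort("`target_suppression` must name danger, uncertainty and safety.")
  }
  rho <- target_suppression[CUES]
  if (any(rho < -1 | rho > 1)) {
    abort("Target suppression ratios must lie in [-1, 1].")
  }
  structure(list(baseline_poke_rate = baseline_poke_rate,
                 target_suppression = rho,
                 trial_noise_sd = trial_noise_sd,
                 within_cue_profile = within_cue_profile),
            class = "pag_behavior_spec")
}

#' Single-unit generator settings
#'
#' Spike trains are inhomogeneous Poisson with intensity
#' `baseline + modulation(t)`:
#' * `onset` — an exponentially decaying transient from cue onset,
#'   `gain * exp(-t / onset_decay_tau)`;
#' * `ramping` — a linear ramp from `ramp_start` after cue onset to the
#'   expected shock time (cue offset + trace), sustained until shock and
#'   optionally truncated back to baseline afterwards;
#' * `hfr` — the ramping shape on a high-baseline unit;
#' * `nonresponsive` — no modulation.
#'
#' The per-trial gain is `probability_gain * p(cue) + fear_gain * fear`,
#' where `p(cue)` is the programmed shock probability and `fear` is that
#' trial's measured total suppression ratio (supplied at simulation time),
#' so units can encode threat probability, fear output, or a mixture.
#'
#' @param profile One of `"onset"`, `"ramping"`, `"hfr"`, `"nonresponsive"`.
#' @param baseline_rate Baseline intensity, spikes/s.
#' @param probability_gain Spikes/s per unit shock probability.
#' @param fear_gain Spikes/s per unit suppression ratio.
#' @param onset_decay_tau Onset transient time constant, seconds.
#' @param ramp_start Ramp start relative to cue onset, seconds; must lie in
#'   `[0, cue_duration)`.
#' @param truncate_after_shock Drop back to baseline at (expected) shock
#'   onset? Applies to ramping/hfr profiles.
#' @param blank_shock_window Zero all spikes inside the 0.5 s shock window,
#'   mimicking exclusion of electrically contaminated data.
#' @return A `pag_unit_spec` list.
#' @export
unit_spec <- function(profile = c("onset", "ramping", "hfr", "nonresponsive"),
                      baseline_rate = NULL,
                      probability_gain = 15,
                      fear_gain = 0,
                      onset_decay_tau = 1,
                      ramp_start = 2,
                      truncate_after_shock = TRUE,
                      blank_shock_window = FALSE) {
  profile <- match.arg(profile)
  if (is.null(baseline_rate)) {
    baseline_rate <- switch(profile, hfr = 15, 4)
  }
  if (baseline_rate < 0) abort("`baseline_rate` must be >= 0.")
  if (onset_decay_tau <= 0) abort("`onset_decay_tau` must be > 0.")
  if (ramp_start < 0) abort("`ramp_start` must be >= 0.")
  structure(list(profile = profile,
                 baseline_rate = baseline_rate,
                 probability_gain = probability_gain,
                 fear_gain = fear_gain,
                 onset_decay_tau = onset_decay_tau,
                 ramp_start = ramp_start,
                 truncate_after_shock = truncate_after_shock,
                 blank_shock_window = blank_shock_window),
            class = "pag_unit_spec")
}

#' Draw a randomized trial sequence
#'
#' Trial types are shuffled uniformly; inter-trial intervals (the cue-free
#' gap from the end of one trial's shock window to the next cue onset) are
#' drawn as `min_iti + Exponential(mean_iti - min_iti)`, which has the
#' design's stated mean. A lead-in gap of the same distribution (at least
#' 12.5 s) precedes the first cue so pre-cue baselines and the 10 s
#' pre-onset histogram window exist; a trailing 12.5 s closes the session
#' so the 12 s post-offset window fits.
#'
#' @param design A `pag_design`.
#' @param seed Optional RNG seed.
#' @return Tibble of trials (`index`, `trial_type`, `cue_on`, `cue_off`,
#'   `shock_on`) with attribute `session_span`.
#' @export
make_trial_sequence <- function(design, seed = NULL) {
  with_seed(seed, {
    types <- rep(TRIAL_TYPES, times = design$trial_counts[TRIAL_TYPES])
    types <- sample(types)
    n <- length(types)
    draw_iti <- function(k) {
      design$min_iti + if (design$mean_iti > design$min_iti) {
        rexp(k, rate = 1 / (design$mean_iti - design$min_iti))
      } else rep(0, k)
    }
    itis <- draw_iti(n)
    itis[1] <- max(itis[1], 12.5)  # lead-in: room for the 10 s pre-cue window
    block <- design$cue_duration + design$trace_to_shock + design$shock_duration
    cue_on <- numeric(n)
    t0 <- 0
    for (i in seq_len(n)) {
      cue_on[i] <- t0 + itis[i]
      t0 <- cue_on[i] + block
    }
    cue_off <- cue_on + design$cue_duration
    shock_on <- ifelse(types %in% c("danger", "uncertainty_shock"),
                       cue_off + design$trace_to_shock, NA_real_)
    out <- tibble(index = seq_len(n), trial_type = types,
                  cue_on = cue_on, cue_off = cue_off, shock_on = shock_on)
    attr(out, "session_span") <- t0 + 12.5
    out
  })
}

# Poke rate implied by a target suppression ratio rho at baseline rate b:
# inverting rho = (b - c)/(b + c) gives c = b (1 - rho)/(1 + rho).
rate_from_ratio <- function(baseline, rho) {
  if (any(rho < -1 | rho > 1)) abort("Suppression ratio outside [-1, 1].")
  ifelse(rho >= 1, 0, baseline * (1 - rho) / (1 + rho))
}

#' Simulate a nose-poke record
#'
#' Homogeneous Poisson pokes at the baseline rate outside cues; during each
#' cue, Poisson at the rate implied by that trial's (noise-perturbed)
#' target suppression ratio, optionally shaped within the cue by the
#' spec's interval profile.
#'
#' @param trials Trial tibble from [make_trial_sequence()].
#' @param spec A `pag_behavior_spec`.
#' @param session_span Session length in seconds (defaults to the trials'
#'   `session_span` attribute).
#' @param seed Optional RNG seed.
#' @return Sorted numeric vector of poke times with attribute
#'   `trial_target_ratio` (the realized per-trial targets).
#' @export
simulate_pokes <- function(trials, spec, session_span = NULL, seed = NULL) {
  if (is.null(session_span)) session_span <- attr(trials, "session_span")
  with_seed(seed, {
    b <- spec$baseline_poke_rate
    cue <- cue_of_type(trials$trial_type)
    rho <- spec$target_suppression[cue] +
      rnorm(nrow(trials), 0, spec$trial_noise_sd)
    rho <- pmin(1, pmax(-1, rho))

    # piecewise-constant intensity: baseline everywhere, replaced in cues
    pokes <- numeric(0)
    prev_end <- 0
    for (i in seq_len(nrow(trials))) {
      pokes <- c(pokes, seg_poisson(prev_end, trials$cue_on[i], b))
      cue_len <- trials$cue_off[i] - trials$cue_on[i]
      rate <- rate_from_ratio(b, rho[i])
      prof <- spec$within_cue_profile
      if (is.null(prof)) {
        pokes <- c(pokes, seg_poisson(trials$cue_on[i], trials$cue_off[i], rate))
      } else {
        edges <- seq(0, cue_len, length.out = length(prof) + 1)
        for (k in seq_along(prof)) {
          pokes <- c(pokes, seg_poisson(trials$cue_on[i] + edges[k],
                                        trials$cue_on[i] + edges[k + 1],
                                        max(0, rate * prof[k])))
        }
      }
      prev_end <- trials$cue_off[i]
    }
    pokes <- c(pokes, seg_poisson(prev_end, session_span, b))
    out <- sort(pokes)
    attr(out, "trial_target_ratio") <- rho
    out
  })
}

seg_poisson <- function(t0, t1, rate) {
  if (t1 <= t0 || rate <= 0) return(numeric(0))
  n <- rpois(1, rate * (t1 - t0))
  sort(runif(n, t0, t1))
}

#' Simulate one unit's spike train
#'
#' Inhomogeneous Poisson spikes over the whole session by thinning: a
#' homogeneous candidate train at the intensity ceiling is kept with
#' probability `lambda(t) / lambda_max`, which is exact for bounded
#' intensities.
#'
#' @param trials Trial tibble.
#' @param spec A `pag_unit_spec`.
#' @param design A `pag_design` (for trace/shock timing).
#' @param trial_fear Optional per-trial fear values (e.g. measured total
#'   suppression ratios) driving the `fear_gain` term; required when
#'   `fear_gain != 0`.
#' @param session_span Session length (defaults to the trials' attribute).
#' @param unit_id Identifier for the returned record.
#' @param seed Optional RNG seed.
#' @return A `pag_unit` whose waveform features are drawn to match its
#'   class (narrow/symmetric for high-rate units, broader otherwise) and
#'   whose `baseline_rate` feature is the spec's true baseline.
#' @export
simulate_unit <- function(trials, spec, design, trial_fear = NULL,
                          session_span = NULL, unit_id = "unit1",
                          seed = NULL) {
  if (is.null(session_span)) session_span <- attr(trials, "session_span")
  if (spec$fear_gain != 0 && is.null(trial_fear)) {
    abort("`trial_fear` must be supplied when fear_gain != 0.")
  }
  if (is.null(trial_fear)) trial_fear <- rep(0, nrow(trials))
  with_seed(seed, {
    p <- design$shock_probabilities[cue_of_type(trials$trial_type)]
    gain <- spec$probability_gain * p + spec$fear_gain * trial_fear
    lam_max <- spec$baseline_rate + max(0, max(gain))
    spikes <- if (lam_max > 0) {
      cand <- seg_poisson(0, session_span, lam_max)
      lam <- unit_intensity(cand, trials, spec, design, gain)
      cand[runif(length(cand)) < lam / lam_max]
    } else numeric(0)
    if (spec$blank_shock_window) {
      for (i in which(is.finite(trials$shock_on))) {
        drop <- spikes >= trials$shock_on[i] &
          spikes < trials$shock_on[i] + design$shock_duration
        spikes <- spikes[!drop]
      }
    }
    wf <- list(
      half_duration = max(0.05, rnorm(1,
        mean = if (spec$profile == "hfr") 0.15 else 0.30, sd = 0.04)),
      amplitude_ratio = min(1, max(-1, rnorm(1, 0.2, 0.15))),
      baseline_rate = spec$baseline_rate)
    unit_record(unit_id, sort(spikes), waveform = wf)
  })
}

# Intensity lambda(t) at arbitrary times, vectorized; negative intensities
# are impossible by construction (gains clipped at 0 in the shape term).
unit_intensity <- function(times, trials, spec, design, gain) {
  lam <- rep(spec$baseline_rate, length(times))
  if (spec$profile == "nonresponsive" || length(times) == 0) return(lam)
  shape_end <- trials$cue_off + design$trace_to_shock  # expected shock time
  for (i in seq_len(nrow(trials))) {
    if (gain[i] <= 0) next
    rel <- times - trials$cue_on[i]
    if (spec$profile == "onset") {
      in_win <- rel >= 0 & rel < design$cue_duration
      lam[in_win] <- lam[in_win] +
        gain[i] * exp(-rel[in_win] / spec$onset_decay_tau)
    } else {  # ramping / hfr
      end_rel <- shape_end[i] - trials$cue_on[i]
      stop_rel <- if (spec$truncate_after_shock) end_rel else
        end_rel + design$shock_duration + 2.5
      in_win <- rel >= spec$ramp_start & rel < stop_rel
      frac <- pmin(1, (rel[in_win] - spec$ramp_start) /
                     (end_rel - spec$ramp_start))
      lam[in_win] <- lam[in_win] + gain[i] * pmax(0, frac)
    }
  }
  lam
}

#' Cohort composition for simulation
#'
#' @param n_onset,n_ramping,n_hfr,n_nonresponsive Units per response class
#'   per session.
#' @param n_sessions Number of sessions to generate.
#' @param lfr_baseline_range,hfr_baseline_range Uniform ranges (spikes/s)
#'   from which low- and high-firing baseline rates are drawn; the defaults
#'   give the bimodal baseline-rate mixture that drives the two-cluster
#'   structure.
#' @param hfr_fraction_nonresponsive Fraction of nonresponsive units drawn
#'   from the high-firing range (most recorded units are low-firing).
#' @return A `pag_cohort_spec` list.
#' @export
cohort_spec <- function(n_onset = 6, n_ramping = 6, n_hfr = 3,
                        n_nonresponsive = 15, n_sessions = 1,
                        lfr_baseline_range = c(2, 5),
                        hfr_baseline_range = c(13, 18),
                        hfr_fraction_nonresponsive = 0.2) {
  counts <- c(n_onset, n_ramping, n_hfr, n_nonresponsive, n_sessions)
  if (any(counts < 0)) abort("Counts must be >= 0.")
  structure(list(n_onset = n_onset, n_ramping = n_ramping, n_hfr = n_hfr,
                 n_nonresponsive = n_nonresponsive, n_sessions = n_sessions,
                 lfr_baseline_range = lfr_baseline_range,
                 hfr_baseline_range = hfr_baseline_range,
                 hfr_fraction_nonresponsive = hfr_fraction_nonresponsive),
            class = "pag_cohort_spec")
}

#' Simulate a cohort of sessions with ground-truth labels
#'
#' Generates `n_sessions` full sessions (trial sequence, nose pokes, spike
#' trains for every unit) and returns the planted response class of every
#' unit alongside, for recovery testing.
#'
#' @param cohort A `pag_cohort_spec`.
#' @param design A `pag_design`.
#' @param bspec A `pag_behavior_spec`.
#' @param fear_gain_ramping Fear gain applied to ramping units (default 0:
#'   pure probability coding).
#' @param seed RNG seed (one stream drives the whole cohort, so a fixed
#'   seed reproduces it exactly).
#' @return List with `sessions` (list of `pag_session`) and `labels`
#'   (tibble: `session_id`, `unit_id`, `true_label`, `baseline_rate`,
#'   `true_cluster`).
#' @export
simulate_cohort <- function(cohort, design = session_design(),
                            bspec = behavior_spec(),
                            fear_gain_ramping = 0, seed = NULL) {
  with_seed(seed, {
    sessions <- vector("list", cohort$n_sessions)
    labels <- vector("list", cohort$n_sessions)
    for (si in seq_len(cohort$n_sessions)) {
      sid <- sprintf("session%03d", si)
      trials <- make_trial_sequence(design)
      span <- attr(trials, "session_span")
      pokes <- simulate_pokes(trials, bspec, session_span = span)
      sup <- NULL  # measured fear, computed lazily only if a unit needs it

      profs <- c(rep("onset", cohort$n_onset),
                 rep("ramping", cohort$n_ramping),
                 rep("hfr", cohort$n_hfr),
                 rep("nonresponsive", cohort$n_nonresponsive))
      n_units <- length(profs)
      units <- vector("list", n_units)
      lab <- vector("list", n_units)
      for (ui in seq_len(n_units)) {
        prof <- profs[ui]
        uid <- sprintf("%s_u%03d", sid, ui)
        is_hfr <- prof == "hfr" ||
          (prof == "nonresponsive" &&
             runif(1) < cohort$hfr_fraction_nonresponsive)
        base <- runif(1,
          (if (is_hfr) cohort$hfr_baseline_range else
             cohort$lfr_baseline_range)[1],
          (if (is_hfr) cohort$hfr_baseline_range else
             cohort$lfr_baseline_range)[2])
        fg <- if (prof == "ramping") fear_gain_ramping else 0
        tf <- NULL
        if (fg != 0) {
          if (is.null(sup)) {
            tmp <- session(design, trials, pokes, list(), span,
                           session_id = sid)
            sup <- session_suppression(tmp)
          }
          tf <- sup$total_ratio
          tf[is.na(tf)] <- 0
        }
        spc <- unit_spec(profile = prof, baseline_rate = base, fear_gain = fg)
        units[[ui]] <- simulate_unit(trials, spc, design, trial_fear = tf,
                                     session_span = span, unit_id = uid)
        units[[ui]]$session_id <- sid
        lab[[ui]] <- tibble(session_id = sid, unit_id = uid,
                            true_label = if (prof == "hfr")
                              "hfr_cue_responsive" else prof,
                            baseline_rate = base,
                            true_cluster = if (is_hfr) "HFR" else "LFR")
      }
      sessions[[si]] <- session(design, trials, pokes, units, span,
                                session_id = sid)
      labels[[si]] <- dplyr::bind_rows(lab)
    }
    list(sessions = sessions, labels = dplyr::bind_rows(labels))
  })
}
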