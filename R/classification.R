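#' Waveform features from a sampled mean waveform
#'
#' Half-duration is the time from peak depolarization to the trough of
#' after-hyperpolarization, divided by two. The amplitude ratio is
#' `(n - p) / (n + p)` with `n` the maximal depolarization magnitude and
#' `p` the initial hyperpolarization magnitude.
#'
#' @param samples Numeric vector of waveform voltage samples (mV),
#'   depolarization positive.
#' @param sample_times Sample times in milliseconds (defaults to sample
#'   index at 0.025 ms steps, a 40 kHz sampling rate).
#' @return List with `half_duration` (ms) and `amplitude_ratio`.
#' @export
waveform_features <- function(samples,
                              sample_times = (seq_along(samples) - 1) * 0.025) {
  if (length(samples) < 3 || diff(range(samples)) == 0) {
    abort("Waveform is flat or too short; no peak/trough identifiable.")
  }
  i_peak <- which.max(samples)
  after <- samples[i_peak:length(samples)]
  i_trough <- i_peak + which.min(after) - 1L
  if (i_trough <= i_peak) {
    abort("No after-hyperpolarization trough beyond the peak.")
  }
  n <- abs(samples[i_peak])
  pre <- samples[seq_len(i_peak - 1L)]
  p <- if (length(pre) > 0 && any(pre < 0)) abs(min(pre)) else 0
  list(half_duration = (sample_times[i_trough] - sample_times[i_peak]) / 2,
       amplitude_ratio = if (n + p == 0) NA_real_ else (n - p) / (n + p))
}

#' Mean baseline firing rate across trials
#'
#' Rate in the window `baseline_window` seconds before cue onset, averaged
#' over all trials.
#'
#' @param unit A `pag_unit`.
#' @param trials Trial tibble.
#' @param baseline_window Window length in seconds before cue onset
#'   (default 2).
#' @return Spikes/s.
#' @export
baseline_firing_rate <- function(unit, trials, baseline_window = 2) {
  if (nrow(trials) < 1) abort("Need at least one trial.")
  rates <- vapply(seq_len(nrow(trials)), function(i) {
    poke_rate(unit$spike_times,
              c(trials$cue_on[i] - baseline_window, trials$cue_on[i]))
  }, numeric(1))
  mean(rates)
}

#' Feature table for a set of units
#'
#' @param s A `pag_session`.
#' @param baseline_window Baseline window (s) for the rate feature.
#' @return Tibble: `unit_id`, `baseline_rate` (measured over pre-cue
#'   windows), `half_duration`, `amplitude_ratio` (from the stored waveform
#'   summaries).
#' @export
unit_features <- function(s, baseline_window = 2) {
  purrr::map_dfr(s$units, function(u) {
    tibble(unit_id = u$unit_id,
           baseline_rate = baseline_firing_rate(u, s$trials, baseline_window),
           half_duration = u$waveform$half_duration %||% NA_real_,
           amplitude_ratio = u$waveform$amplitude_ratio %||% NA_real_)
  })
}

#' Partition units into low- and high-firing clusters
#'
#' K-means (k = 2) on standardized baseline rate, waveform half-duration
#' and amplitude ratio. The cluster with the lower mean raw baseline rate
#' is labelled LFR, the other HFR — in recorded vlPAG cohorts these proxy
#' putative glutamatergic and GABAergic classes. A one-way ANOVA per
#' feature across the two clusters reports which features actually drive
#' membership (empirically, baseline rate dominates).
#'
#' @param features Tibble from [unit_features()] (columns `unit_id`,
#'   `baseline_rate`, `half_duration`, `amplitude_ratio`).
#' @param seed RNG seed for the k-means starts.
#' @param nstart Random starts for [stats::kmeans()].
#' @param standardize Scale features to unit variance first? Default
#'   `FALSE`: features enter in their native units (spikes/s, ms,
#'   dimensionless), so the firing-rate axis — the only bimodal feature —
#'   dominates the Euclidean distance, and well-separated rate mixtures
#'   are recovered exactly. With standardization, pure-noise waveform
#'   dimensions get equal weight and can flip borderline units. Either
#'   way, the per-feature ANOVA reports which features actually differ
#'   across the clusters.
#' @return List with `assignments` (tibble: `unit_id`, `cluster`),
#'   `centroids` (cluster x feature, raw units) and `feature_tests`
#'   (tibble: `feature`, `F`, `df1`, `df2`, `p`).
#' @export
cluster_units <- function(features, seed = 1, nstart = 25,
                          standardize = FALSE) {
  feats <- c("baseline_rate", "half_duration", "amplitude_ratio")
  x <- as.data.frame(features[feats])
  if (nrow(x) < 2 || length(unique(features$baseline_rate)) < 2) {
    abort("Need >= 2 units with distinct baseline rates.")
  }
  xs <- if (standardize) {
    z <- scale(x)
    z[, apply(x, 2, function(v) sd(v) == 0)] <- 0  # constant: no weight
    z
  } else as.matrix(x)
  cl_id <- if (nrow(xs) == 2) {
    1:2  # k = 2 on two units: each its own cluster
  } else {
    with_seed(seed, kmeans(xs, centers = 2, nstart = nstart))$cluster
  }
  mean_rate <- tapply(features$baseline_rate, cl_id, mean)
  lfr_id <- as.integer(names(which.min(mean_rate)))
  cluster <- ifelse(cl_id == lfr_id, "LFR", "HFR")
  centroids <- as_tibble(
    stats::aggregate(x, by = list(cluster = cluster), FUN = mean))
  feature_tests <- purrr::map_dfr(feats, function(f) {
    if (sd(x[[f]]) == 0) {
      return(tibble(feature = f, F = NA_real_, df1 = NA_real_,
                    df2 = NA_real_, p = NA_real_))
    }
    a <- anova(lm(x[[f]] ~ cluster))
    tibble(feature = f, F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
           p = a$`Pr(>F)`[1])
  })
  list(assignments = tibble(unit_id = features$unit_id, cluster = cluster),
       centroids = centroids,
       feature_tests = feature_tests)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen one unit for excitatory cue responsiveness
#'
#' Paired two-tailed t-test of per-trial raw firing rate, 2 s pre-cue
#' baseline vs. a 1 s cue interval (first or last), run separately for
#' each of the three cues (uncertainty trial types collapsed) at the
#' Bonferroni-corrected threshold 0.05/3 (p < 0.017). A unit is flagged
#' responsive when any cue shows both p below threshold and a firing
#' increase — the screen targets excitatory responses only.
#'
#' @param unit A `pag_unit`.
#' @param trials Trial tibble.
#' @param interval `"first"` or `"last"` 1 s cue interval.
#' @param cue_duration Cue length (s).
#' @param alpha Corrected per-cue threshold (default 0.05/3).
#' @return List with `tests` (tibble: `cue`, `n`, `mean_baseline`,
#'   `mean_interval`, `t`, `df`, `p`, `increase`) and `responsive` (logical
#'   flag).
#' @export
screen_cue_responsive <- function(unit, trials, interval = c("first", "last"),
                                  cue_duration = 10, alpha = 0.05 / 3) {
  interval <- match.arg(interval)
  off <- if (interval == "first") c(0, 1) else c(cue_duration - 1, cue_duration)
  cue <- cue_of_type(trials$trial_type)
  tests <- purrr::map_dfr(CUES, function(cu) {
    idx <- which(cue == cu)
    if (length(idx) < 2) {
      return(tibble(cue = cu, n = length(idx), mean_baseline = NA_real_,
                    mean_interval = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, increase = NA))
    }
    base <- vapply(idx, function(i) poke_rate(
      unit$spike_times, c(trials$cue_on[i] - 2, trials$cue_on[i])), numeric(1))
    intr <- vapply(idx, function(i) poke_rate(
      unit$spike_times,
      c(trials$cue_on[i] + off[1], trials$cue_on[i] + off[2])), numeric(1))
    if (sd(intr - base) == 0) {
      warn(sprintf("Unit %s, cue %s: zero-variance differences, test undefined.",
                   unit$unit_id, cu))
      return(tibble(cue = cu, n = length(idx), mean_baseline = mean(base),
                    mean_interval = mean(intr), t = NA_real_, df = NA_real_,
                    p = NA_real_, increase = mean(intr) > mean(base)))
    }
    tt <- t.test(intr, base, paired = TRUE)
    tibble(cue = cu, n = length(idx), mean_baseline = mean(base),
           mean_interval = mean(intr), t = unname(tt$statistic),
           df = unname(tt$parameter), p = tt$p.value,
           increase = mean(intr) > mean(base))
  })
  responsive <- any(!is.na(tests$p) & tests$p < alpha & tests$increase)
  list(tests = tests, responsive = isTRUE(responsive))
}

#' Label every unit's response class
#'
#' Precedence: (1) responsive in the first 1 s cue interval — onset;
#' (2) else responsive in the last interval and in the LFR cluster —
#' ramping; (3) else responsive in the last interval and HFR —
#' hfr_cue_responsive; (4) else nonresponsive. Labels partition the
#' population. Onset units are expected (but not forced) to fall in the
#' LFR cluster; the returned table lets that be verified.
#'
#' @param s A `pag_session`.
#' @param clusters Cluster assignment tibble from [cluster_units()].
#' @param alpha Corrected per-cue screening threshold.
#' @return Tibble: `unit_id`, `cluster`, `label`, plus per-cue screening
#'   p values for both intervals (`p_first_danger`, ..., `p_last_safety`).
#' @export
classify_population <- function(s, clusters, alpha = 0.05 / 3) {
  purrr::map_dfr(s$units, function(u) {
    cl <- clusters$cluster[clusters$unit_id == u$unit_id]
    if (length(cl) != 1) abort(sprintf("No cluster for unit %s.", u$unit_id))
    first <- screen_cue_responsive(u, s$trials, "first",
                                   s$design$cue_duration, alpha)
    last <- screen_cue_responsive(u, s$trials, "last",
                                  s$design$cue_duration, alpha)
    label <- if (first$responsive) "onset"
      else if (last$responsive && cl == "LFR") "ramping"
      else if (last$responsive && cl == "HFR") "hfr_cue_responsive"
      else "nonresponsive"
    ps <- c(setNames(first$tests$p, paste0("p_first_", first$tests$cue)),
            setNames(last$tests$p, paste0("p_last_", last$tests$cue)))
    dplyr::bind_cols(tibble(unit_id = u$unit_id, cluster = cl, label = label),
                     as_tibble(as.list(ps)))
  })
}
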