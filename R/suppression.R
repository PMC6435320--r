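#' Event rate in a half-open window
#'
#' @param times Sorted numeric event timestamps (pokes or spikes), seconds.
#' @param window Length-2 numeric `c(t0, t1)`; events in `[t0, t1)` count.
#' @return Events per second.
#' @export
poke_rate <- function(times, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be c(t0, t1) with t1 > t0.")
  }
  sum(times >= window[1] & times < window[2]) / (window[2] - window[1])
}

#' Conditioned suppression ratio
#'
#' `(baseline - cue) / (baseline + cue)` on poke rates: 1 indicates complete
#' suppression of reward seeking (high fear), 0 no suppression (low fear),
#' negative values facilitation. When both rates are zero the ratio is
#' undefined and `NA` is returned — undefined ratios are excluded from
#' averages downstream, never imputed as zero.
#'
#' @param baseline_rate,cue_rate Poke rates, pokes/s, both `>= 0`.
#' @return Ratio in \[-1, 1\], or `NA` for the 0/0 case.
#' @export
suppression_ratio <- function(baseline_rate, cue_rate) {
  if (any(baseline_rate < 0) || any(cue_rate < 0)) {
    abort("Rates must be >= 0.")
  }
  out <- (baseline_rate - cue_rate) / (baseline_rate + cue_rate)
  out[baseline_rate + cue_rate == 0] <- NA_real_
  out
}

#' Suppression measures for one trial
#'
#' Computes the trial's pre-cue baseline poke rate, the total-cue ratio,
#' ten 1 s cue-interval ratios, and optionally ten 500 ms post-cue ratios
#' (four delay, one shock, five post-shock), all against the same pre-cue
#' baseline. Interval ratios give relative fear at fine timescale; the
#' total ratio gives fear over the whole cue.
#'
#' @param s A `pag_session`.
#' @param trial_index 1-based trial index.
#' @param baseline_window Pre-cue baseline length in seconds (default 10).
#'   Must not reach back into the previous trial's shock window unless
#'   `auto_shorten = TRUE`, in which case it is clipped to the available
#'   cue-free gap.
#' @param include_postcue Also compute the ten 500 ms post-cue ratios?
#' @param auto_shorten Clip an overlapping baseline instead of erroring.
#' @return One-row tibble: `index`, `trial_type`, `baseline_rate`,
#'   `total_ratio`, `interval_1` .. `interval_10`, and with
#'   `include_postcue` also `postcue_1` .. `postcue_10`.
#' @export
trial_suppression <- function(s, trial_index, baseline_window = 10,
                              include_postcue = FALSE, auto_shorten = FALSE) {
  tr <- s$trials[s$trials$index == trial_index, ]
  if (nrow(tr) != 1) abort(sprintf("No trial with index %d.", trial_index))
  d <- s$design
  b0 <- tr$cue_on - baseline_window
  prev <- s$trials[s$trials$cue_on < tr$cue_on, ]
  if (nrow(prev) > 0) {
    pe <- max(prev$cue_off + ifelse(is.finite(prev$shock_on),
                                    d$trace_to_shock + d$shock_duration, 0))
    if (b0 < pe) {
      if (!auto_shorten) {
        abort(sprintf(
          "Trial %d: baseline window reaches into the previous trial (starts %.2f s, previous ends %.2f s); shorten it or set auto_shorten = TRUE.",
          trial_index, b0, pe))
      }
      b0 <- pe
    }
  }
  if (b0 < 0) b0 <- 0
  if (tr$cue_on - b0 <= 0) {
    abort(sprintf("Trial %d: no room for a baseline window.", trial_index))
  }
  base <- poke_rate(s$pokes, c(b0, tr$cue_on))
  total <- suppression_ratio(base, poke_rate(s$pokes, c(tr$cue_on, tr$cue_off)))
  n_int <- as.integer(round(d$cue_duration))
  ints <- vapply(seq_len(n_int), function(k) {
    suppression_ratio(base, poke_rate(
      s$pokes, c(tr$cue_on + k - 1, tr$cue_on + k)))
  }, numeric(1))
  out <- tibble(index = tr$index, trial_type = tr$trial_type,
                baseline_rate = base, total_ratio = total)
  out[paste0("interval_", seq_len(n_int))] <- as.list(ints)
  if (include_postcue) {
    pc <- vapply(1:10, function(k) {
      suppression_ratio(base, poke_rate(
        s$pokes, c(tr$cue_off + 0.5 * (k - 1), tr$cue_off + 0.5 * k)))
    }, numeric(1))
    out[paste0("postcue_", 1:10)] <- as.list(pc)
  }
  out
}

#' Suppression measures for all trials of a session
#'
#' @inheritParams trial_suppression
#' @return Tibble with one row per trial (see [trial_suppression()]) plus a
#'   `session_id` column.
#' @export
session_suppression <- function(s, baseline_window = 10,
                                include_postcue = FALSE,
                                auto_shorten = FALSE) {
  rows <- lapply(s$trials$index, trial_suppression, s = s,
                 baseline_window = baseline_window,
                 include_postcue = include_postcue,
                 auto_shorten = auto_shorten)
  dplyr::bind_rows(rows) |>
    dplyr::mutate(session_id = s$session_id, .before = 1)
}

#' Cue-wise discrimination summary across sessions
#'
#' Collapses trials to cues (uncertainty trial types merged), averages
#' ratios within session, then summarizes across sessions: mean and SEM
#' per cue, and paired t-tests for each cue pair, for the total-cue ratio
#' and for each 1 s interval (with the interval tests held to a
#' Bonferroni-corrected threshold, default 0.05/10 = 0.005). Undefined
#' (`NA`) ratios are excluded and counted.
#'
#' @param suppression Tibble of per-trial measures from
#'   [session_suppression()], possibly row-bound over many sessions.
#' @param interval_alpha Per-interval significance threshold after
#'   Bonferroni correction.
#' @return List with `means` (cue x scope summary), `tests` (pairwise
#'   paired t-tests) and `n_undefined` (count of excluded ratios).
#' @export
discrimination_summary <- function(suppression, interval_alpha = 0.005) {
  int_cols <- grep("^interval_", names(suppression), value = TRUE)
  long <- suppression |>
    dplyr::mutate(cue = cue_of_type(.data$trial_type)) |>
    tidyr::pivot_longer(dplyr::all_of(c("total_ratio", int_cols)),
                        names_to = "scope", values_to = "ratio")
  n_undef <- sum(is.na(long$ratio))
  per_session <- long |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$session_id, .data$cue, .data$scope) |>
    dplyr::summarise(ratio = mean(.data$ratio), .groups = "drop")
  if (dplyr::n_distinct(per_session$session_id) < 2) {
    abort("Need >= 2 sessions for SEM and paired tests.")
  }
  means <- per_session |>
    dplyr::group_by(.data$cue, .data$scope) |>
    dplyr::summarise(mean = mean(.data$ratio),
                     sem = sd(.data$ratio) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  pairs <- list(c("danger", "uncertainty"),
                c("uncertainty", "safety"),
                c("danger", "safety"))
  wide <- per_session |>
    tidyr::pivot_wider(names_from = "cue", values_from = "ratio")
  tests <- purrr::map_dfr(unique(wide$scope), function(sc) {
    w <- wide[wide$scope == sc, ]
    purrr::map_dfr(pairs, function(pr) {
      ok <- stats::complete.cases(w[, pr])
      tt <- t.test(w[[pr[1]]][ok], w[[pr[2]]][ok], paired = TRUE)
      alpha <- if (sc == "total_ratio") 0.05 else interval_alpha
      tibble(scope = sc, cue_a = pr[1], cue_b = pr[2],
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, alpha = alpha, significant = tt$p.value < alpha)
    })
  })
  list(means = means, tests = tests, n_undefined = n_undef)
}
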