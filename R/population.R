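#' Sliding-window departure of two population firing traces
#'
#' Slides a 1 s window across the cue in 100 ms steps and, in each window,
#' runs a paired two-tailed t-test across units on mean normalized firing
#' to cue A vs. cue B. The departure time is the start of the first window
#' whose p value falls below threshold — reported both at p < 0.05 and at
#' the Bonferroni-corrected threshold `0.05 / bonferroni_divisor`.
#'
#' @param z_a,z_b Unit x bin matrices of normalized firing for the two
#'   cues, bins starting at cue onset.
#' @param bin Bin width (s).
#' @param window Window length (s).
#' @param step Step between window starts (s).
#' @param span Extent of the sweep (s from cue onset; default covers the
#'   full matrices).
#' @param bonferroni_divisor Divisor for the corrected threshold; `NULL`
#'   (default) uses windows x `n_comparisons`.
#' @param n_comparisons Number of parallel cue comparisons the correction
#'   accounts for (default 2: danger vs. safety and uncertainty vs.
#'   safety).
#' @return List: `windows` (tibble `start`, `t`, `p`, `mean_a`, `mean_b`),
#'   `departure_p05`, `departure_bonferroni` (window start times, `NA` if
#'   never significant), `n_windows`, `bonferroni_divisor`,
#'   `bonferroni_threshold`.
#' @export
sliding_departure <- function(z_a, z_b, bin = 0.1, window = 1, step = 0.1,
                              span = NULL, bonferroni_divisor = NULL,
                              n_comparisons = 2) {
  if (!is.matrix(z_a) || !is.matrix(z_b) || nrow(z_a) < 2 ||
      !all(dim(z_a) == dim(z_b))) {
    abort("`z_a` and `z_b` must be matching unit x bin matrices with >= 2 units.")
  }
  if (is.null(span)) span <- ncol(z_a) * bin
  starts <- seq(0, span - window, by = step)
  wbins <- round(window / bin)
  res <- purrr::map_dfr(starts, function(s0) {
    k0 <- round(s0 / bin) + 1L
    a <- rowMeans(z_a[, k0:(k0 + wbins - 1L), drop = FALSE])
    b <- rowMeans(z_b[, k0:(k0 + wbins - 1L), drop = FALSE])
    if (sd(a - b) == 0) {
      return(tibble(start = s0, t = NA_real_, p = 1,
                    mean_a = mean(a), mean_b = mean(b)))
    }
    tt <- t.test(a, b, paired = TRUE)
    tibble(start = s0, t = unname(tt$statistic), p = tt$p.value,
           mean_a = mean(a), mean_b = mean(b))
  })
  divisor <- as.integer(round(
    bonferroni_divisor %||% (length(starts) * n_comparisons)))
  thr <- 0.05 / divisor
  first_at <- function(alpha) {
    hit <- which(res$p < alpha)
    if (length(hit) == 0) NA_real_ else res$start[hit[1]]
  }
  list(windows = res,
       departure_p05 = first_at(0.05),
       departure_bonferroni = first_at(thr),
       n_windows = length(starts),
       bonferroni_divisor = divisor,
       bonferroni_threshold = thr)
}

#' Rate of firing increase from departure to the last window
#'
#' `(z_last - z_departure) / dt`, where the two values are population mean
#' normalized firing in the departure window and in the last 1 s window of
#' the cue, and `dt` is the time between the window starts.
#'
#' @param z Unit x bin matrix of normalized firing, bins from cue onset.
#' @param departure_time Departure window start (s), e.g. from
#'   [sliding_departure()]. `NA` or a departure at the last window yields a
#'   flagged-undefined result.
#' @param bin Bin width (s).
#' @param window Window length (s).
#' @param cue_duration Cue length (s).
#' @return List: `rate` (Z units/s, `NA` when undefined), `defined`,
#'   `z_departure`, `z_last`.
#' @export
rate_of_increase <- function(z, departure_time, bin = 0.1, window = 1,
                             cue_duration = 10) {
  last_start <- cue_duration - window
  if (is.na(departure_time) || departure_time >= last_start) {
    return(list(rate = NA_real_, defined = FALSE,
                z_departure = NA_real_, z_last = NA_real_))
  }
  win_mean <- function(s0) {
    k0 <- round(s0 / bin) + 1L
    mean(z[, k0:(k0 + round(window / bin) - 1L), drop = FALSE])
  }
  zd <- win_mean(departure_time)
  zl <- win_mean(last_start)
  list(rate = (zl - zd) / (last_start - departure_time), defined = TRUE,
       z_departure = zd, z_last = zl)
}

PATTERNS <- c("d>u>s", "d>s>u", "u>d>s", "u>s>d", "s>d>u", "s>u>d")

#' Categorize a unit's relative cue firing
#'
#' Maps the unit's normalized firing to danger, uncertainty and safety to
#' one of the six strict orderings (e.g. `"d>u>s"`). Exact ties are broken
#' by the fixed priority danger > uncertainty > safety and flagged.
#'
#' @param values Named numeric vector with entries `danger`, `uncertainty`,
#'   `safety` (finite).
#' @return Ordering label with attribute `tie` (logical).
#' @export
categorize_pattern <- function(values) {
  v <- values[CUES]
  if (any(!is.finite(v))) abort("Cue firing values must be finite.")
  tie <- anyDuplicated(v) > 0
  # order() is stable, so input order danger, uncertainty, safety is the
  # tie-break priority
  o <- order(-v)
  label <- paste(c("d", "u", "s")[o], collapse = ">")
  structure(label, tie = tie)
}

#' Shuffle null for firing-pattern counts
#'
#' Counts observed units per ordering, then builds the chance distribution
#' by independently permuting each unit's three cue values and re-counting,
#' repeated `n_shuffles` times. Summaries follow box-plot conventions:
#' median, quartiles and the most extreme non-outliers (within 1.5 IQR of
#' the quartiles). An observed count is flagged as exceeding chance when it
#' lies above the upper non-outlier whisker.
#'
#' @param values Unit x 3 matrix (columns danger, uncertainty, safety) of
#'   normalized interval firing.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Optional RNG seed.
#' @return Tibble per ordering: `pattern`, `observed`, `shuffle_median`,
#'   `shuffle_q25`, `shuffle_q75`, `whisker_lo`, `whisker_hi`,
#'   `exceeds_chance`.
#' @export
shuffle_pattern_null <- function(values, n_shuffles = 1000, seed = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) != 3) {
    abort("`values` must be a unit x 3 matrix.")
  }
  colnames(values) <- CUES
  count_patterns <- function(m) {
    labs <- apply(m, 1, function(r) {
      as.character(categorize_pattern(setNames(r, CUES)))
    })
    table(factor(labs, levels = PATTERNS))
  }
  observed <- count_patterns(values)
  with_seed(seed, {
    shuf <- t(vapply(seq_len(n_shuffles), function(b) {
      m <- t(apply(values, 1, sample))
      as.numeric(count_patterns(m))
    }, numeric(length(PATTERNS))))
  })
  purrr::map_dfr(seq_along(PATTERNS), function(k) {
    x <- shuf[, k]
    obs_k <- as.numeric(observed[[k]])
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    tibble(pattern = PATTERNS[k], observed = obs_k,
           shuffle_median = q[2], shuffle_q25 = q[1], shuffle_q75 = q[3],
           whisker_lo = lo, whisker_hi = hi,
           exceeds_chance = obs_k > hi)
  })
}

#' Correlation and sign-test bias summary for paired firing
#'
#' Pearson R-squared with its t-distributed p value, plus an exact
#' two-tailed binomial sign test on the paired differences (ties excluded).
#' Used to show population-wide biases, e.g. greater firing to danger than
#' uncertainty across units.
#'
#' @param x,y Paired numeric vectors (>= 3 pairs).
#' @return Tibble: `n`, `r`, `r2`, `p_cor`, `n_pos`, `n_neg`, `n_ties`,
#'   `p_sign`. Degenerate variance gives `NA` correlation; all-ties gives
#'   `NA` sign-test p.
#' @export
bias_tests <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need >= 3 paired values.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    r <- NA_real_; p_cor <- NA_real_
  } else {
    ct <- cor.test(x, y)
    r <- unname(ct$estimate); p_cor <- ct$p.value
  }
  d <- x - y
  n_pos <- sum(d > 0); n_neg <- sum(d < 0); n_ties <- sum(d == 0)
  p_sign <- if (n_pos + n_neg == 0) NA_real_ else {
    binom.test(n_pos, n_pos + n_neg, 0.5)$p.value
  }
  tibble(n = length(x), r = r, r2 = r^2, p_cor = p_cor,
         n_pos = n_pos, n_neg = n_neg, n_ties = n_ties, p_sign = p_sign)
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 table of successes/failures, without
#' continuity correction by default.
#'
#' @param a_successes,n1 Successes and total for group A.
#' @param b_successes,n2 Successes and total for group B.
#' @param correct Apply the Yates continuity correction?
#' @return Tibble: `statistic`, `df`, `p`, `prop_a`, `prop_b`.
#' @export
chisq_proportions <- function(a_successes, n1, b_successes, n2,
                              correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) abort("Group sizes must be > 0.")
  tab <- rbind(c(a_successes, n1 - a_successes),
               c(b_successes, n2 - b_successes))
  if (any(tab < 0)) abort("Successes cannot exceed group size.")
  if (any(colSums(tab) == 0)) abort("A margin of the 2x2 table is zero.")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value, prop_a = a_successes / n1, prop_b = b_successes / n2)
}

#' Firing around spontaneous nose-poke cessation
#'
#' Control analysis: finds cue-free poke gaps of at least `gap_threshold`
#' seconds lying fully inside inter-trial intervals, aligns the unit's
#' session-normalized firing to gap onsets, and tests post-onset firing
#' (0 to 2 s) against the pre-gap baseline (-2 to 0 s) with a paired
#' t-test. If cue-evoked firing merely tracked poke cessation, these
#' spontaneous cessations would show the same change.
#'
#' @param unit A `pag_unit`.
#' @param s A `pag_session`.
#' @param gap_threshold Minimum poke-free gap (s), default 5.
#' @param baseline Pre-gap baseline length (s), default 2.
#' @param bin Bin width (s) for the aligned trace.
#' @param post Trace extent after gap onset (s).
#' @return List: `n_gaps`, `gap_onsets`, `aligned` (tibble `time`,
#'   `mean_z`), `test` (tibble `t`, `df`, `p`, or all-`NA` when no gaps or
#'   degenerate). Empty result (0 gaps) is returned, not raised.
#' @export
poke_cessation_control <- function(unit, s, gap_threshold = 5, baseline = 2,
                                   bin = 0.1, post = 5) {
  d <- s$design
  # ITI = outside [cue_on - baseline-pad, shock-window end + 2 s]
  excl_lo <- s$trials$cue_on - (baseline + 0.5)
  excl_hi <- s$trials$cue_off +
    ifelse(is.finite(s$trials$shock_on),
           d$trace_to_shock + d$shock_duration, 0) + 2
  pk <- s$pokes
  gaps <- if (length(pk) >= 2) {
    starts <- pk[-length(pk)]
    lens <- diff(pk)
    keep <- lens >= gap_threshold
    starts[keep]
  } else numeric(0)
  in_iti <- vapply(gaps, function(g0) {
    win <- c(g0 - baseline, g0 + post)
    !any(win[2] > excl_lo & win[1] < excl_hi)
  }, logical(1))
  gaps <- gaps[in_iti]
  gaps <- gaps[gaps - baseline >= 0 & gaps + post <= s$session_span]
  if (length(gaps) == 0) {
    return(list(n_gaps = 0L, gap_onsets = numeric(0), aligned = NULL,
                test = tibble(t = NA_real_, df = NA_real_, p = NA_real_)))
  }
  # session-wide normalization of 100 ms rates for the aligned trace
  edges <- seq(0, s$session_span, by = bin)
  all_rates <- tabulate(findInterval(unit$spike_times, edges,
                                     left.open = FALSE),
                        nbins = length(edges) - 1L) / bin
  mu <- mean(all_rates); sdev <- pop_sd(all_rates)
  if (sdev == 0) sdev <- 1
  rel <- seq(-baseline, post - bin, by = bin)
  traces <- vapply(gaps, function(g0) {
    vapply(rel, function(t0) {
      (poke_rate(unit$spike_times, c(g0 + t0, g0 + t0 + bin)) - mu) / sdev
    }, numeric(1))
  }, numeric(length(rel)))
  pre <- vapply(gaps, function(g0) {
    poke_rate(unit$spike_times, c(g0 - baseline, g0))
  }, numeric(1))
  pst <- vapply(gaps, function(g0) {
    poke_rate(unit$spike_times, c(g0, g0 + 2))
  }, numeric(1))
  test <- if (length(gaps) >= 2 && sd(pst - pre) > 0) {
    tt <- t.test(pst, pre, paired = TRUE)
    tibble(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  } else tibble(t = NA_real_, df = NA_real_, p = NA_real_)
  list(n_gaps = length(gaps), gap_onsets = gaps,
       aligned = tibble(time = rel, mean_z = rowMeans(traces)),
       test = test)
}
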