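# Build unit x bin Z matrices with a step increase planted at a known time.
planted_step <- function(n_units, n_bins = 100, step_bin = NULL, effect = 0,
                         noise = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_units * n_bins, 0, noise), n_units, n_bins)
  if (!is.null(step_bin)) m[, step_bin:n_bins] <- m[, step_bin:n_bins] + effect
  m
}

test_that("identical populations never depart; planted steps are localized", {
  a <- planted_step(20, seed = 61)
  res0 <- sliding_departure(a, a)
  expect_true(is.na(res0$departure_p05))
  expect_true(is.na(res0$departure_bonferroni))

  # a step of 1 Z planted at 3.0 s: the first p<0.05 window can fire early
  # by chance (a ~5% false rate over overlapping null windows), so the
  # uncorrected departure is checked on replicates via its median, while
  # the Bonferroni-corrected departure — whose false rate is negligible —
  # must localize the step within window overlap in every run
  deps <- t(vapply(1:11, function(r) {
    b <- planted_step(20, step_bin = 31, effect = 1, seed = 600 + r)
    a2 <- planted_step(20, seed = 700 + r)
    res_r <- sliding_departure(b, a2)
    c(res_r$departure_p05, res_r$departure_bonferroni)
  }, numeric(2)))
  expect_gte(median(deps[, 1]), 2.1)
  expect_lte(median(deps[, 1]), 3.2)
  expect_true(all(deps[, 2] >= 2.1 & deps[, 2] <= 3.2))
  expect_true(all(deps[, 1] <= deps[, 2]))

  b <- planted_step(20, step_bin = 31, effect = 1, seed = 601)
  a2 <- planted_step(20, seed = 701)
  res <- sliding_departure(b, a2)
  expect_identical(res$n_windows, 91L)
  expect_identical(res$bonferroni_divisor, 182L)  # windows x 2 comparisons
  expect_equal(res$bonferroni_threshold, 0.05 / 182)
  expect_gte(res$departure_bonferroni, res$departure_p05)
  # the divisor is overridable (e.g. a fixed 200)
  res200 <- sliding_departure(b, a2, bonferroni_divisor = 200)
  expect_equal(res200$bonferroni_threshold, 0.05 / 200)
})

test_that("rate of increase matches a linear ramp and flags degenerate cases", {
  n_bins <- 100
  ramp <- matrix(rep(seq(0, 9.9, by = 0.1) * 0.5, each = 4), nrow = 4,
                 byrow = FALSE)  # slope 0.5 Z/s
  roi <- rate_of_increase(ramp, departure_time = 2)
  expect_true(roi$defined)
  expect_equal(roi$rate, 0.5, tolerance = 0.02)
  flat <- matrix(1, 4, n_bins)
  expect_equal(rate_of_increase(flat, 2)$rate, 0)
  expect_false(rate_of_increase(flat, NA)$defined)
  expect_false(rate_of_increase(flat, 9)$defined)  # departure at last window
})

test_that("pattern categorization orders cues with deterministic tie-breaks", {
  expect_equal(as.character(categorize_pattern(
    c(danger = 2, uncertainty = 1, safety = 0))), "d>u>s")
  expect_equal(as.character(categorize_pattern(
    c(danger = 0, uncertainty = 1, safety = 2))), "s>u>d")
  tied <- categorize_pattern(c(danger = 1, uncertainty = 1, safety = 0))
  expect_equal(as.character(tied), "d>u>s")  # danger wins ties
  expect_true(attr(tied, "tie"))
  expect_error(categorize_pattern(c(danger = NA, uncertainty = 1, safety = 0)),
               "finite")
})

test_that("shuffle null is symmetric, reproducible, and flags planted patterns", {
  set.seed(64)
  vals <- matrix(rnorm(30 * 3), 30, 3)
  pc <- shuffle_pattern_null(vals, n_shuffles = 500, seed = 65)
  expect_equal(sum(pc$observed), 30)
  # permutation symmetry: each ordering's shuffle median near n/6 = 5
  expect_true(all(abs(pc$shuffle_median - 5) <= 1))
  expect_true(all(pc$shuffle_q25 <= pc$shuffle_median &
                    pc$shuffle_median <= pc$shuffle_q75))
  pc2 <- shuffle_pattern_null(vals, n_shuffles = 500, seed = 65)
  expect_identical(pc, pc2)
  # a population planted all d>u>s exceeds chance in that cell only
  planted <- matrix(rep(c(3, 2, 1), each = 30), 30, 3)
  pp <- shuffle_pattern_null(planted, n_shuffles = 500, seed = 66)
  expect_true(pp$exceeds_chance[pp$pattern == "d>u>s"])
  expect_false(any(pp$exceeds_chance[pp$pattern != "d>u>s"]))
})

test_that("bias tests match closed forms", {
  x <- seq(1, 29)
  expect_equal(bias_tests(x, x - 1)$r2, 1)
  # 25 of 29 positive differences: exact two-tailed binomial
  y <- x; y[1:25] <- y[1:25] - 1; y[26:29] <- y[26:29] + 1
  bt <- bias_tests(x, y)
  expect_identical(bt$n_pos, 25L)
  p_exact <- 2 * sum(dbinom(25:29, 29, 0.5))
  expect_equal(bt$p_sign, p_exact)
  # all ties: sign test undefined, correlation degenerate handled
  bt2 <- bias_tests(x, x)
  expect_identical(bt2$n_ties, 29L)
  expect_true(is.na(bt2$p_sign))
})

test_that("sign-test p values are valid under an exchangeable null", {
  # the exact test is discrete, so null p values are conservative rather
  # than uniform: P(p <= a) <= a at every level, within Monte Carlo error
  set.seed(67)
  ps <- replicate(300, {
    x <- rnorm(29); y <- rnorm(29)
    bias_tests(x, y)$p_sign
  })
  for (a in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / length(ps)))
  }
})

test_that("chi-square on proportions matches a hand-computed oracle", {
  # independent oracle: Pearson formula from expected counts
  pearson <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  expect_equal(chisq_proportions(5, 10, 5, 10)$statistic, 0)
  t1 <- rbind(c(13, 7), c(4, 16))
  r1 <- chisq_proportions(13, 20, 4, 20)
  expect_equal(r1$statistic, pearson(t1), tolerance = 1e-12)
  t2 <- rbind(c(6, 14), c(1, 19))
  r2 <- chisq_proportions(6, 20, 1, 20)
  expect_equal(r2$statistic, pearson(t2), tolerance = 1e-12)
  expect_error(chisq_proportions(0, 20, 0, 20), "margin")
})

test_that("poke-cessation control finds gaps and controls false positives", {
  d <- quick_design(mean_iti = 40, min_iti = 25)
  tr <- make_trial_sequence(d, seed = 68)
  span <- attr(tr, "session_span")
  # sparse poking yields natural >= 5 s gaps inside ITIs
  bs <- behavior_spec(baseline_poke_rate = 0.15)
  pk <- simulate_pokes(tr, bs, seed = 69)
  s <- session(d, tr, pk, list(), span)
  flat <- simulate_unit(tr, unit_spec("nonresponsive", baseline_rate = 5), d,
                        session_span = span, seed = 70)
  res <- poke_cessation_control(flat, s)
  expect_gt(res$n_gaps, 0)
  expect_identical(nrow(res$aligned), as.integer((2 + 5) / 0.1))
  # continuous poking -> no qualifying gaps, empty result
  dense <- session(d, tr, sort(runif(8000, 0, span)), list(), span)
  res2 <- poke_cessation_control(flat, dense)
  expect_identical(res2$n_gaps, 0L)
  expect_true(is.na(res2$test$p))
  # a unit locked to cessation (silence while pokes stop) is detected
  gaps <- res$gap_onsets
  extra <- unlist(lapply(gaps, function(g) runif(60, g, g + 2)))
  locked <- unit_record("locked", sort(c(flat$spike_times, extra)))
  res3 <- poke_cessation_control(locked, s)
  expect_lt(res3$test$p, 0.05)
})

test_that("flat units show no cessation-locked change beyond chance", {
  d <- quick_design(mean_iti = 40, min_iti = 25)
  n_sig <- 0L; n_def <- 0L
  for (i in 1:20) {
    tr <- make_trial_sequence(d, seed = 7100 + i)
    span <- attr(tr, "session_span")
    pk <- simulate_pokes(tr, behavior_spec(baseline_poke_rate = 0.15),
                         seed = 7200 + i)
    s <- session(d, tr, pk, list(), span)
    u <- simulate_unit(tr, unit_spec("nonresponsive", baseline_rate = 5), d,
                       session_span = span, seed = 7300 + i)
    res <- poke_cessation_control(u, s)
    if (!is.na(res$test$p)) {
      n_def <- n_def + 1L
      if (res$test$p < 0.05) n_sig <- n_sig + 1L
    }
  }
  expect_gt(n_def, 10)
  expect_lte(n_sig / n_def, 0.05 + 3 * sqrt(0.05 * 0.95 / n_def))
})
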