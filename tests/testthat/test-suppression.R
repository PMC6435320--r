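test_that("poke_rate uses half-open windows", {
  expect_equal(poke_rate(seq(0.5, 19.5, by = 2), c(0, 20)), 0.5)
  expect_equal(poke_rate(numeric(0), c(0, 10)), 0)
  expect_equal(poke_rate(c(1, 5), c(0, 5)), 0.2)  # poke at t1 excluded
  expect_error(poke_rate(1:3, c(5, 5)), "t1 > t0")
})

test_that("suppression_ratio matches its closed form and flags 0/0", {
  expect_equal(suppression_ratio(0.5, 0), 1)
  expect_equal(suppression_ratio(0.3, 0.3), 0)
  expect_equal(suppression_ratio(0.3, 0.1), 0.5)
  expect_true(is.na(suppression_ratio(0, 0)))
  expect_error(suppression_ratio(-1, 0.5), ">= 0")
})

test_that("defined ratios are bounded and monotone in cue rate", {
  b <- runif(200, 0.01, 5)
  c_ <- runif(200, 0, 5)
  r <- suppression_ratio(b, c_)
  expect_true(all(r >= -1 & r <= 1))
  # monotone decreasing in cue rate at fixed baseline
  cr <- seq(0, 3, by = 0.1)
  expect_true(all(diff(suppression_ratio(rep(1, length(cr)), cr)) < 0))
})

test_that("trial suppression: zero cue pokes give ratio 1 everywhere", {
  d <- quick_design()
  tr <- make_trial_sequence(d, seed = 31)
  bs <- behavior_spec(target_suppression = c(danger = 1, uncertainty = 1,
                                             safety = 1), trial_noise_sd = 0)
  pk <- simulate_pokes(tr, bs, seed = 32)
  s <- session(d, tr, pk, list(), attr(tr, "session_span"))
  row <- trial_suppression(s, 1)
  expect_equal(row$total_ratio, 1)
  ints <- unlist(row[paste0("interval_", 1:10)])
  expect_true(all(ints == 1 | is.na(ints)))  # NA only if baseline had 0 pokes
})

test_that("constant poking yields near-zero ratios on average", {
  d <- session_design(
    trial_counts = c(danger = 0, uncertainty_shock = 0,
                     uncertainty_omission = 0, safety = 100),
    mean_iti = 12, min_iti = 11)
  bs <- behavior_spec(baseline_poke_rate = 1,
                      target_suppression = c(danger = 0, uncertainty = 0,
                                             safety = 0), trial_noise_sd = 0)
  tr <- make_trial_sequence(d, seed = 33)
  pk <- simulate_pokes(tr, bs, seed = 34)
  s <- session(d, tr, pk, list(), attr(tr, "session_span"))
  sup <- session_suppression(s, auto_shorten = TRUE)
  expect_lt(abs(mean(sup$total_ratio, na.rm = TRUE)), 0.1)
})

test_that("baseline window overlapping the previous shock errors unless shortened", {
  d <- quick_design(mean_iti = 15.5, min_iti = 15)
  tr <- make_trial_sequence(d, seed = 35)
  pk <- simulate_pokes(tr, behavior_spec(), seed = 36)
  s <- session(d, tr, pk, list(), attr(tr, "session_span"))
  # a 20 s baseline reaches back into the previous trial for 15 s ITIs
  shock_prev <- which(
    s$trials$trial_type[-nrow(s$trials)] %in%
      c("danger", "uncertainty_shock")) + 1L
  i <- s$trials$index[shock_prev[1]]
  expect_error(trial_suppression(s, i, baseline_window = 20),
               "baseline window")
  row <- trial_suppression(s, i, baseline_window = 20, auto_shorten = TRUE)
  expect_true(is.finite(row$baseline_rate))
})

test_that("interval ratios inflate relative to total ratios at equal rates", {
  # At low Poisson rates the per-1 s ratio is upward biased while the 10 s
  # ratio is nearly unbiased, so short intervals overstate absolute fear.
  d <- session_design(
    trial_counts = c(danger = 0, uncertainty_shock = 0,
                     uncertainty_omission = 0, safety = 120),
    mean_iti = 12, min_iti = 11)
  bs <- behavior_spec(baseline_poke_rate = 0.4,
                      target_suppression = c(danger = 0, uncertainty = 0,
                                             safety = 0), trial_noise_sd = 0)
  tr <- make_trial_sequence(d, seed = 37)
  pk <- simulate_pokes(tr, bs, seed = 38)
  s <- session(d, tr, pk, list(), attr(tr, "session_span"))
  sup <- session_suppression(s, auto_shorten = TRUE)
  int_mean <- mean(unlist(sup[paste0("interval_", 1:10)]), na.rm = TRUE)
  tot_mean <- mean(sup$total_ratio, na.rm = TRUE)
  expect_gt(int_mean, tot_mean + 0.05)
})

test_that("discrimination summary recovers the target ordering and means", {
  d <- quick_design()
  sup <- purrr::map_dfr(1:30, function(i) {
    tr <- make_trial_sequence(d, seed = 400 + i)
    pk <- simulate_pokes(tr, behavior_spec(), seed = 500 + i)
    s <- session(d, tr, pk, list(), attr(tr, "session_span"),
                 session_id = sprintf("s%02d", i))
    session_suppression(s)
  })
  ds <- discrimination_summary(sup)
  m <- ds$means[ds$means$scope == "total_ratio", ]
  mm <- setNames(m$mean, m$cue)
  expect_lt(abs(mm[["danger"]] - 0.80), 0.05)
  expect_lt(abs(mm[["uncertainty"]] - 0.53), 0.05)
  expect_lt(abs(mm[["safety"]] - 0.03), 0.05)
  expect_true(mm[["danger"]] > mm[["uncertainty"]])
  expect_true(mm[["uncertainty"]] > mm[["safety"]])
  tt <- ds$tests[ds$tests$scope == "total_ratio", ]
  expect_true(all(tt$significant))
})

test_that("identical poke statistics across cues rarely test significant", {
  d <- quick_design(mean_iti = 20, min_iti = 15)
  bs <- behavior_spec(target_suppression = c(danger = 0.3, uncertainty = 0.3,
                                             safety = 0.3))
  n_sig <- 0L; n_tests <- 0L
  for (rep in 1:10) {
    sup <- purrr::map_dfr(1:8, function(i) {
      tr <- make_trial_sequence(d, seed = 1000 * rep + i)
      pk <- simulate_pokes(tr, bs, seed = 2000 * rep + i)
      s <- session(d, tr, pk, list(), attr(tr, "session_span"),
                   session_id = sprintf("s%02d", i))
      session_suppression(s)
    })
    tt <- discrimination_summary(sup)$tests
    tt <- tt[tt$scope == "total_ratio", ]
    n_sig <- n_sig + sum(tt$p < 0.05)
    n_tests <- n_tests + nrow(tt)
  }
  # nominal type-I: expect about 5%; bound well below 1 in 3
  expect_lt(n_sig / n_tests, 0.2)
})
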