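# Independent oracle: solve the normal equations directly.
ols_oracle <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

test_that("the worked example reproduces its printed beta coefficients", {
  w <- load_worked_example()
  fit <- fit_ols(w)
  est <- setNames(fit$estimate, fit$term)
  expect_equal(round(est[["interval_fear"]], 2), 0.24)
  expect_equal(round(est[["total_fear"]], 2), -0.14)
  expect_equal(round(est[["probability"]], 2), 2.19)
  # and matches the normal-equations oracle at full precision
  X <- as.matrix(w[, c("constant", "interval_fear", "total_fear",
                       "probability")])
  expect_equal(unname(est), ols_oracle(X, w$z_firing), tolerance = 1e-9)
})

test_that("OLS equals the normal-equations oracle on random designs", {
  set.seed(81)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    k <- sample(1:3, 1)
    X <- cbind(1, matrix(rnorm(n * k), n, k))
    colnames(X) <- c("constant", c("interval_fear", "total_fear",
                                   "probability")[seq_len(k)])
    y <- rnorm(n)
    rm_ <- tibble::tibble(z_firing = y, constant = 1)
    for (j in 2:ncol(X)) rm_[[colnames(X)[j]]] <- X[, j]
    fit <- fit_ols(rm_, subset = colnames(X)[-1])
    expect_equal(fit$estimate, ols_oracle(X, y), tolerance = 1e-9)
  }
})

test_that("degenerate responses and designs are handled", {
  w <- load_worked_example()
  w0 <- w; w0$z_firing <- rep(0.7, 32)
  fit <- fit_ols(w0)
  expect_equal(fit$estimate[fit$term != "constant"], rep(0, 3),
               tolerance = 1e-12)
  # constant suppression across trials collapses onto the intercept
  wc <- w; wc$interval_fear <- 1; wc$total_fear <- 1
  expect_error(fit_ols(wc), "collinear")
  expect_error(regressor_matrix(w$trial_type, w$z_firing,
                                interval_fear = rep(0.5, 32),
                                total_fear = rep(0.5, 32)),
               "collinear")
})

test_that("regressor matrices are ordered by type with the assigned probability", {
  s <- profiled_session(seed = 82)
  sup <- session_suppression(s)
  rm_ <- build_regressors(s, find_unit(s, "onset"), interval = 1,
                          suppression = sup)
  expect_identical(nrow(rm_), 32L)
  expect_identical(rm_$trial_type,
                   rep(c("danger", "uncertainty_shock",
                         "uncertainty_omission", "safety"),
                       times = c(6, 6, 10, 10)))
  expect_true(all(rm_$constant == 1))
  expect_setequal(unique(rm_$probability), c(1, 0.375, 0))
  rm1 <- build_regressors(s, find_unit(s, "onset"), interval = 1,
                          u_assign = 1, suppression = sup)
  expect_setequal(unique(rm1$probability), c(1, 0))
})

test_that("fitted betas recover planted generative coefficients", {
  # firing = a + bp * probability + bf * fear + noise across many units
  set.seed(83)
  s <- quick_session(seed = 84)
  sup <- session_suppression(s)
  sup <- sup[match(s$trials$index, sup$index), ]
  p_true <- trial_probability(s$design, s$trials$trial_type)
  bp <- 1.5; bf <- 0.8
  est <- t(replicate(60, {
    y <- 0.2 + bp * p_true + bf * sup$total_ratio + rnorm(32, 0, 0.5)
    rm_ <- regressor_matrix(s$trials$trial_type, y,
                            interval_fear = sup$interval_1,
                            total_fear = sup$total_ratio)
    fit <- fit_ols(rm_)
    setNames(fit$estimate, fit$term)[c("probability", "total_fear")]
  }))
  ci <- function(v) 3 * sd(v) / sqrt(length(v))
  expect_lt(abs(mean(est[, "probability"]) - bp), ci(est[, "probability"]))
  expect_lt(abs(mean(est[, "total_fear"]) - bf), ci(est[, "total_fear"]))
})

test_that("shuffling the response destroys beta significance at nominal rate", {
  set.seed(85)
  s <- quick_session(seed = 86)
  sup <- session_suppression(s)
  sup <- sup[match(s$trials$index, sup$index), ]
  p_true <- trial_probability(s$design, s$trials$trial_type)
  n_sig <- 0L; n_tot <- 0L
  for (i in 1:100) {
    y <- sample(0.2 + 1.5 * p_true + rnorm(32, 0, 0.5))  # shuffled
    rm_ <- regressor_matrix(s$trials$trial_type, y,
                            interval_fear = sup$interval_1,
                            total_fear = sup$total_ratio)
    fit <- fit_ols(rm_)
    ps <- fit$p[fit$term != "constant"]
    n_sig <- n_sig + sum(ps < 0.05)
    n_tot <- n_tot + length(ps)
  }
  expect_lt(n_sig / n_tot, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("interval sweep fits all ten intervals and summaries flag signals", {
  s <- profiled_session(seed = 87)
  sup <- session_suppression(s)
  sw <- interval_sweep(s, "onset", suppression = sup)
  expect_setequal(unique(sw$interval), 1:10)
  expect_setequal(unique(sw$term),
                  c("constant", "interval_fear", "total_fear", "probability"))
  sm <- summarize_betas(dplyr::mutate(sw, unit_id = paste0(
    sw$unit_id, "_", rep(1:2, length.out = nrow(sw)))))
  expect_true(all(c("mean", "sem", "p") %in% names(sm)))
})

test_that("tuning curve equals the base fit at 0.375 and peaks truthfully", {
  s <- profiled_session(seed = 88)
  sup <- session_suppression(s)
  rm_ <- build_regressors(s, find_unit(s, "onset"), interval = 1,
                          suppression = sup)
  tw <- tuning_sweep(list(rm_))
  base <- fit_ols(rm_)
  expect_equal(tw$curve$mean_beta[tw$curve$u_assign == 0.375],
               base$estimate[base$term == "probability"], tolerance = 1e-12)
  expect_identical(nrow(tw$curve), 9L)
})

test_that("post-cue regression uses nine intervals without total fear", {
  s <- profiled_session(seed = 89)
  sup <- session_suppression(s, include_postcue = TRUE)
  pc <- postcue_regression(s, "ramping", suppression = sup)
  expect_identical(sort(unique(pc$interval)), c(1:4, 6:10))
  expect_false("total_fear" %in% pc$term)
  expect_setequal(unique(pc$term),
                  c("constant", "interval_fear", "probability"))
})

test_that("beta correlation matrix is symmetric and detects persistence", {
  # perfectly persistent betas: every cross cell has R^2 = 1
  set.seed(90)
  base <- rnorm(12)
  persistent <- matrix(rep(base, 9), 12, 9,
                       dimnames = list(NULL, paste0("i", setdiff(1:10, 5))))
  bc <- beta_correlation_matrix(persistent)
  expect_true(all(abs(bc$cross_cells$r2 - 1) < 1e-9))
  expect_identical(bc$n_significant_05, 20L)
  # i.i.d. betas: about 5% of cells significant at 0.05
  n_sig <- 0L
  for (i in 1:30) {
    m <- matrix(rnorm(12 * 9), 12, 9,
                dimnames = list(NULL, paste0("i", setdiff(1:10, 5))))
    n_sig <- n_sig + beta_correlation_matrix(m)$n_significant_05
  }
  rate <- n_sig / (30 * 20)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / (30 * 20)))
  # symmetry
  expect_equal(bc$p, t(bc$p), tolerance = 1e-12)
})

test_that("pairs regression flags planted coupling and spares noise", {
  set.seed(91)
  ramp <- matrix(rnorm(32 * 10), 32, 10)
  ident <- pairs_regression(ramp, ramp)
  expect_equal(ident$beta, rep(1, 10), tolerance = 1e-12)
  expect_true(all(ident$p < 1e-10))
  expect_false(any(ident$negative_significant))
  # planted anti-correlation (rho = -0.8)
  anti <- -0.8 * ramp + sqrt(1 - 0.8^2) * matrix(rnorm(32 * 10), 32, 10)
  res <- pairs_regression(anti, ramp)
  expect_gt(mean(res$negative_significant), 0.5)
  # independent noise pairs: negative-significant in about 2.5% of intervals
  n_neg <- 0L
  for (i in 1:60) {
    a <- matrix(rnorm(32 * 10), 32, 10)
    b <- matrix(rnorm(32 * 10), 32, 10)
    n_neg <- n_neg + sum(pairs_regression(a, b)$negative_significant)
  }
  rate <- n_neg / (60 * 10)
  expect_lt(rate, 0.025 + 3 * sqrt(0.025 * 0.975 / (60 * 10)))
})
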