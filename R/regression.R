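#' Assemble a trial-by-trial regressor matrix
#'
#' Builds the design for one unit x one interval: 32 rows (for the default
#' session) ordered by trial type as danger, uncertainty shock,
#' uncertainty omission, safety; response `z_firing`; regressors
#' `constant` (all ones), `interval_fear` (that trial's suppression ratio
#' in the specific interval), `total_fear` (that trial's whole-cue
#' suppression ratio) and `probability` (the cue's programmed shock
#' probability, with the uncertainty entry set by `u_assign`).
#'
#' @param trial_type Character vector of trial types, one per trial.
#' @param z_firing Per-trial normalized firing (response).
#' @param interval_fear,total_fear Per-trial fear regressors; `total_fear`
#'   may be omitted when not in `subset`.
#' @param u_assign Probability assigned to the uncertainty cue (default the
#'   programmed 0.375).
#' @param subset Regressors to include (any of `interval_fear`,
#'   `total_fear`, `probability`).
#' @return A `pag_regressors` tibble. Errors on a rank-deficient design,
#'   naming the collinear columns.
#' @export
regressor_matrix <- function(trial_type, z_firing, interval_fear,
                             total_fear = NULL, u_assign = 0.375,
                             subset = c("interval_fear", "total_fear",
                                        "probability")) {
  subset <- match.arg(subset, several.ok = TRUE)
  n <- length(trial_type)
  if (length(z_firing) != n || length(interval_fear) != n ||
      (!is.null(total_fear) && length(total_fear) != n)) {
    abort("All per-trial inputs must have the same length.")
  }
  if ("total_fear" %in% subset && is.null(total_fear)) {
    abort("`total_fear` values required when in `subset`.")
  }
  prob <- c(danger = 1, uncertainty_shock = u_assign,
            uncertainty_omission = u_assign, safety = 0)[trial_type]
  d <- tibble(trial_type = trial_type, z_firing = z_firing, constant = 1,
              interval_fear = interval_fear,
              total_fear = total_fear %||% NA_real_,
              probability = unname(prob))
  d <- d[order(match(d$trial_type, TRIAL_TYPES)), ]
  d$trial <- seq_len(n)
  d <- d[, c("trial", "trial_type", "z_firing", "constant",
             "interval_fear", "total_fear", "probability")]
  X <- as.matrix(d[, c("constant", subset)])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(d, class = c("pag_regressors", class(d)),
            subset = subset, u_assign = u_assign)
}

#' Ordinary least squares fit of a regressor matrix
#'
#' OLS with intercept (the constant column); per-coefficient standard
#' errors from the residual variance and two-tailed p values from the t
#' distribution with n - k degrees of freedom.
#'
#' @param rm A `pag_regressors` tibble.
#' @param subset Regressors to fit (default the matrix's own subset).
#' @return Tibble: `term`, `estimate`, `se`, `statistic`, `p`, with
#'   attributes `n`, `df`, `sigma`.
#' @export
fit_ols <- function(rm, subset = NULL) {
  subset <- subset %||% attr(rm, "subset") %||%
    intersect(c("interval_fear", "total_fear", "probability"), names(rm))
  X <- as.matrix(rm[, c("constant", subset)])
  y <- rm$z_firing
  n <- length(y); k <- ncol(X)
  if (n <= k) abort("Need more trials than coefficients.")
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - k)
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df = n - k, lower.tail = FALSE)
  structure(
    tibble(term = colnames(X), estimate = unname(beta), se = unname(se),
           statistic = unname(tstat), p = unname(p)),
    n = n, df = n - k, sigma = sqrt(sigma2))
}

#' Build the regressor matrix for one unit and one cue interval
#'
#' Combines the per-interval trial-wise Z firing (response) with the
#' session's measured fear regressors for that interval.
#'
#' @param s A `pag_session`.
#' @param unit A `pag_unit` (or a unit id present in the session).
#' @param interval 1-based 1 s cue interval (1..cue_duration).
#' @param u_assign Uncertainty probability assignment.
#' @param subset Regressors to include.
#' @param suppression Optional precomputed [session_suppression()] table
#'   (computed on the fly otherwise).
#' @inheritParams session_suppression
#' @return A `pag_regressors` tibble.
#' @export
build_regressors <- function(s, unit, interval = 1, u_assign = 0.375,
                             subset = c("interval_fear", "total_fear",
                                        "probability"),
                             suppression = NULL, baseline_window = 10,
                             auto_shorten = FALSE) {
  if (is.character(unit)) {
    ids <- vapply(s$units, `[[`, character(1), "unit_id")
    unit <- s$units[[match(unit, ids)]]
  }
  sup <- suppression %||% session_suppression(
    s, baseline_window = baseline_window, auto_shorten = auto_shorten)
  sup <- sup[match(s$trials$index, sup$index), ]
  z <- interval_trial_z(unit, s$trials, c(interval - 1, interval))
  regressor_matrix(
    trial_type = s$trials$trial_type,
    z_firing = as.numeric(z),
    interval_fear = sup[[paste0("interval_", interval)]],
    total_fear = sup$total_ratio,
    u_assign = u_assign, subset = subset)
}

#' Per-interval regression sweep over the cue
#'
#' Fits the trial-by-trial OLS for every 1 s cue interval of one unit.
#' Intervals whose design is degenerate (zero firing variance, collinear
#' fear columns) are skipped with a warning.
#'
#' @inheritParams build_regressors
#' @param intervals Intervals to fit (default all ten).
#' @return Tibble of coefficients with `unit_id` and `interval` columns.
#' @export
interval_sweep <- function(s, unit, intervals = NULL, u_assign = 0.375,
                           subset = c("interval_fear", "total_fear",
                                      "probability"),
                           suppression = NULL, baseline_window = 10,
                           auto_shorten = FALSE) {
  if (is.character(unit)) {
    ids <- vapply(s$units, `[[`, character(1), "unit_id")
    unit <- s$units[[match(unit, ids)]]
  }
  intervals <- intervals %||% seq_len(as.integer(round(s$design$cue_duration)))
  sup <- suppression %||% session_suppression(
    s, baseline_window = baseline_window, auto_shorten = auto_shorten)
  purrr::map_dfr(intervals, function(iv) {
    out <- tryCatch({
      rm_ <- build_regressors(s, unit, interval = iv, u_assign = u_assign,
                              subset = subset, suppression = sup)
      fit <- fit_ols(rm_)
      dplyr::mutate(fit, unit_id = unit$unit_id, interval = iv, .before = 1)
    }, error = function(e) {
      warn(sprintf("Unit %s, interval %d skipped: %s", unit$unit_id, iv,
                   conditionMessage(e)))
      NULL
    })
    out
  })
}

#' Population summary of beta coefficients
#'
#' Mean, SEM and a single-sample t-test against zero per regressor per
#' interval, with a Bonferroni-corrected threshold across the intervals
#' (default 0.05/10 = 0.005).
#'
#' @param betas Coefficient tibble from [interval_sweep()] (or
#'   [postcue_regression()]) row-bound across units.
#' @param alpha Corrected per-test threshold.
#' @return Tibble: `term`, `interval`, `n`, `mean`, `sem`, `t`, `df`, `p`,
#'   `significant`.
#' @export
summarize_betas <- function(betas, alpha = 0.005) {
  betas |>
    dplyr::filter(.data$term != "constant") |>
    dplyr::group_by(.data$term, .data$interval) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$estimate),
      sem = sd(.data$estimate) / sqrt(dplyr::n()),
      t = if (dplyr::n() >= 2 && sd(.data$estimate) > 0) {
        mean(.data$estimate) / (sd(.data$estimate) / sqrt(dplyr::n()))
      } else NA_real_,
      df = dplyr::n() - 1,
      .groups = "drop") |>
    dplyr::mutate(
      p = 2 * pt(abs(.data$t), df = .data$df, lower.tail = FALSE),
      significant = !is.na(.data$p) & .data$p < alpha)
}

#' Threat-probability tuning sweep
#'
#' Refits the trial-by-trial regression nine times, holding danger at 1.00
#' and safety at 0.00 but assigning the uncertainty cue each probability
#' in `grid` (0 to 1 in 0.125 steps). The curve is the mean probability
#' beta across units at each assignment; its peak locates the uncertainty
#' weighting that best captures the population's firing. Pure
#' threat-probability coding peaks at the programmed 0.375; mixing in fear
#' output (where uncertainty sits closer to danger) shifts the peak right.
#'
#' @param matrices List of `pag_regressors`, one per unit (built at any
#'   `u_assign`; the probability column is reassigned per grid point).
#' @param grid Uncertainty assignments to evaluate.
#' @return List: `curve` (tibble `u_assign`, `mean_beta`, `sem_beta`, `n`),
#'   `peak` (grid value maximizing the mean beta).
#' @export
tuning_sweep <- function(matrices, grid = seq(0, 1, by = 0.125)) {
  if (!length(matrices)) abort("Need at least one regressor matrix.")
  curve <- purrr::map_dfr(grid, function(u) {
    betas <- vapply(matrices, function(rm_) {
      rm2 <- rm_
      rm2$probability <- c(danger = 1, uncertainty_shock = u,
                           uncertainty_omission = u,
                           safety = 0)[rm2$trial_type]
      fit <- fit_ols(rm2, subset = attr(rm_, "subset"))
      fit$estimate[fit$term == "probability"]
    }, numeric(1))
    tibble(u_assign = u, mean_beta = mean(betas),
           sem_beta = sd(betas) / sqrt(length(betas)), n = length(betas))
  })
  list(curve = curve, peak = curve$u_assign[which.max(curve$mean_beta)])
}

#' Post-cue trial-by-trial regression
#'
#' Fits the regression in 500 ms intervals over the 5 s following cue
#' offset, excluding the shock interval (2.0-2.5 s after offset): nine
#' intervals, four delay and five post-shock. The total-fear regressor is
#' omitted because it samples only the cue period; interval fear is the
#' suppression ratio in the matching 500 ms window.
#'
#' @inheritParams build_regressors
#' @return Tibble of coefficients with `unit_id` and `interval` (1-10,
#'   without 5) columns.
#' @export
postcue_regression <- function(s, unit, u_assign = 0.375,
                               suppression = NULL, baseline_window = 10,
                               auto_shorten = FALSE) {
  if (is.character(unit)) {
    ids <- vapply(s$units, `[[`, character(1), "unit_id")
    unit <- s$units[[match(unit, ids)]]
  }
  sup <- suppression
  if (is.null(sup) || !"postcue_1" %in% names(sup)) {
    sup <- session_suppression(s, baseline_window = baseline_window,
                               include_postcue = TRUE,
                               auto_shorten = auto_shorten)
  }
  sup <- sup[match(s$trials$index, sup$index), ]
  cd <- s$design$cue_duration
  shock_iv <- 5L  # 2.0-2.5 s after offset
  purrr::map_dfr(setdiff(1:10, shock_iv), function(k) {
    win <- cd + c(0.5 * (k - 1), 0.5 * k)
    out <- tryCatch({
      z <- interval_trial_z(unit, s$trials, win)
      fear <- sup[[paste0("postcue_", k)]]
      fear[is.na(fear)] <- 0  # undefined 0/0 ratio: no measurable change
      rm_ <- regressor_matrix(
        trial_type = s$trials$trial_type, z_firing = as.numeric(z),
        interval_fear = fear, u_assign = u_assign,
        subset = c("interval_fear", "probability"))
      fit <- fit_ols(rm_)
      dplyr::mutate(fit, unit_id = unit$unit_id, interval = k, .before = 1)
    }, error = function(e) {
      warn(sprintf("Unit %s, post-cue interval %d skipped: %s",
                   unit$unit_id, k, conditionMessage(e)))
      NULL
    })
    out
  })
}

#' Between-interval correlation matrix of probability betas
#'
#' For a population's probability beta coefficients over the nine post-cue
#' intervals (four delay: 1-4; five post-shock: 6-10), computes the
#' Pearson R-squared and p value for every interval pair. The twenty
#' delay x post-shock cells measure whether threat-probability signaling
#' present before shock persists after it; cell counts are reported at
#' p < 0.05 and at the Bonferroni threshold 0.05/5 = 0.01.
#'
#' @param beta_mat Unit x interval matrix of probability betas with column
#'   names `i1`..`i4`, `i6`..`i10` (e.g. from reshaping
#'   [postcue_regression()] output).
#' @return List: `r2`, `p` (9x9 matrices), `cross_cells` (tibble of the 20
#'   delay x post-shock pairs), `n_significant_05`, `n_significant_bonf`,
#'   `bonferroni_threshold`.
#' @export
beta_correlation_matrix <- function(beta_mat) {
  beta_mat <- as.matrix(beta_mat)
  if (nrow(beta_mat) < 3) abort("Need >= 3 units.")
  ivs <- colnames(beta_mat) %||% paste0("i", setdiff(1:10, 5))
  k <- ncol(beta_mat)
  r2 <- matrix(NA_real_, k, k, dimnames = list(ivs, ivs))
  pm <- r2
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) { r2[a, b] <- 1; pm[a, b] <- 0; next }
    if (sd(beta_mat[, a]) == 0 || sd(beta_mat[, b]) == 0) next
    ct <- cor.test(beta_mat[, a], beta_mat[, b])
    r2[a, b] <- unname(ct$estimate)^2
    pm[a, b] <- ct$p.value
  }
  delay <- paste0("i", 1:4)
  post <- paste0("i", 6:10)
  cross <- purrr::map_dfr(delay, function(a) {
    purrr::map_dfr(post, function(b) {
      tibble(delay = a, post_shock = b, r2 = r2[a, b], p = pm[a, b])
    })
  })
  thr <- 0.05 / 5
  list(r2 = r2, p = pm, cross_cells = cross,
       n_significant_05 = sum(cross$p < 0.05, na.rm = TRUE),
       n_significant_bonf = sum(cross$p < thr, na.rm = TRUE),
       bonferroni_threshold = thr)
}

#' Onset-ramping pairs regression
#'
#' For two units recorded in the same session, regresses the onset unit's
#' per-trial interval firing on the ramping unit's (simple OLS with
#' intercept), per 1 s cue interval. A significantly negative slope would
#' indicate one population driving down the other; its absence shows the
#' populations are independent.
#'
#' @param onset_z,ramping_z Trials x intervals matrices of per-interval
#'   trial-wise Z firing for the two units (aligned rows).
#' @param alpha Significance threshold for the negative-slope flag.
#' @return Tibble: `interval`, `beta`, `se`, `p`, `negative_significant`.
#'   Intervals with zero predictor variance are skipped.
#' @export
pairs_regression <- function(onset_z, ramping_z, alpha = 0.05) {
  onset_z <- as.matrix(onset_z); ramping_z <- as.matrix(ramping_z)
  if (!all(dim(onset_z) == dim(ramping_z))) {
    abort("Matrices must have matching dimensions (aligned trials).")
  }
  purrr::map_dfr(seq_len(ncol(onset_z)), function(iv) {
    x <- ramping_z[, iv]; y <- onset_z[, iv]
    if (sd(x) == 0) return(NULL)
    sm <- summary(lm(y ~ x))$coefficients
    tibble(interval = iv, beta = sm["x", "Estimate"],
           se = sm["x", "Std. Error"], p = sm["x", "Pr(>|t|)"],
           negative_significant = sm["x", "Estimate"] < 0 &
             sm["x", "Pr(>|t|)"] < alpha)
  })
}
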