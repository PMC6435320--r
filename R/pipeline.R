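#' Pipeline configuration
#'
#' Collects every tunable the end-to-end run uses; validated up front so a
#' bad parameter fails before any stage runs.
#'
#' @param design A `pag_design`.
#' @param cohort A `pag_cohort_spec`.
#' @param behavior A `pag_behavior_spec`.
#' @param seed Master RNG seed for the whole run.
#' @param baseline_window Behavioral baseline length (s).
#' @param screen_alpha Corrected cue-responsiveness threshold.
#' @param interval_alpha Corrected per-interval threshold for population
#'   beta tests.
#' @param u_assign Uncertainty probability for the base regressions.
#' @param tuning_grid Uncertainty assignments for the tuning sweep.
#' @param n_shuffles Shuffle count for the pattern null.
#' @param fear_gain_ramping Fear gain planted in ramping units.
#' @return A `pag_config` list with a content hash attribute.
#' @export
pipeline_config <- function(design = session_design(),
                            cohort = cohort_spec(),
                            behavior = behavior_spec(),
                            seed = 1,
                            baseline_window = 10,
                            screen_alpha = 0.05 / 3,
                            interval_alpha = 0.005,
                            u_assign = 0.375,
                            tuning_grid = seq(0, 1, by = 0.125),
                            n_shuffles = 1000,
                            fear_gain_ramping = 0) {
  stopifnot(inherits(design, "pag_design"),
            inherits(cohort, "pag_cohort_spec"),
            inherits(behavior, "pag_behavior_spec"))
  if (baseline_window <= 0) abort("`baseline_window` must be > 0.")
  if (!all(tuning_grid >= 0 & tuning_grid <= 1)) {
    abort("`tuning_grid` values must lie in [0, 1].")
  }
  cfg <- list(design = design, cohort = cohort, behavior = behavior,
              seed = seed, baseline_window = baseline_window,
              screen_alpha = screen_alpha, interval_alpha = interval_alpha,
              u_assign = u_assign, tuning_grid = tuning_grid,
              n_shuffles = n_shuffles,
              fear_gain_ramping = fear_gain_ramping)
  structure(cfg, class = "pag_config", hash = rlang::hash(cfg))
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' simulate -> behavior -> classify -> normalize -> population -> regress.
#' Deterministic given the config seed. Each stage's tables are returned;
#' with `out` set they are also written as CSV alongside the serialized
#' config and its hash. A stage that cannot run for the generated cohort
#' (e.g. too few units of a class) is recorded in `notes` rather than
#' aborting the rest.
#'
#' @param config A `pag_config`.
#' @param out Optional output directory for CSV tables.
#' @return Named list of stage outputs: `sessions`, `labels`,
#'   `suppression`, `discrimination`, `features`, `clusters`, `unit_labels`,
#'   `patterns`, `departure`, `betas`, `beta_summary`, `tuning`,
#'   `postcue_betas`, `beta_correlation`, `notes`, `config_hash`.
#' @export
run_pipeline <- function(config, out = NULL) {
  notes <- character()
  note <- function(msg) notes <<- c(notes, msg)

  sim <- simulate_cohort(config$cohort, config$design, config$behavior,
                         fear_gain_ramping = config$fear_gain_ramping,
                         seed = config$seed)
  sessions <- sim$sessions

  sup <- purrr::map_dfr(sessions, session_suppression,
                        baseline_window = config$baseline_window,
                        include_postcue = TRUE)
  discrimination <- if (length(sessions) >= 2) {
    discrimination_summary(sup, interval_alpha = config$interval_alpha)
  } else {
    note("discrimination summary skipped: needs >= 2 sessions")
    NULL
  }

  features <- purrr::map_dfr(sessions, unit_features)
  clusters <- cluster_units(features, seed = config$seed)
  unit_labels <- purrr::map_dfr(sessions, classify_population,
                                clusters = clusters$assignments,
                                alpha = config$screen_alpha)
  by_label <- split(unit_labels$unit_id, unit_labels$label)

  session_of <- function(uid) {
    for (s in sessions) {
      if (uid %in% vapply(s$units, `[[`, character(1), "unit_id")) return(s)
    }
    NULL
  }
  unit_of <- function(s, uid) {
    s$units[[match(uid, vapply(s$units, `[[`, character(1), "unit_id"))]]
  }

  # per-unit mean interval Z per cue, for patterns and departure
  cue_interval_z <- function(uid, interval) {
    s <- session_of(uid)
    z <- interval_trial_z(unit_of(s, uid), s$trials,
                          c(interval - 1, interval))
    tapply(as.numeric(z), cue_of_type(s$trials$trial_type), mean)[CUES]
  }

  patterns <- NULL
  pattern_pop <- function(ids, interval, pop) {
    vals <- t(vapply(ids, cue_interval_z, numeric(3), interval = interval))
    colnames(vals) <- CUES
    shuffle_pattern_null(vals, n_shuffles = config$n_shuffles,
                         seed = config$seed) |>
      dplyr::mutate(population = pop, .before = 1)
  }
  last_iv <- as.integer(round(config$design$cue_duration))
  if (length(by_label$onset %||% character()) >= 1) {
    patterns <- dplyr::bind_rows(
      patterns, pattern_pop(by_label$onset, 1L, "onset"))
  } else note("pattern analysis skipped for onset: no units")
  if (length(by_label$ramping %||% character()) >= 1) {
    patterns <- dplyr::bind_rows(
      patterns, pattern_pop(by_label$ramping, last_iv, "ramping"))
  } else note("pattern analysis skipped for ramping: no units")

  departure <- NULL
  ramp_ids <- by_label$ramping %||% character()
  if (length(ramp_ids) >= 2) {
    zmats <- lapply(ramp_ids, function(uid) {
      s <- session_of(uid)
      zs <- zscore_unit(unit_of(s, uid), s$trials)
      cue_bins <- zs$bin_start >= 0 & zs$bin_start < config$design$cue_duration
      zs$z[, cue_bins, drop = FALSE]
    })
    cue_mat <- function(cu) do.call(rbind, lapply(zmats, function(m) m[cu, ]))
    departure <- purrr::map_dfr(c("danger", "uncertainty"), function(cu) {
      dep <- sliding_departure(cue_mat(cu), cue_mat("safety"))
      roi <- rate_of_increase(cue_mat(cu), dep$departure_p05,
                              cue_duration = config$design$cue_duration)
      tibble(comparison = paste0(cu, "_vs_safety"),
             departure_p05 = dep$departure_p05,
             departure_bonferroni = dep$departure_bonferroni,
             n_windows = dep$n_windows,
             bonferroni_divisor = dep$bonferroni_divisor,
             rate_of_increase = roi$rate)
    })
  } else note("departure analysis skipped: < 2 ramping units")

  sup_by_session <- split(sup, sup$session_id)
  unit_matrices <- function(ids, interval) {
    purrr::compact(lapply(ids, function(uid) {
      s <- session_of(uid)
      tryCatch(
        build_regressors(s, unit_of(s, uid), interval = interval,
                         u_assign = config$u_assign,
                         suppression = sup_by_session[[s$session_id]]),
        error = function(e) {
          note(sprintf("unit %s excluded at interval %d: %s", uid, interval,
                       conditionMessage(e)))
          NULL
        })
    }))
  }

  betas <- NULL; beta_summary <- NULL; tuning <- NULL
  onset_ids <- by_label$onset %||% character()
  if (length(onset_ids) >= 2) {
    betas <- purrr::map_dfr(onset_ids, function(uid) {
      s <- session_of(uid)
      interval_sweep(s, unit_of(s, uid), u_assign = config$u_assign,
                     suppression = sup_by_session[[s$session_id]]) |>
        dplyr::mutate(population = "onset")
    })
    beta_summary <- summarize_betas(betas, alpha = config$interval_alpha)
    tw <- tuning_sweep(unit_matrices(onset_ids, 1L), config$tuning_grid)
    tuning <- dplyr::mutate(tw$curve, population = "onset",
                            peak = tw$peak, interval = 1L)
  } else note("cue regression skipped: < 2 onset units")
  if (length(ramp_ids) >= 2) {
    tw <- tuning_sweep(unit_matrices(ramp_ids, last_iv), config$tuning_grid)
    tuning <- dplyr::bind_rows(
      tuning, dplyr::mutate(tw$curve, population = "ramping",
                            peak = tw$peak, interval = last_iv))
  }

  postcue_betas <- NULL; beta_correlation <- NULL
  if (length(ramp_ids) >= 3) {
    postcue_betas <- purrr::map_dfr(ramp_ids, function(uid) {
      s <- session_of(uid)
      postcue_regression(s, unit_of(s, uid), u_assign = config$u_assign,
                         suppression = sup_by_session[[s$session_id]])
    })
    pb <- postcue_betas |>
      dplyr::filter(.data$term == "probability") |>
      dplyr::select(dplyr::all_of(c("unit_id", "interval", "estimate"))) |>
      tidyr::pivot_wider(names_from = "interval", values_from = "estimate",
                         names_prefix = "i")
    beta_correlation <- beta_correlation_matrix(
      as.matrix(pb[, paste0("i", setdiff(1:10, 5))]))
  } else note("post-cue regression skipped: < 3 ramping units")

  results <- list(sessions = sessions, labels = sim$labels,
                  suppression = sup, discrimination = discrimination,
                  features = features, clusters = clusters,
                  unit_labels = unit_labels, patterns = patterns,
                  departure = departure, betas = betas,
                  beta_summary = beta_summary, tuning = tuning,
                  postcue_betas = postcue_betas,
                  beta_correlation = beta_correlation,
                  notes = notes, config_hash = attr(config, "hash"))
  if (!is.null(out)) write_pipeline_outputs(results, config, out)
  results
}

write_pipeline_outputs <- function(results, config, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  emit <- function(x, name) {
    if (is.null(x)) return()
    write.csv(x, file.path(out, paste0(name, ".csv")), row.names = FALSE)
  }
  emit(results$suppression, "suppression")
  if (!is.null(results$discrimination)) {
    emit(results$discrimination$means, "discrimination_means")
    emit(results$discrimination$tests, "discrimination_tests")
  }
  emit(results$features, "features")
  emit(results$clusters$assignments, "clusters")
  emit(results$unit_labels, "labels")
  emit(results$patterns, "patterns")
  emit(results$departure, "departure")
  emit(results$betas, "betas")
  emit(results$beta_summary, "beta_summary")
  emit(results$tuning, "tuning")
  emit(results$postcue_betas, "postcue_betas")
  if (!is.null(results$beta_correlation)) {
    emit(results$beta_correlation$cross_cells, "beta_corr")
  }
  provenance <- list(config_hash = attr(config, "hash"),
                     seed = config$seed,
                     r_version = as.character(getRversion()),
                     package_version = as.character(
                       utils::packageVersion("pagfear")),
                     notes = results$notes)
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Export summary figures from pipeline results
#'
#' Writes figure files (PDF) mirroring the core summary panels:
#' suppression by cue, population beta by interval, and the threat-tuning
#' curve (the generating uncertainty probability marked). Missing stages
#' are skipped with a warning.
#'
#' @param results Output of [run_pipeline()].
#' @param out Output directory.
#' @param u_true Generating uncertainty probability to mark on the tuning
#'   panel.
#' @return Character vector of files written, invisibly.
#' @export
export_report <- function(results, out, u_true = 0.375) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  save_fig <- function(p, name) {
    f <- file.path(out, paste0(name, ".pdf"))
    ggplot2::ggsave(f, p, width = 5, height = 4)
    written <<- c(written, f)
  }
  sup <- results$suppression
  if (!is.null(sup)) {
    d <- sup |>
      dplyr::mutate(cue = cue_of_type(.data$trial_type)) |>
      dplyr::group_by(.data$session_id, .data$cue) |>
      dplyr::summarise(ratio = mean(.data$total_ratio, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::group_by(.data$cue) |>
      dplyr::summarise(mean = mean(.data$ratio),
                       sem = sd(.data$ratio) / sqrt(dplyr::n()),
                       .groups = "drop")
    p <- ggplot2::ggplot(d, ggplot2::aes(
        x = factor(.data$cue, levels = CUES), y = .data$mean)) +
      ggplot2::geom_col(fill = "grey40") +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
        width = 0.2) +
      ggplot2::labs(x = NULL, y = "Suppression ratio (whole cue)") +
      ggplot2::theme_classic()
    save_fig(p, "suppression_by_cue")
  } else warn("suppression figure skipped: no data")
  if (!is.null(results$beta_summary)) {
    p <- ggplot2::ggplot(results$beta_summary, ggplot2::aes(
        x = .data$interval, y = .data$mean, colour = .data$term)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem)) +
      ggplot2::labs(x = "Cue interval (s)", y = "Beta coefficient",
                    colour = "Regressor") +
      ggplot2::theme_classic()
    save_fig(p, "beta_by_interval")
  } else warn("beta-by-interval figure skipped: no regression stage")
  if (!is.null(results$tuning)) {
    p <- ggplot2::ggplot(results$tuning, ggplot2::aes(
        x = .data$u_assign, y = .data$mean_beta,
        colour = .data$population)) +
      ggplot2::geom_vline(xintercept = u_true, linetype = 2,
                          colour = "grey60") +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Uncertainty probability assignment",
                    y = "Mean probability beta", colour = NULL) +
      ggplot2::theme_classic()
    save_fig(p, "tuning_curve")
  } else warn("tuning figure skipped: no tuning stage")
  invisible(written)
}
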