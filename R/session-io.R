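# Full-precision numeric serialization: %.17g round-trips IEEE doubles.
fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

num_or_na <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[!nzchar(as.character(x)) | is.na(x)] <- NA_real_
  out
}

#' Save a session bundle to disk
#'
#' Writes the documented plain-text schema: `manifest.json` (design,
#' identifiers, span), `trials.csv`, `pokes.csv`, and per unit
#' `units/<unit_id>.csv` plus `units/<unit_id>.meta.json`. Timestamps are
#' serialized at full double precision so [load_session()] inverts exactly.
#'
#' @param s A `pag_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_session <- function(s, path) {
  problems <- validate_session(s)
  if (length(problems) > 0) {
    abort(paste0("Refusing to save an invalid session:\n",
                 paste("-", problems, collapse = "\n")))
  }
  dir.create(file.path(path, "units"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("Cannot create directory '%s'.", path))
  d <- s$design
  manifest <- list(
    session_id = s$session_id,
    subject_id = s$subject_id,
    session_span = s$session_span,
    unit_ids = vapply(s$units, function(u) u$unit_id, character(1)),
    design = list(
      cue_duration = d$cue_duration,
      trace_to_shock = d$trace_to_shock,
      shock_duration = d$shock_duration,
      trial_counts = as.list(d$trial_counts),
      mean_iti = d$mean_iti,
      min_iti = d$min_iti,
      shock_probabilities = as.list(d$shock_probabilities)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  tr <- data.frame(
    index = s$trials$index,
    trial_type = s$trials$trial_type,
    cue_on = fmt_num(s$trials$cue_on),
    cue_off = fmt_num(s$trials$cue_off),
    shock_on = fmt_num(s$trials$shock_on))
  write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(time = fmt_num(s$pokes)), file.path(path, "pokes.csv"),
            row.names = FALSE, quote = FALSE)
  for (u in s$units) {
    write.csv(data.frame(time = fmt_num(u$spike_times)),
              file.path(path, "units", paste0(u$unit_id, ".csv")),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(unit_id = u$unit_id, session_id = u$session_id,
           subject_id = u$subject_id, waveform = u$waveform),
      file.path(path, "units", paste0(u$unit_id, ".meta.json")),
      auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Load a session bundle from disk
#'
#' Reads the schema written by [save_session()] and re-validates every
#' invariant; a violation raises an error naming the offending field.
#'
#' @param path Directory containing `manifest.json`.
#' @return A validated `pag_session`.
#' @export
load_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    abort(sprintf("No session manifest at '%s'.", mf_path))
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  d <- mf$design
  design <- session_design(
    cue_duration = d$cue_duration,
    trace_to_shock = d$trace_to_shock,
    shock_duration = d$shock_duration,
    trial_counts = unlist(d$trial_counts),
    mean_iti = d$mean_iti,
    min_iti = d$min_iti,
    shock_probabilities = unlist(d$shock_probabilities))
  tr_raw <- read.csv(file.path(path, "trials.csv"),
                     colClasses = "character")
  trials <- tibble(
    index = as.integer(tr_raw$index),
    trial_type = tr_raw$trial_type,
    cue_on = num_or_na(tr_raw$cue_on),
    cue_off = num_or_na(tr_raw$cue_off),
    shock_on = num_or_na(tr_raw$shock_on))
  bad_type <- which(!trials$trial_type %in% TRIAL_TYPES)
  if (length(bad_type) > 0) {
    abort(sprintf("trials.csv line %d: unknown trial_type '%s'.",
                  bad_type[1] + 1L, trials$trial_type[bad_type[1]]))
  }
  pk_path <- file.path(path, "pokes.csv")
  pokes <- if (file.exists(pk_path)) {
    pk <- read.csv(pk_path, colClasses = "character")
    num_or_na(pk$time)
  } else numeric()
  pokes <- pokes[!is.na(pokes)]
  units <- lapply(mf$unit_ids, function(uid) {
    sp_path <- file.path(path, "units", paste0(uid, ".csv"))
    if (!file.exists(sp_path)) {
      abort(sprintf("Missing spike file for unit '%s'.", uid))
    }
    sp <- read.csv(sp_path, colClasses = "character")
    spikes <- num_or_na(sp$time)
    spikes <- spikes[!is.na(spikes)]
    meta <- jsonlite::read_json(
      file.path(path, "units", paste0(uid, ".meta.json")),
      simplifyVector = TRUE)
    wf <- meta$waveform
    if (length(wf) == 0) wf <- NULL
    unit_record(uid, spikes, waveform = wf,
                session_id = meta$session_id, subject_id = meta$subject_id)
  })
  session(design, trials, pokes, units,
          session_span = mf$session_span,
          session_id = mf$session_id, subject_id = mf$subject_id)
}

#' Load the packaged 32-trial worked-example regression input
#'
#' Returns the complete regression input for first-interval firing of one
#' onset-type unit: 32 trials ordered by type, with the normalized firing
#' response and the constant, interval-fear, total-fear and probability
#' regressors. The probability column carries the programmed cue
#' contingencies 1.00 / 0.375 / 0.00.
#'
#' @return A `pag_regressors` tibble (see [regressor_matrix()]) with columns
#'   `trial`, `trial_type`, `z_firing`, `constant`, `interval_fear`,
#'   `total_fear`, `probability`.
#' @export
load_worked_example <- function() {
  path <- system.file("extdata", "worked_example_regression.csv",
                      package = "pagfear", mustWork = TRUE)
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  structure(d, class = c("pag_regressors", class(d)),
            subset = c("interval_fear", "total_fear", "probability"),
            u_assign = 0.375)
}
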