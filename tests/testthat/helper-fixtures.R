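# Shared fixtures: short-ITI designs keep simulated sessions small enough
# for fast tests while preserving the 32-trial composition and all window
# conventions (10 s pre-cue baseline, 2 s neural baseline, 12 s post-offset
# histogram extent fit inside a 15 s minimum ITI).

quick_design <- function(mean_iti = 30, min_iti = 15) {
  session_design(mean_iti = mean_iti, min_iti = min_iti)
}

quick_session <- function(seed, n_units = 0, bspec = behavior_spec(),
                          design = quick_design()) {
  tr <- make_trial_sequence(design, seed = seed)
  span <- attr(tr, "session_span")
  pk <- simulate_pokes(tr, bspec, seed = seed + 1)
  units <- if (n_units > 0) {
    lapply(seq_len(n_units), function(i) {
      simulate_unit(tr, unit_spec("nonresponsive", baseline_rate = 3 + i),
                    design, session_span = span,
                    unit_id = sprintf("u%02d", i), seed = seed + 10 + i)
    })
  } else list()
  session(design, tr, pk, units, span)
}

# Session with one planted unit of each response profile, shared across
# tests that need labelled units without a full cohort.
profiled_session <- function(seed = 7, design = quick_design()) {
  tr <- make_trial_sequence(design, seed = seed)
  span <- attr(tr, "session_span")
  pk <- simulate_pokes(tr, behavior_spec(), seed = seed + 1)
  specs <- list(
    onset = unit_spec("onset"),
    ramping = unit_spec("ramping"),
    hfr = unit_spec("hfr"),
    flat = unit_spec("nonresponsive", baseline_rate = 4))
  units <- purrr::imap(specs, function(sp, nm) {
    simulate_unit(tr, sp, design, session_span = span, unit_id = nm,
                  seed = seed + match(nm, names(specs)))
  })
  session(design, tr, pk, unname(units), span)
}

find_unit <- function(s, id) {
  s$units[[match(id, vapply(s$units, `[[`, character(1), "unit_id"))]]
}
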