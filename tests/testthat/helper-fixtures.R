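# Small designs and observers shared across tests.

small_config <- function(n_participants = 2, rng_seed = 11L) {
  design_config(n_participants = n_participants, n_blocks = 2,
                trials_per_block = 30, rng_seed = rng_seed)
}

# Mid-sized design whose cells clear the default minimum fit size.
medium_config <- function(n_participants = 4, rng_seed = 5L) {
  design_config(n_participants = n_participants, n_blocks = 10,
                trials_per_block = 60, rng_seed = rng_seed)
}

# Observer with identical parameters in every cell (no condition effects).
flat_observer <- function(dprime = 1.5, criterion = 0.15,
                          gamma = 3.5, alpha = 1, theta = 0.35,
                          anticipation_rate = 0, timing_failure_rate = 0) {
  cells <- default_observer_cells()
  cells$dprime <- dprime
  cells$gamma <- gamma
  cells$alpha <- alpha
  cells$theta <- theta
  observer_model(cells = cells, criterion = criterion, dprime_base = dprime,
                 anticipation_rate = anticipation_rate,
                 timing_failure_rate = timing_failure_rate)
}

# Minimal hand-built trial table, one row per call spec.
trial_row <- function(participant = 1L, target_present = TRUE,
                      target_side = "left", cue_present = TRUE,
                      cue_side = "left", soa_ms = 150,
                      congruency = "congruent", response = "yes",
                      rt_ms = 400, excluded = FALSE,
                      exclusion_reason = NA_character_) {
  tibble::tibble(participant = participant, block = 1L, trial = 1L,
                 target_present = target_present, target_side = target_side,
                 cue_present = cue_present, cue_side = cue_side,
                 soa_ms = soa_ms, congruency = congruency,
                 response = response, rt_ms = rt_ms, excluded = excluded,
                 exclusion_reason = exclusion_reason)
}

# n signal-present and n noise rows for one participant/cell with the given
# counts, for composition tests of the d-prime table.
counted_cell_trials <- function(participant, soa_ms, congruency,
                                hits, misses, fas, crs) {
  opposite <- c(left = "right", right = "left")
  present <- trial_row(participant, soa_ms = soa_ms, congruency = congruency,
                       cue_side = if (congruency == "congruent") "left"
                                  else "right")[
    rep(1L, hits + misses), ]
  present$response <- rep(c("yes", "no"), times = c(hits, misses))
  present$rt_ms[present$response == "no"] <- NA_real_
  absent <- trial_row(participant, target_present = FALSE,
                      target_side = "none", soa_ms = NA_real_,
                      congruency = NA_character_)[rep(1L, fas + crs), ]
  absent$response <- rep(c("yes", "no"), times = c(fas, crs))
  absent$rt_ms <- ifelse(absent$response == "yes", 500, NA_real_)
  dplyr::bind_rows(present, absent)
}
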