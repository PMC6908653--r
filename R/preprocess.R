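#' Exclude anticipatory responses
#'
#' Flags responses faster than `cutoff_ms` (strictly under; default 150 ms)
#' as anticipations: the minimum latency of a voluntary response to the
#' target is taken to be at least the cutoff, so faster presses cannot be
#' target-driven. No upper RT cutoff is applied - slow responses carry real
#' information about the decision process and are kept. Rows flagged by the
#' generator as hardware timing failures remain excluded. Flagging is
#' idempotent: re-running on already-filtered output excludes nothing new.
#'
#' @param trials Trial table with `response`, `rt_ms`, `excluded`,
#'   `exclusion_reason` columns.
#' @param cutoff_ms Anticipation cutoff in milliseconds (>= 0).
#' @return List with `trials` (the table with exclusion flags updated) and
#'   `summary`, a one-row tibble: `n_total`, `n_excluded_fast`,
#'   `n_excluded_timing`, `fraction_excluded`.
#' @seealso [kept_trials()] for the analysis view.
#' @export
#' @examples
#' cfg <- design_config(n_participants = 1)
#' trials <- simulate_behavior(build_design(cfg), observer_model(), seed = 1)
#' exclude_fast_responses(trials)$summary
exclude_fast_responses <- function(trials, cutoff_ms = 150) {
  if (!is.numeric(cutoff_ms) || length(cutoff_ms) != 1 || cutoff_ms < 0) {
    stop_domain("`cutoff_ms` must be a single non-negative number.")
  }
  yes <- trials$response == "yes"
  if (any(yes & is.na(trials$rt_ms))) {
    stop_validation("Every `response == \"yes\"` row must carry an rt_ms.")
  }
  fast <- yes & !trials$excluded & trials$rt_ms < cutoff_ms
  trials$excluded[fast] <- TRUE
  trials$exclusion_reason[fast] <- "anticipation"

  n_total <- nrow(trials)
  n_fast <- sum(trials$exclusion_reason == "anticipation", na.rm = TRUE)
  n_timing <- sum(trials$exclusion_reason == "timing", na.rm = TRUE)
  summary <- tibble::tibble(
    n_total = n_total,
    n_excluded_fast = n_fast,
    n_excluded_timing = n_timing,
    fraction_excluded = (n_fast + n_timing) / n_total)
  list(trials = trials, summary = summary)
}

#' Analysis view of a trial table
#'
#' @param trials Trial table with an `excluded` column.
#' @return The non-excluded rows.
#' @export
kept_trials <- function(trials) {
  dplyr::filter(trials, !.data$excluded)
}

#' Assign analysis cells (strata) to trials
#'
#' Every trial maps to exactly one stratum: cue-present target-present trials
#' form the SOA x congruency cells (`"cue"`), target-present no-cue trials
#' form the no-cue stratum (`"no_cue"`), and all target-absent trials -
#' whether a cue was played or not - form the pooled false-alarm stratum
#' (`"fa_pool"`) per participant, since without both stimuli SOA and
#' congruency are undefined.
#'
#' Inconsistent rows (congruency or SOA defined without both stimuli, or
#' missing where both are present, or an RT without a yes response) raise a
#' validation error listing the offending row numbers.
#'
#' @param trials Trial table.
#' @return The table with a `stratum` column appended.
#' @export
assign_cells <- function(trials) {
  both <- trials$target_present & trials$cue_present
  bad_congr <- xor(both, !is.na(trials$congruency))
  bad_soa <- xor(both, !is.na(trials$soa_ms))
  bad_congr_def <- both & !is.na(trials$congruency) &
    ((trials$congruency == "congruent") != (trials$cue_side == trials$target_side))
  bad_rt <- (trials$response == "yes") != !is.na(trials$rt_ms)
  bad <- which(bad_congr | bad_soa | bad_congr_def | bad_rt)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "Inconsistent trial rows (congruency/SOA/RT definition): %s%s",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) sprintf(" and %d more", length(bad) - 10) else ""))
  }
  trials$stratum <- dplyr::case_when(
    both ~ "cue",
    trials$target_present ~ "no_cue",
    TRUE ~ "fa_pool")
  trials
}

# Assign cells if the caller has not already done so.
ensure_cells <- function(trials) {
  if (!"stratum" %in% names(trials)) assign_cells(trials) else trials
}
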