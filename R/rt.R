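#' Per-cell median response times
#'
#' Median of the kept hit RTs per participant and stratum (each SOA x
#' congruency cell plus the no-cue stratum). Only hits enter: false-alarm
#' RTs are never analyzed. Even-sized cells use the midpoint convention of
#' [stats::median()]. Cells below `min_n` trials are flagged so group
#' averages can drop them.
#'
#' @param trials Trial table (cells assigned if missing, excluded rows
#'   dropped).
#' @param min_n Minimum trials for an unflagged cell.
#' @return Tibble: `participant`, `stratum`, `soa_ms`, `congruency`,
#'   `median_rt_ms`, `n`, `flagged`.
#' @export
median_rt_table <- function(trials, min_n = 5) {
  hits <- dplyr::filter(kept_trials(ensure_cells(trials)),
                        .data$target_present, .data$response == "yes")
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$participant, .data$stratum,
                    .data$soa_ms, .data$congruency),
    median_rt_ms = stats::median(.data$rt_ms),
    n = dplyr::n(),
    .groups = "drop")
  out$flagged <- out$n < min_n
  out
}

#' Inverse efficiency scores
#'
#' Divides each hit RT by the accuracy (hit rate over target-present trials)
#' of the participant x condition cell it belongs to, then averages per cell.
#' IES folds the speed-accuracy trade-off into a single cost measure in
#' milliseconds: lower is more efficient. Division happens per trial before
#' aggregation. Cells with zero accuracy are flagged and excluded from the
#' per-cell output; false-alarm trials never enter.
#'
#' @param trials Trial table.
#' @return List with `per_trial` (one `IESRecord` row per kept hit:
#'   cell keys, `rt_ms`, `accuracy`, `ies_ms`) and `per_cell` (mean IES per
#'   cell with `n` and `accuracy`).
#' @export
ies_table <- function(trials) {
  trials <- kept_trials(ensure_cells(trials))
  present <- dplyr::filter(trials, .data$target_present)
  acc <- dplyr::summarise(
    dplyr::group_by(present, .data$participant, .data$stratum,
                    .data$soa_ms, .data$congruency),
    accuracy = mean(.data$response == "yes"),
    .groups = "drop")
  hits <- dplyr::filter(present, .data$response == "yes")
  per_trial <- dplyr::left_join(
    hits, acc,
    by = c("participant", "stratum", "soa_ms", "congruency"))
  per_trial <- dplyr::mutate(per_trial, ies_ms = .data$rt_ms / .data$accuracy)
  per_trial <- dplyr::select(per_trial, "participant", "stratum", "soa_ms",
                             "congruency", "rt_ms", "accuracy", "ies_ms")
  per_cell <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$participant, .data$stratum,
                    .data$soa_ms, .data$congruency),
    accuracy = .data$accuracy[1],
    mean_ies_ms = mean(.data$ies_ms),
    n = dplyr::n(),
    .groups = "drop")
  zero <- dplyr::anti_join(
    acc[acc$accuracy == 0, ], per_cell,
    by = c("participant", "stratum", "soa_ms", "congruency"))
  list(per_trial = per_trial, per_cell = per_cell, flagged_cells = zero)
}

#' Correlation between pre- and retro-cueing congruency effects
#'
#' For each participant, the congruency effect (incongruent minus congruent
#' mean IES) is computed at the short pre-cue SOA and the short retro-cue
#' SOA; the Spearman rank correlation between the two effect vectors asks
#' whether participants who benefit more from congruent pre-cues also benefit
#' more from congruent retro-cues. The two-sided p-value uses the exact
#' permutation null for `n <= exact_max_n` (no ties), and the t
#' approximation otherwise.
#'
#' @param ies_cells Per-cell IES table (the `per_cell` element of
#'   [ies_table()], or any tibble with `participant`, `soa_ms`, `congruency`,
#'   `mean_ies_ms`).
#' @param soa_pre,soa_retro The two SOAs compared (ms).
#' @param exact_max_n Largest n for the exact permutation p-value.
#' @return One-row tibble: `rho`, `p_value`, `n`, `method`.
#' @export
congruency_effect_correlation <- function(ies_cells, soa_pre = -150,
                                          soa_retro = 150, exact_max_n = 10) {
  eff <- function(soa) {
    d <- dplyr::filter(ies_cells, .data$soa_ms %in% soa,
                       !is.na(.data$congruency))
    w <- tidyr::pivot_wider(
      dplyr::summarise(
        dplyr::group_by(d, .data$participant, .data$congruency),
        ies = mean(.data$mean_ies_ms), .groups = "drop"),
      names_from = "congruency", values_from = "ies")
    if (!all(c("congruent", "incongruent") %in% names(w))) {
      stop_insufficient(sprintf("Missing congruency cells at SOA %g ms.", soa))
    }
    tibble::tibble(participant = w$participant,
                   effect = w$incongruent - w$congruent)
  }
  both <- dplyr::inner_join(eff(soa_pre), eff(soa_retro), by = "participant",
                            suffix = c("_pre", "_retro"))
  both <- both[stats::complete.cases(both), ]
  n <- nrow(both)
  if (n < 4) stop_insufficient("Need at least 4 participants with both effects.")
  x <- both$effect_pre
  y <- both$effect_retro
  rho <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= exact_max_n && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = min(p, 1), n = n, method = method)
}
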