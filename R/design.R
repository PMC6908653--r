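#' Configuration of a cross-modal cueing detection experiment
#'
#' Describes the factorial structure of a speeded go/no-go detection
#' experiment in which a lateralized auditory cue can precede (negative SOA)
#' or follow (positive SOA) a lateralized near-threshold visual target.
#' Trials are evenly split among the cue conditions (each SOA plus an
#' optional no-cue condition); within each condition a fixed proportion of
#' trials carries a target, balanced left/right, and cue-present
#' target-present trials are balanced across congruent/incongruent cue sides.
#'
#' The defaults reproduce the reference design: 20 participants, 20 blocks of
#' 60 trials (1,200 trials per participant), SOAs -600/-150/+150/+450 ms plus
#' a no-cue condition (240 trials each), 2/3 target-present (160 present and
#' 80 absent per condition), jittered pre/post delays of 1-1.5 s and a 1.5 s
#' response window.
#'
#' @param n_participants Number of participants.
#' @param n_blocks,trials_per_block Blocks per participant and trials per
#'   block.
#' @param soa_levels Signed SOAs in milliseconds (cue onset minus target
#'   onset sign convention: negative = pre-cue).
#' @param include_no_cue Include a no-cue condition as an equal share of
#'   trials.
#' @param p_target_present Probability that a trial carries a target.
#' @param jitter_range Two-element vector (ms), uniform jitter for the delays
#'   before and after the target window.
#' @param response_window Response window in ms (metadata only).
#' @param rng_seed Integer seed controlling trial order and jitters.
#' @return An object of class `design_config` (named list).
#' @export
#' @examples
#' cfg <- design_config(n_participants = 2)
#' nrow(build_design(cfg))
design_config <- function(n_participants = 20,
                          n_blocks = 20,
                          trials_per_block = 60,
                          soa_levels = c(-600, -150, 150, 450),
                          include_no_cue = TRUE,
                          p_target_present = 2 / 3,
                          jitter_range = c(1000, 1500),
                          response_window = 1500,
                          rng_seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              soa_levels = as.numeric(soa_levels),
              include_no_cue = isTRUE(include_no_cue),
              p_target_present = p_target_present,
              jitter_range = as.numeric(jitter_range),
              response_window = as.numeric(response_window),
              rng_seed = as.integer(rng_seed))
  validate_design_config(cfg)
  structure(cfg, class = "design_config")
}

validate_design_config <- function(cfg) {
  if (cfg$n_participants < 1 || cfg$n_blocks < 1 || cfg$trials_per_block < 1) {
    stop_domain("Participant, block and trial counts must be positive.")
  }
  if (length(cfg$soa_levels) < 1 && !cfg$include_no_cue) {
    stop_domain("At least one condition (SOA or no-cue) is required.")
  }
  if (anyDuplicated(cfg$soa_levels)) stop_domain("`soa_levels` must be distinct.")
  if (cfg$p_target_present < 0 || cfg$p_target_present > 1) {
    stop_domain("`p_target_present` must lie in [0, 1].")
  }
  if (length(cfg$jitter_range) != 2 || diff(cfg$jitter_range) < 0) {
    stop_domain("`jitter_range` must be an increasing two-element interval.")
  }
  invisible(cfg)
}

# Integer condition arithmetic; errors rather than rounding so fixture counts
# are always exact.
design_counts <- function(cfg) {
  total <- cfg$n_blocks * cfg$trials_per_block
  n_cond <- length(cfg$soa_levels) + cfg$include_no_cue
  if (total %% n_cond != 0) {
    stop_balance(sprintf(
      "%d trials cannot be split evenly across %d conditions.", total, n_cond))
  }
  per_cond <- total %/% n_cond
  n_present <- per_cond * cfg$p_target_present
  if (abs(n_present - round(n_present)) > 1e-9) {
    stop_balance(sprintf(
      "p_target_present = %g does not yield a whole number of target-present trials per condition (%d trials).",
      cfg$p_target_present, per_cond))
  }
  n_present <- as.integer(round(n_present))
  n_absent <- per_cond - n_present
  if (n_present > 0 && n_present %% 2 != 0) {
    stop_balance(sprintf(
      "%d target-present trials per condition cannot be split over sides and congruencies.",
      n_present))
  }
  list(total = total, n_cond = n_cond, per_cond = per_cond,
       n_present = n_present, n_absent = n_absent)
}

one_participant_design <- function(cfg, counts) {
  rows <- list()
  opposite <- c(left = "right", right = "left")
  for (soa in cfg$soa_levels) {
    if (counts$n_present > 0) {
      # n_present/2 per congruency; target sides counterbalanced within each
      # congruency, with opposite remainders so the side margin stays exact
      m <- counts$n_present %/% 2
      side_con <- rep(c("left", "right"), times = c(ceiling(m / 2), floor(m / 2)))
      side_inc <- rep(c("left", "right"), times = c(floor(m / 2), ceiling(m / 2)))
      grid <- data.frame(
        target_side = c(side_con, side_inc),
        congruency = rep(c("congruent", "incongruent"), each = m))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = as.character(soa),
        target_present = TRUE,
        target_side = grid$target_side,
        cue_present = TRUE,
        cue_side = ifelse(grid$congruency == "congruent",
                          grid$target_side, opposite[grid$target_side]),
        soa_ms = soa,
        congruency = grid$congruency)
    }
    if (counts$n_absent > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = as.character(soa),
        target_present = FALSE,
        target_side = "none",
        cue_present = TRUE,
        cue_side = rep_len(c("left", "right"), counts$n_absent),
        soa_ms = NA_real_,        # SOA is undefined without both stimuli
        congruency = NA_character_)
    }
  }
  if (cfg$include_no_cue) {
    if (counts$n_present > 0) {
      h <- counts$n_present %/% 2
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = "no_cue",
        target_present = TRUE,
        target_side = rep(c("left", "right"), times = c(h, h)),
        cue_present = FALSE,
        cue_side = "none",
        soa_ms = NA_real_,
        congruency = NA_character_)
    }
    if (counts$n_absent > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = "no_cue",
        target_present = FALSE,
        target_side = "none",
        cue_present = FALSE,
        cue_side = "none",
        soa_ms = NA_real_,
        congruency = NA_character_)[rep(1L, counts$n_absent), ]
    }
  }
  dplyr::bind_rows(rows)
}

#' Build the stimulus-side trial table of an experiment
#'
#' Emits exactly `n_blocks * trials_per_block` rows per participant with the
#' condition bookkeeping of [design_config()]: equal condition shares, the
#' target-present proportion within each condition, left/right target balance
#' and, within each SOA, an exact congruent/incongruent split. SOA and
#' congruency are left undefined (`NA`) on trials where cue or target is
#' absent, since both refer to the relation between the two stimuli. Trial
#' order is randomized within participant under `rng_seed`; jittered pre- and
#' post-target delays are drawn uniformly from `jitter_range` (emitted for
#' schema realism, unused by analysis).
#'
#' @param config A [design_config()].
#' @return Tibble with columns `participant`, `block`, `trial`, `condition`,
#'   `target_present`, `target_side`, `cue_present`, `cue_side`, `soa_ms`,
#'   `congruency`, `jitter_pre_ms`, `jitter_post_ms`.
#' @export
#' @examples
#' d <- build_design(design_config(n_participants = 1))
#' table(d$condition)
build_design <- function(config) {
  validate_design_config(config)
  counts <- design_counts(config)
  base <- one_participant_design(config, counts)
  with_seed(config$rng_seed, {
    per_part <- lapply(seq_len(config$n_participants), function(p) {
      d <- base[sample.int(nrow(base)), ]
      d$participant <- p
      d$block <- rep(seq_len(config$n_blocks), each = config$trials_per_block)
      d$trial <- rep(seq_len(config$trials_per_block), times = config$n_blocks)
      d$jitter_pre_ms <- stats::runif(nrow(d), config$jitter_range[1],
                                      config$jitter_range[2])
      d$jitter_post_ms <- stats::runif(nrow(d), config$jitter_range[1],
                                       config$jitter_range[2])
      d
    })
    out <- dplyr::bind_rows(per_part)
    dplyr::select(out, "participant", "block", "trial", "condition",
                  "target_present", "target_side", "cue_present", "cue_side",
                  "soa_ms", "congruency", "jitter_pre_ms", "jitter_post_ms")
  })
}

#' Generative observer for the synthetic experiment
#'
#' An equal-variance Gaussian signal-detection observer with per-cell
#' sensitivity and per-cell shifted-Wald response-time parameters. On
#' target-present trials the yes probability is `pnorm(dprime/2 - criterion)`
#' with the cell's d'; on target-absent trials (which belong to no SOA or
#' congruency cell) it is `pnorm(-dprime_base/2 - criterion)` with a single
#' baseline d'. Hit RTs are exact shifted-Wald draws from the cell's
#' parameters; false-alarm RTs come from `fa_params`. A small proportion of
#' responses are anticipations (uniform 50-150 ms), exercising the exclusion
#' rule, and a small proportion of trials are flagged as hardware-timing
#' failures.
#'
#' The default cell table encodes the qualitative effects of the reference
#' study: a general sensitivity and drift-rate boost for the short pre-cue
#' (-150 ms), a spatially specific congruency advantage at the short SOAs
#' (+-150 ms) expressed as higher d' and a 20 ms shorter non-decision time
#' for congruent cues, and no condition effect on the decision threshold.
#'
#' @param cells Tibble with one row per condition cell: `soa_ms` (NA for the
#'   no-cue cell), `congruency` (NA for no-cue), `dprime`, `gamma`, `alpha`,
#'   `theta` (seconds).
#' @param criterion Decision criterion c, distance from the equal-variance
#'   midpoint (positive = conservative).
#' @param dprime_base Baseline d' governing the pooled false-alarm rate.
#' @param fa_params [sw_params()] for false-alarm response times (the
#'   reference study does not report false-alarm RT distributions; these
#'   defaults are unconstrained and the RTs are never modeled).
#' @param anticipation_rate Probability that a response RT is replaced by an
#'   artifactual anticipation in [50, 150) ms.
#' @param timing_failure_rate Probability that a trial is flagged as a
#'   hardware timing failure.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(cells = default_observer_cells(),
                           criterion = 0.15,
                           dprime_base = 1.5,
                           fa_params = sw_params(2.5, 1, 0.4),
                           anticipation_rate = 0.02,
                           timing_failure_rate = 0.01) {
  cells <- tibble::as_tibble(cells)
  need <- c("soa_ms", "congruency", "dprime", "gamma", "alpha", "theta")
  if (!all(need %in% names(cells))) {
    stop_config(paste("Observer cell table must have columns:",
                      paste(need, collapse = ", ")))
  }
  if (any(!is.finite(cells$dprime))) stop_config("All cell d' values must be finite.")
  check_sw(cells$gamma, cells$alpha, cells$theta)
  if (!inherits(fa_params, "sw_params")) {
    fa_params <- do.call(sw_params, as.list(fa_params))
  }
  for (r in c(anticipation_rate, timing_failure_rate)) {
    if (r < 0 || r >= 1) stop_config("Rates must lie in [0, 1).")
  }
  structure(list(cells = cells, criterion = criterion,
                 dprime_base = dprime_base, fa_params = fa_params,
                 anticipation_rate = anticipation_rate,
                 timing_failure_rate = timing_failure_rate),
            class = "observer_model")
}

#' @rdname observer_model
#' @export
default_observer_cells <- function() {
  tibble::tribble(
    ~soa_ms, ~congruency,    ~dprime, ~gamma, ~alpha, ~theta,
    -600,    "congruent",    1.5,     3.5,    1.0,    0.35,
    -600,    "incongruent",  1.5,     3.5,    1.0,    0.35,
    -150,    "congruent",    2.0,     4.0,    1.0,    0.31,
    -150,    "incongruent",  1.8,     4.0,    1.0,    0.33,
     150,    "congruent",    1.7,     3.5,    1.0,    0.33,
     150,    "incongruent",  1.5,     3.5,    1.0,    0.35,
     450,    "congruent",    1.5,     3.5,    1.0,    0.35,
     450,    "incongruent",  1.5,     3.5,    1.0,    0.35,
     NA,     NA,             1.5,     3.3,    1.0,    0.36)
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(
    "Signal-detection observer: c = %.3g, baseline d' = %.3g, %d condition cells\n",
    x$criterion, x$dprime_base, nrow(x$cells)))
  cat(sprintf("  anticipation rate %.3g, timing-failure rate %.3g\n",
              x$anticipation_rate, x$timing_failure_rate))
  invisible(x)
}

#' Simulate observer responses on a designed trial table
#'
#' Adds `response` ("yes"/"no"), `rt_ms`, `excluded` and `exclusion_reason`
#' columns to a [build_design()] table according to the generative model in
#' [observer_model()]. Fully reproducible under `seed`; the caller's RNG
#' state is untouched.
#'
#' @param design Trial table from [build_design()].
#' @param model An [observer_model()].
#' @param seed Integer seed.
#' @return The trial table with response columns appended.
#' @export
#' @examples
#' cfg <- design_config(n_participants = 1)
#' trials <- simulate_behavior(build_design(cfg), observer_model(), seed = 7)
#' table(trials$response)
simulate_behavior <- function(design, model, seed) {
  stopifnot(inherits(model, "observer_model"))
  n <- nrow(design)
  present_cued <- design$target_present & design$cue_present
  present_uncued <- design$target_present & !design$cue_present

  key <- function(soa, congr) paste(soa, congr, sep = "|")
  cell_tab <- model$cells
  cell_key <- key(cell_tab$soa_ms, cell_tab$congruency)
  row_key <- rep(NA_character_, n)
  row_key[present_cued] <- key(design$soa_ms[present_cued],
                               design$congruency[present_cued])
  row_key[present_uncued] <- key(NA_real_, NA_character_)
  idx <- match(row_key, cell_key)
  missing <- design$target_present & is.na(idx)
  if (any(missing)) {
    bad <- unique(row_key[missing])
    stop_config(paste("Observer model has no parameters for cell(s):",
                      paste(bad, collapse = "; ")))
  }

  with_seed(seed, {
    p_yes <- numeric(n)
    p_yes[design$target_present] <-
      stats::pnorm(cell_tab$dprime[idx[design$target_present]] / 2 - model$criterion)
    p_yes[!design$target_present] <-
      stats::pnorm(-model$dprime_base / 2 - model$criterion)
    response <- ifelse(stats::runif(n) < p_yes, "yes", "no")

    rt <- rep(NA_real_, n)
    hit <- design$target_present & response == "yes"
    for (ci in unique(idx[hit])) {
      sel <- which(hit & idx == ci)
      rt[sel] <- s_to_ms(rsw(length(sel), cell_tab$gamma[ci],
                             cell_tab$alpha[ci], cell_tab$theta[ci]))
    }
    fa <- !design$target_present & response == "yes"
    if (any(fa)) {
      rt[fa] <- s_to_ms(rsw(sum(fa), model$fa_params$gamma,
                            model$fa_params$alpha, model$fa_params$theta))
    }
    yes <- response == "yes"
    if (model$anticipation_rate > 0 && any(yes)) {
      antic <- yes & stats::runif(n) < model$anticipation_rate
      rt[antic] <- stats::runif(sum(antic), 50, 150)
    }
    timing <- stats::runif(n) < model$timing_failure_rate

    out <- design
    out$response <- response
    out$rt_ms <- rt
    out$excluded <- timing
    out$exclusion_reason <- ifelse(timing, "timing", NA_character_)
    out
  })
}

#' Between-block contrast adjustment rule
#'
#' After each block, the target contrast is stepped down by 0.1 (percent
#' contrast) when the block hit rate exceeded 80%, stepped up by 0.1 when it
#' fell below 70%, and left unchanged inside the 70-80% dead band. The result
#' is clamped to \[0.1, 100\] (contrast must stay positive; one step is the
#' smallest representable level).
#'
#' @param block_hit_rate Hit rate of the preceding block, in \[0, 1\].
#' @param current_contrast Current Gabor contrast in percent.
#' @return Adjusted contrast in percent.
#' @export
#' @examples
#' adapt_contrast(0.85, 1.0)  # too easy -> 0.9
#' adapt_contrast(0.65, 1.0)  # too hard -> 1.1
adapt_contrast <- function(block_hit_rate, current_contrast) {
  if (any(block_hit_rate < 0 | block_hit_rate > 1)) {
    stop_domain("`block_hit_rate` must lie in [0, 1].")
  }
  out <- current_contrast +
    ifelse(block_hit_rate > 0.80, -0.1,
           ifelse(block_hit_rate < 0.70, 0.1, 0))
  pmin(pmax(out, 0.1), 100)
}

#' Simple contrast-to-sensitivity map
#'
#' Linear stand-in for a full psychometric function, used to demonstrate the
#' adaptive contrast rule: `dprime = slope * contrast`. No staircase
#' procedure is reproduced.
#'
#' @param contrast Contrast in percent.
#' @param slope d' per percent contrast.
#' @return d' values (floored at 0).
#' @export
contrast_to_dprime <- function(contrast, slope = 1.5) {
  pmax(slope * contrast, 0)
}
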