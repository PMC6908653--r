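#' Reproducible end-to-end run configuration
#'
#' Bundles everything a full analysis run needs: the master seed, the
#' experiment design, the generative observer, which analysis stages run,
#' and the guard thresholds. A run is reproducible from the configuration
#' alone; the master seed deterministically spawns per-stage seeds so stages
#' can be re-run in isolation.
#'
#' @param seed Master integer seed.
#' @param design A [design_config()].
#' @param observer An [observer_model()].
#' @param stages Character subset of `c("sdt", "rt", "fit", "gof", "anova")`.
#' @param fit_soas SOAs (ms) whose cells are fitted.
#' @param min_cell_n Minimum hits per fitted cell.
#' @param n_boot Bootstrap resamples for contrasts.
#' @param gof_thresholds Named vector with `delta_bar` and `rho_delta_sigma`
#'   warn thresholds.
#' @param output_dir Optional directory for tidy CSV outputs and the JSON
#'   report.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       design = design_config(),
                       observer = observer_model(),
                       stages = c("sdt", "rt", "fit", "gof", "anova"),
                       fit_soas = c(-150, 150),
                       min_cell_n = 20,
                       n_boot = 10000,
                       gof_thresholds = c(delta_bar = 0.5, rho_delta_sigma = 0.3),
                       output_dir = NULL) {
  stages <- match.arg(stages, c("sdt", "rt", "fit", "gof", "anova"),
                      several.ok = TRUE)
  structure(list(seed = as.integer(seed), design = design, observer = observer,
                 stages = stages, fit_soas = fit_soas,
                 min_cell_n = min_cell_n, n_boot = n_boot,
                 gof_thresholds = gof_thresholds, output_dir = output_dir),
            class = "run_config")
}

# Per-stage substreams from the master seed; offsets are arbitrary but fixed.
stage_seed <- function(seed, stage) {
  offsets <- c(design = 101L, behavior = 211L, boot = 307L, fit = 401L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> signal-detection analysis -> RT/IES
#' analysis -> per-cell shifted-Wald fits -> goodness-of-fit battery ->
#' per-parameter repeated-measures ANOVAs, honoring the stage switches in
#' the configuration. Returns a report (and writes tidy CSVs plus a JSON
#' report when `output_dir` is set). Two runs with the same configuration
#' produce identical reports.
#'
#' @param config A [run_config()].
#' @return A list report: `seed`, `counts`, `exclusions`, and per-stage
#'   blocks (`sdt`, `rt`, `fit`, `gof`, `anova`) for the enabled stages. The
#'   full trial table and fit table are attached as attributes `trials` and
#'   `fits`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  cfg$design$rng_seed <- stage_seed(cfg$seed, "design")
  design <- build_design(cfg$design)
  trials <- simulate_behavior(design, cfg$observer,
                              seed = stage_seed(cfg$seed, "behavior"))
  ex <- exclude_fast_responses(trials)
  trials <- assign_cells(ex$trials)
  kept <- kept_trials(trials)

  report <- list(
    package_version = as.character(utils::packageVersion("retrocue")),
    seed = cfg$seed,
    counts = list(
      n_participants = cfg$design$n_participants,
      n_trials_total = nrow(trials),
      n_trials_per_participant = nrow(trials) / cfg$design$n_participants,
      n_kept = nrow(kept)),
    exclusions = as.list(ex$summary))

  if ("sdt" %in% cfg$stages) {
    dtab <- dprime_table(trials)
    cue_cells <- dplyr::filter(dtab, .data$stratum == "cue")
    an <- rm_anova_2way(cue_cells, dv = "dprime", factor_a = "soa_ms",
                        factor_b = "congruency")
    no_cue <- dplyr::filter(dtab, .data$stratum == "no_cue")
    cued_mean <- dplyr::summarise(
      dplyr::group_by(cue_cells, .data$participant, .data$soa_ms),
      dprime = mean(.data$dprime), .groups = "drop")
    soas <- sort(unique(cued_mean$soa_ms))
    contrasts <- purrr::map_dfr(soas, function(s) {
      a <- cued_mean$dprime[cued_mean$soa_ms == s][order(cued_mean$participant[cued_mean$soa_ms == s])]
      b <- no_cue$dprime[order(no_cue$participant)]
      ci <- bootstrap_mean_diff_ci(a, b, n_boot = cfg$n_boot,
                                   n_comparisons = length(soas),
                                   seed = stage_seed(cfg$seed, "boot") + match(s, soas))
      dplyr::mutate(ci, contrast = sprintf("cued(%g ms) - no-cue", s),
                    .before = 1)
    })
    report$sdt <- list(anova = an, contrasts = contrasts,
                       grand_mean_dprime = mean(dtab$dprime))
    report$sdt_table <- dtab
  }

  if ("rt" %in% cfg$stages) {
    med <- median_rt_table(trials)
    ies <- ies_table(trials)
    corr <- congruency_effect_correlation(ies$per_cell)
    report$rt <- list(
      median_rt = med, ies_per_cell = ies$per_cell,
      effect_correlation = corr,
      grand_median_rt_ms = stats::median(med$median_rt_ms))
  }

  fits <- NULL
  if ("fit" %in% cfg$stages) {
    fits <- fit_all_cells(trials, soa_levels = cfg$fit_soas,
                          min_n = cfg$min_cell_n)
    report$fit <- list(
      n_cells_attempted = nrow(fits),
      n_cells_fitted = sum(fits$converged & !fits$skipped),
      n_cells_skipped = sum(fits$skipped),
      group_params = group_sw_params(fits))
  }

  if ("gof" %in% cfg$stages && !is.null(fits)) {
    g <- gof_summary(trials, fits,
                     delta_bar_warn = cfg$gof_thresholds[["delta_bar"]],
                     rho_warn = cfg$gof_thresholds[["rho_delta_sigma"]])
    report$gof <- list(delta_bar = g$delta_bar, delta_sd = g$delta_sd,
                       q95_range = g$q95_range,
                       rho_delta_sigma = g$rho_delta_sigma,
                       flags = as.list(g$flags))
    report$gof_report <- g
  }

  if ("anova" %in% cfg$stages && !is.null(fits)) {
    ok <- dplyr::filter(fits, .data$converged & !.data$skipped)
    # the RM-ANOVA needs complete cases: drop participants missing any cell
    n_cells_expected <- length(unique(ok$soa_ms)) * length(unique(ok$congruency))
    complete <- dplyr::filter(
      dplyr::add_count(ok, .data$participant, name = ".n_cells"),
      .data$.n_cells == n_cells_expected)
    complete$.n_cells <- NULL
    if (length(unique(complete$participant)) >= 2) {
      report$anova <- lapply(
        stats::setNames(c("gamma", "alpha", "theta"),
                        c("gamma", "alpha", "theta")),
        function(par) rm_anova_2way(complete, dv = par, factor_a = "soa_ms",
                                    factor_b = "congruency"))
      report$anova_n_participants <- length(unique(complete$participant))
    } else {
      report$anova <- NULL
      report$anova_n_participants <- length(unique(complete$participant))
    }
  }

  if (!is.null(cfg$output_dir)) write_pipeline_outputs(report, trials, fits, cfg)
  attr(report, "trials") <- trials
  attr(report, "fits") <- fits
  report
}

write_pipeline_outputs <- function(report, trials, fits, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(trials, file.path(cfg$output_dir, "trials.csv"))
  if (!is.null(report$sdt_table)) {
    readr::write_csv(report$sdt_table, file.path(cfg$output_dir, "dprime.csv"), na = "")
  }
  if (!is.null(fits)) {
    readr::write_csv(fits, file.path(cfg$output_dir, "sw_fits.csv"), na = "")
  }
  slim <- report
  slim$sdt_table <- NULL
  slim$gof_report <- NULL
  jsonlite::write_json(slim, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}

#' Parameter- and effect-recovery study
#'
#' Repeats simulate + preprocess + fit `n_replicates` times and tabulates,
#' per replicate, the group-mean fitted parameters, the congruency effects
#' on each parameter at the fitted SOAs (incongruent minus congruent), the
#' d' congruency effect (congruent minus incongruent), and the
#' repeated-measures-ANOVA congruency p-values for theta and alpha. The
#' summary compares each effect with the generator truth (bias, RMSE) and
#' counts how often the ANOVA flags it at the 0.05 level - with a true
#' non-decision-time effect and no threshold effect, theta should be flagged
#' more often than alpha.
#'
#' @param config A [run_config()]; its observer defines the truth.
#' @param n_replicates Number of simulated experiments.
#' @param seed Integer seed; replicate i uses `seed + i`.
#' @return List with `replicates` (one row each), `summary` and `truth`.
#' @export
recover_effects <- function(config, n_replicates = 20, seed = 1L) {
  stopifnot(inherits(config, "run_config"))
  if (n_replicates < 1) stop_domain("`n_replicates` must be >= 1.")
  cells <- config$observer$cells
  short <- dplyr::filter(cells, .data$soa_ms %in% config$fit_soas)
  truth_of <- function(par) {
    w <- tidyr::pivot_wider(short[, c("soa_ms", "congruency", par)],
                            names_from = "congruency",
                            values_from = dplyr::all_of(par))
    mean(w$incongruent - w$congruent)
  }
  # With pooled false alarms the estimated d' is (d'_cell + d'_base)/2 under
  # the generative convention (hit prob pnorm(d'/2 - c), shared FA term), so
  # the measurable congruency contrast is half the generative difference.
  truth <- list(theta_effect = truth_of("theta"),
                alpha_effect = truth_of("alpha"),
                gamma_effect = truth_of("gamma"),
                dprime_effect = -truth_of("dprime") / 2)

  reps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    cfg$stages <- c("sdt", "fit", "anova")
    cfg$output_dir <- NULL
    rep_out <- run_pipeline(cfg)
    fits <- dplyr::filter(attr(rep_out, "fits"), .data$converged & !.data$skipped)
    eff <- function(par) {
      per <- tidyr::pivot_wider(
        dplyr::summarise(
          dplyr::group_by(fits, .data$participant, .data$congruency),
          v = mean(.data[[par]]), .groups = "drop"),
        names_from = "congruency", values_from = "v")
      mean(per$incongruent - per$congruent)
    }
    dtab <- dplyr::filter(rep_out$sdt_table, .data$stratum == "cue",
                          .data$soa_ms %in% config$fit_soas)
    dper <- tidyr::pivot_wider(
      dplyr::summarise(
        dplyr::group_by(dtab, .data$participant, .data$congruency),
        v = mean(.data$dprime), .groups = "drop"),
      names_from = "congruency", values_from = "v")
    p_of <- function(par) {
      an <- rep_out$anova[[par]]
      if (is.null(an)) return(NA_real_)
      an$p_gg[an$effect == "congruency"]
    }
    tibble::tibble(
      replicate = i,
      theta_effect = eff("theta"),
      alpha_effect = eff("alpha"),
      gamma_effect = eff("gamma"),
      dprime_effect = mean(dper$congruent - dper$incongruent),
      p_theta_congruency = p_of("theta"),
      p_alpha_congruency = p_of("alpha"),
      n_cells_fitted = nrow(fits))
  })

  summarize_one <- function(name) {
    est <- reps[[paste0(name, "_effect")]]
    tr <- truth[[paste0(name, "_effect")]]
    tibble::tibble(effect = name, truth = tr, mean_estimate = mean(est),
                   bias = mean(est) - tr, rmse = sqrt(mean((est - tr)^2)))
  }
  summary <- dplyr::bind_rows(lapply(c("theta", "alpha", "gamma", "dprime"),
                                     summarize_one))
  list(replicates = reps, summary = summary, truth = truth,
       power = c(theta = mean(reps$p_theta_congruency < 0.05, na.rm = TRUE),
                 alpha = mean(reps$p_alpha_congruency < 0.05, na.rm = TRUE)))
}

#' Serialize and restore run configurations
#'
#' Round-trips a [run_config()] through YAML (or JSON, by file extension) so
#' a run is reproducible from the file alone.
#'
#' @param config A [run_config()].
#' @param path Destination (`.yaml`/`.yml` or `.json`).
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    seed = config$seed,
    design = unclass(config$design),
    observer = list(
      cells = lapply(seq_len(nrow(config$observer$cells)), function(i)
        as.list(config$observer$cells[i, ])),
      criterion = config$observer$criterion,
      dprime_base = config$observer$dprime_base,
      fa_params = unclass(config$observer$fa_params),
      anticipation_rate = config$observer$anticipation_rate,
      timing_failure_rate = config$observer$timing_failure_rate),
    stages = config$stages,
    fit_soas = config$fit_soas,
    min_cell_n = config$min_cell_n,
    n_boot = config$n_boot,
    gof_thresholds = as.list(config$gof_thresholds),
    output_dir = config$output_dir)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(x$seed)) stop_config("Run configuration must carry a seed.")
  cells <- dplyr::bind_rows(lapply(x$observer$cells, function(r) {
    tibble::tibble(
      soa_ms = if (is.null(r$soa_ms)) NA_real_ else as.numeric(r$soa_ms),
      congruency = if (is.null(r$congruency)) NA_character_ else r$congruency,
      dprime = r$dprime, gamma = r$gamma, alpha = r$alpha, theta = r$theta)
  }))
  design <- do.call(design_config, x$design[names(x$design) != ""])
  observer <- observer_model(
    cells = cells, criterion = x$observer$criterion,
    dprime_base = x$observer$dprime_base,
    fa_params = do.call(sw_params, x$observer$fa_params),
    anticipation_rate = x$observer$anticipation_rate,
    timing_failure_rate = x$observer$timing_failure_rate)
  run_config(seed = x$seed, design = design, observer = observer,
             stages = unlist(x$stages), fit_soas = unlist(x$fit_soas),
             min_cell_n = x$min_cell_n, n_boot = x$n_boot,
             gof_thresholds = unlist(x$gof_thresholds),
             output_dir = x$output_dir)
}
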