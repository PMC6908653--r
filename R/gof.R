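#' Quantile-quantile points for a fitted shifted-Wald cell
#'
#' Pairs the empirical order statistics with the model quantiles at plotting
#' positions `(i - 0.5)/n`. A least-squares line through the points
#' summarizes systematic misfit: slope near 1 and intercept near 0 indicate a
#' good fit; a pure location misfit shows up in the intercept (in seconds).
#'
#' @param rts Response times in seconds.
#' @param fit An `sw_fit` (from [fit_sw_mle()]).
#' @return Tibble with columns `p`, `empirical_s`, `model_s`, and attributes
#'   `slope` and `intercept`; `NULL` (with a warning) for an unconverged fit.
#' @export
qq_points <- function(rts, fit) {
  if (!isTRUE(fit$converged)) {
    warning("Skipping QQ points for an unconverged fit.")
    return(NULL)
  }
  n <- length(rts)
  if (n < 10) stop_insufficient("Need at least 10 response times for QQ points.")
  p <- (seq_len(n) - 0.5) / n
  emp <- sort(rts)
  mod <- qsw(p, fit$gamma, fit$alpha, fit$theta)
  co <- stats::coef(stats::lm(emp ~ mod))
  out <- tibble::tibble(p = p, empirical_s = emp, model_s = mod)
  attr(out, "intercept") <- unname(co[1])
  attr(out, "slope") <- unname(co[2])
  out
}

#' Standardized decile residuals of a shifted-Wald fit
#'
#' For deciles p = 0.1, ..., 0.9: `(empirical decile - model decile) / SD(X)`
#' where `SD(X) = sqrt(alpha/gamma^3)` is the fitted distribution's standard
#' deviation. Standardizing by SD(X) partially compensates for residual
#' variance growing with the spread of the data, making cells comparable.
#' Empirical deciles use the linear-interpolation (type 7) convention.
#'
#' @param rts Response times in seconds.
#' @param fit An `sw_fit`.
#' @return Numeric 9-vector of standardized residuals.
#' @export
decile_residuals <- function(rts, fit) {
  if (length(rts) < 20) {
    stop_insufficient("Need at least 20 response times for decile residuals.")
  }
  p <- seq(0.1, 0.9, by = 0.1)
  emp <- stats::quantile(rts, p, type = 7, names = FALSE)
  mod <- qsw(p, fit$gamma, fit$alpha, fit$theta)
  sdx <- sw_moments(fit$gamma, fit$alpha, fit$theta)[["sd"]]
  (emp - mod) / sdx
}

#' Goodness-of-fit battery over fitted cells
#'
#' The three-step descriptive battery for per-cell shifted-Wald fits: per
#' cell, the sum of the nine standardized decile residuals (Delta); across
#' cells, the mean (Delta-bar), standard deviation (sigma) and 2.5-97.5%
#' quantile range of Delta; and the Pearson correlation rho between Delta
#' and each cell's fitted SD(X), which measures whether SD(X) succeeded as a
#' standardization statistic. Both Delta-bar and rho should be as close to
#' zero as possible; the report carries warn flags at configurable
#' thresholds. Outlying cells are reported, never removed.
#'
#' @param trials Trial table (hit RTs are extracted per cell, in ms).
#' @param fits Output of [fit_all_cells()].
#' @param delta_bar_warn,rho_warn Warn thresholds for |Delta-bar| and
#'   |rho|.
#' @return An object of class `gof_report`: list with `per_cell` (tibble of
#'   `participant`, `soa_ms`, `congruency`, `delta`, `sd_x`, `n`),
#'   `decile_residuals` (long tibble), `delta_bar`, `delta_sd`, `q95_range`,
#'   `rho_delta_sigma`, `flags`.
#' @export
gof_summary <- function(trials, fits, delta_bar_warn = 0.5, rho_warn = 0.3) {
  trials <- kept_trials(ensure_cells(trials))
  ok <- dplyr::filter(fits, .data$converged & !.data$skipped)
  if (nrow(ok) < 3) stop_insufficient("Need at least 3 cells with valid fits.")
  res_rows <- vector("list", nrow(ok))
  per_cell <- vector("list", nrow(ok))
  for (i in seq_len(nrow(ok))) {
    f <- ok[i, ]
    d <- dplyr::filter(trials, .data$participant == f$participant,
                       .data$stratum == "cue",
                       .data$soa_ms == f$soa_ms,
                       .data$congruency == f$congruency,
                       .data$target_present, .data$response == "yes")
    fit <- list(gamma = f$gamma, alpha = f$alpha, theta = f$theta,
                converged = TRUE)
    r <- decile_residuals(ms_to_s(d$rt_ms), fit)
    res_rows[[i]] <- tibble::tibble(
      participant = f$participant, soa_ms = f$soa_ms,
      congruency = f$congruency, decile = seq(0.1, 0.9, by = 0.1),
      residual = r)
    per_cell[[i]] <- tibble::tibble(
      participant = f$participant, soa_ms = f$soa_ms,
      congruency = f$congruency, delta = sum(r),
      sd_x = sw_moments(f$gamma, f$alpha, f$theta)[["sd"]],
      n = nrow(d))
  }
  per_cell <- dplyr::bind_rows(per_cell)
  delta <- per_cell$delta
  delta_sd <- stats::sd(delta)
  degenerate <- delta_sd == 0 || stats::sd(per_cell$sd_x) == 0
  rho <- if (degenerate) NA_real_ else stats::cor(delta, per_cell$sd_x)
  flags <- c(
    delta_bar = abs(mean(delta)) > delta_bar_warn,
    rho_delta_sigma = !is.na(rho) && abs(rho) > rho_warn,
    degenerate = degenerate)
  structure(list(
    per_cell = per_cell,
    decile_residuals = dplyr::bind_rows(res_rows),
    delta_bar = mean(delta),
    delta_sd = delta_sd,
    q95_range = stats::quantile(delta, c(0.025, 0.975), names = FALSE),
    rho_delta_sigma = rho,
    flags = flags), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Goodness-of-fit battery over %d cells\n", nrow(x$per_cell)))
  cat(sprintf("  Delta-bar = %.3f, sigma = %.3f, 95%% range [%.2f, %.2f]\n",
              x$delta_bar, x$delta_sd, x$q95_range[1], x$q95_range[2]))
  cat(sprintf("  rho(Delta, SD) = %s\n",
              if (is.na(x$rho_delta_sigma)) "undefined (degenerate)"
              else sprintf("%.3f", x$rho_delta_sigma)))
  if (any(x$flags)) {
    cat("  warn flags:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  }
  invisible(x)
}
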