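#' Signal-detection sensitivity d'
#'
#' Computes `d' = Z(hit rate) - Z(false-alarm rate)` under the equal-variance
#' Gaussian model, where `Z` is the standard-normal quantile. The default
#' log-linear rate correction adds 0.5 to each of the four counts before
#' forming rates, keeping d' finite at perfect (0 or 1) rates and avoiding
#' the discontinuity of corrections that trigger only at the extremes;
#' `correction = "none"` uses the raw rates (infinite at the extremes).
#'
#' d' is antisymmetric under swapping the signal and noise margins:
#' `dprime(h, m, f, c) == -dprime(f, c, h, m)`.
#'
#' @param hits,misses Counts on target-present trials.
#' @param fas,crs False-alarm and correct-rejection counts on target-absent
#'   trials.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return Numeric d' (vectorized over the counts).
#' @export
#' @examples
#' dprime(120, 40, 20, 60)
#' dprime(75, 25, 25, 75, correction = "none")  # 2 * qnorm(0.75)
dprime <- function(hits, misses, fas, crs,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  counts <- c(hits, misses, fas, crs)
  if (anyNA(counts) || any(counts < 0)) {
    stop_domain("Counts must be non-negative.")
  }
  if (any(hits + misses <= 0) || any(fas + crs <= 0)) {
    stop_insufficient("Both the target-present and target-absent margins need at least one trial.")
  }
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (hits + misses + 1)
    far <- (fas + 0.5) / (fas + crs + 1)
  } else {
    hr <- hits / (hits + misses)
    far <- fas / (fas + crs)
  }
  stats::qnorm(hr) - stats::qnorm(far)
}

#' Per-cell detection sensitivity table
#'
#' One d' per participant x SOA x congruency cell plus the no-cue stratum.
#' Each cell's d' combines the cell's hit rate with the participant's pooled
#' false-alarm rate over all target-absent trials - the single biggest
#' analytic assumption of the pipeline, forced by target-absent trials
#' belonging to no SOA or congruency category. Stored `hit_rate` and
#' `fa_rate` are the raw proportions; the rate correction is applied only
#' inside the d' computation.
#'
#' @param trials Trial table (cells are assigned if missing; excluded rows
#'   are dropped).
#' @inheritParams dprime
#' @return Tibble with one row per cell: `participant`, `stratum`, `soa_ms`,
#'   `congruency`, `n_hits`, `n_misses`, `hit_rate`, `fa_rate`, `dprime`.
#' @export
dprime_table <- function(trials, correction = "loglinear") {
  trials <- kept_trials(ensure_cells(trials))
  absent <- dplyr::filter(trials, !.data$target_present)
  fa_tab <- dplyr::summarise(
    dplyr::group_by(absent, .data$participant),
    n_fas = sum(.data$response == "yes"),
    n_crs = sum(.data$response == "no"),
    .groups = "drop")
  present <- dplyr::filter(trials, .data$target_present)
  if (nrow(present) == 0) stop_insufficient("No target-present trials to analyze.")
  cells <- dplyr::summarise(
    dplyr::group_by(present, .data$participant, .data$stratum,
                    .data$soa_ms, .data$congruency),
    n_hits = sum(.data$response == "yes"),
    n_misses = sum(.data$response == "no"),
    .groups = "drop")
  out <- dplyr::left_join(cells, fa_tab, by = "participant")
  if (any(is.na(out$n_fas)) || any(out$n_fas + out$n_crs == 0)) {
    bad <- unique(out$participant[is.na(out$n_fas)])
    stop_insufficient(paste("No target-absent trials for participant(s):",
                            paste(bad, collapse = ", ")))
  }
  out$hit_rate <- out$n_hits / (out$n_hits + out$n_misses)
  out$fa_rate <- out$n_fas / (out$n_fas + out$n_crs)
  out$dprime <- dprime(out$n_hits, out$n_misses, out$n_fas, out$n_crs,
                       correction = correction)
  dplyr::select(out, "participant", "stratum", "soa_ms", "congruency",
                "n_hits", "n_misses", "hit_rate", "fa_rate", "dprime")
}

# Column-normalized Helmert contrasts: orthonormal, orthogonal to the
# constant; basis for Greenhouse-Geisser epsilon computation.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

gg_epsilon_from <- function(Y, C) {
  d <- ncol(C)
  if (d == 1L) return(1)
  M <- t(C) %*% stats::cov(Y) %*% C
  eps <- sum(diag(M))^2 / (d * sum(M^2))
  min(max(eps, 1 / d), 1)
}

#' Two-way repeated-measures ANOVA with sphericity correction
#'
#' Classical within-subject decomposition for a complete balanced
#' participant x A x B table (one value per cell). Each effect is tested
#' against its own participant-interaction error stratum. Sphericity is
#' handled by the Greenhouse-Geisser epsilon computed from the covariance of
#' the effect's orthonormal contrast scores (epsilon is exactly 1 for
#' two-level effects, and the corrected p equals the uncorrected one when
#' epsilon = 1); `p_gg` is the epsilon-corrected p-value. Effect size is
#' generalized eta squared for a fully within design:
#' `SS_effect / (SS_effect + all subject-related error strata)`.
#'
#' @param data Data frame in long format.
#' @param dv,participant,factor_a,factor_b Column names (strings).
#' @return Tibble with one row per effect (`factor_a`, `factor_b`,
#'   interaction): `effect`, `F`, `df_num`, `df_den`, `gg_epsilon`, `p_gg`,
#'   `gen_eta_sq`, `ss`. The full sums-of-squares decomposition (including
#'   error strata and `ss_total`) is attached as attribute `"ss"`.
#' @export
rm_anova_2way <- function(data, dv, participant = "participant",
                          factor_a, factor_b) {
  p <- factor(data[[participant]])
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  y <- data[[dv]]
  if (anyNA(y)) stop_validation("The dependent variable contains NA.")
  np <- nlevels(p); na <- nlevels(A); nb <- nlevels(B)
  tab <- table(p, A, B)
  if (any(tab != 1)) {
    stop_balance("Design must be complete and balanced: exactly one value per participant x A x B cell.")
  }

  gm <- mean(y)
  m_a <- tapply(y, A, mean)
  m_b <- tapply(y, B, mean)
  m_p <- tapply(y, p, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_pa <- tapply(y, list(p, A), mean)
  m_pb <- tapply(y, list(p, B), mean)

  ss_a <- np * nb * sum((m_a - gm)^2)
  ss_b <- np * na * sum((m_b - gm)^2)
  ss_s <- na * nb * sum((m_p - gm)^2)
  ss_ab <- np * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + gm)^2)
  ss_as <- nb * sum((m_pa - outer(m_p, rep(1, na)) -
                       outer(rep(1, np), m_a) + gm)^2)
  ss_bs <- na * sum((m_pb - outer(m_p, rep(1, nb)) -
                       outer(rep(1, np), m_b) + gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_abs <- ss_total - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  # participant x cell matrix, A-major column order, for epsilon
  Y <- matrix(NA_real_, np, na * nb)
  col <- (as.integer(A) - 1L) * nb + as.integer(B)
  Y[cbind(as.integer(p), col)] <- y
  Ca <- orthonormal_contrasts(na); Cb <- orthonormal_contrasts(nb)
  ones_a <- matrix(1 / sqrt(na), na, 1); ones_b <- matrix(1 / sqrt(nb), nb, 1)
  eps_a <- gg_epsilon_from(Y, kronecker(Ca, ones_b))
  eps_b <- gg_epsilon_from(Y, kronecker(ones_a, Cb))
  eps_ab <- gg_epsilon_from(Y, kronecker(Ca, Cb))

  err_all <- ss_s + ss_as + ss_bs + ss_abs
  row <- function(effect, ss_eff, df1, ss_err, df2, eps) {
    Fv <- (ss_eff / df1) / (ss_err / df2)
    tibble::tibble(effect = effect, F = Fv, df_num = df1, df_den = df2,
                   gg_epsilon = eps,
                   p_gg = stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
                   gen_eta_sq = ss_eff / (ss_eff + err_all),
                   ss = ss_eff)
  }
  out <- dplyr::bind_rows(
    row(factor_a, ss_a, na - 1, ss_as, (na - 1) * (np - 1), eps_a),
    row(factor_b, ss_b, nb - 1, ss_bs, (nb - 1) * (np - 1), eps_b),
    row(paste(factor_a, factor_b, sep = ":"), ss_ab, (na - 1) * (nb - 1),
        ss_abs, (na - 1) * (nb - 1) * (np - 1), eps_ab))
  attr(out, "ss") <- list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
                          ss_s = ss_s, ss_as = ss_as, ss_bs = ss_bs,
                          ss_abs = ss_abs, ss_total = ss_total)
  out
}

#' Percentile bootstrap CI of a paired mean difference
#'
#' Resamples participants (the pairing unit) with replacement and returns the
#' percentile confidence interval of the mean of `a - b` at level
#' `alpha / n_comparisons` (Bonferroni adjustment for a family of
#' contrasts).
#'
#' @param a,b Equal-length paired vectors (one value per participant).
#' @param n_boot Number of bootstrap resamples (default 10,000).
#' @param alpha Family-wise level before adjustment.
#' @param n_comparisons Bonferroni divisor.
#' @param seed Optional seed for reproducibility.
#' @return One-row tibble: `mean_diff`, `lower`, `upper`, `n_boot`,
#'   `alpha_adjusted`.
#' @export
#' @examples
#' bootstrap_mean_diff_ci(rnorm(20, 1), rnorm(20), seed = 1)
bootstrap_mean_diff_ci <- function(a, b, n_boot = 10000, alpha = 0.05,
                                   n_comparisons = 1, seed = NULL) {
  if (length(a) != length(b)) stop_domain("`a` and `b` must be paired (equal length).")
  n <- length(a)
  if (n < 2) stop_insufficient("Need at least 2 pairs.")
  if (anyNA(a) || anyNA(b)) stop_domain("Paired values must not contain NA.")
  d <- a - b
  al <- alpha / n_comparisons
  with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    means <- colMeans(matrix(d[idx], nrow = n))
    ci <- stats::quantile(means, c(al / 2, 1 - al / 2), names = FALSE, type = 7)
    tibble::tibble(mean_diff = mean(d), lower = ci[1], upper = ci[2],
                   n_boot = n_boot, alpha_adjusted = al)
  })
}
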