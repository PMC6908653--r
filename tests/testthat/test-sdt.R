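test_that("d-prime matches the standard-normal quantile oracle", {
  # uncorrected rates: Z(0.75) - Z(0.25) = 2 * qnorm(0.75)
  expect_equal(dprime(75, 25, 25, 75, correction = "none"),
               2 * qnorm(0.75), tolerance = 1e-12)
  # log-linear correction: oracle computed from first principles
  hr <- (75 + 0.5) / 101; far <- (25 + 0.5) / 101
  expect_equal(dprime(75, 25, 25, 75), qnorm(hr) - qnorm(far),
               tolerance = 1e-12)
  # equal rates give zero either way
  expect_equal(dprime(40, 40, 40, 40), 0)
  expect_equal(dprime(40, 40, 10, 10), 0)
  # perfect hit rate stays finite under the correction
  expect_true(is.finite(dprime(160, 0, 10, 70)))
  expect_true(is.infinite(dprime(160, 0, 10, 70, correction = "none")))
  expect_error(dprime(0, 0, 10, 10), class = "retrocue_error_insufficient_data")
  expect_error(dprime(-1, 5, 5, 5), class = "retrocue_error_domain")
})

test_that("d-prime is antisymmetric and monotone in hits", {
  set.seed(71)
  for (i in 1:20) {
    k <- sample(1:50, 4, replace = TRUE)
    expect_equal(dprime(k[1], k[2], k[3], k[4]),
                 -dprime(k[3], k[4], k[1], k[2]), tolerance = 1e-12)
  }
  n <- 60
  d <- vapply(0:n, function(h) dprime(h, n - h, 15, 45), numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("the d-prime table composes cell hits with the pooled FA rate", {
  tr <- counted_cell_trials(1L, 150, "congruent", hits = 120, misses = 40,
                            fas = 20, crs = 60)
  tab <- dprime_table(tr)
  cell <- tab[tab$stratum == "cue", ]
  expect_equal(cell$dprime, dprime(120, 40, 20, 60))
  expect_equal(cell$hit_rate, 120 / 160)  # raw rate, no correction stored
  expect_equal(cell$fa_rate, 20 / 80)

  # all-no responses: correction keeps d-prime defined
  tr2 <- counted_cell_trials(1L, 150, "congruent", hits = 0, misses = 160,
                             fas = 0, crs = 80)
  expect_true(is.finite(dprime_table(tr2)$dprime[1]))
})

test_that("the d-prime table recovers generator truth at full scale", {
  cfg <- design_config(n_participants = 20, rng_seed = 31L)
  obs <- flat_observer(dprime = 1.2, criterion = 0.15)
  trials <- simulate_behavior(build_design(cfg), obs, seed = 31)
  trials <- assign_cells(exclude_fast_responses(trials)$trials)
  tab <- dprime_table(trials)
  expect_lt(abs(mean(tab$dprime) - 1.2), 0.1)
})

test_that("repeated-measures ANOVA matches a brute-force oracle", {
  # 3 participants x 2 x 2 hand table
  fx <- expand.grid(participant = 1:3, a = c("a1", "a2"), b = c("b1", "b2"),
                    stringsAsFactors = FALSE)
  fx$y <- c(4.1, 5.0, 6.2, 5.3, 6.1, 7.4, 3.9, 5.2, 6.0, 6.8, 7.9, 9.1)
  out <- rm_anova_2way(fx, dv = "y", factor_a = "a", factor_b = "b")

  # independent oracle: explicit sums of squares from cell means
  gm <- mean(fx$y)
  mean_of <- function(...) tapply(fx$y, list(...), mean)
  m_a <- mean_of(fx$a); m_b <- mean_of(fx$b); m_p <- mean_of(fx$participant)
  ss_a <- 3 * 2 * sum((m_a - gm)^2)
  ss_b <- 3 * 2 * sum((m_b - gm)^2)
  m_pa <- mean_of(fx$participant, fx$a)
  ss_as <- 0
  for (p in 1:3) for (a in c("a1", "a2")) {
    ss_as <- ss_as + 2 * (m_pa[as.character(p), a] - m_p[as.character(p)] -
                            m_a[a] + gm)^2
  }
  f_a_oracle <- unname((ss_a / 1) / (ss_as / 2))
  expect_equal(out$F[out$effect == "a"], f_a_oracle, tolerance = 1e-9)
  expect_equal(out$ss[out$effect == "a"], ss_a, tolerance = 1e-9)
  expect_equal(out$ss[out$effect == "b"], ss_b, tolerance = 1e-9)

  # cross-check all three F statistics against stats::aov error strata
  fx2 <- fx
  fx2$participant <- factor(fx2$participant)
  av <- summary(stats::aov(y ~ a * b + Error(participant / (a * b)), data = fx2))
  f_aov <- c(av[["Error: participant:a"]][[1]]["a", "F value"],
             av[["Error: participant:b"]][[1]]["b", "F value"],
             av[["Error: participant:a:b"]][[1]]["a:b", "F value"])
  expect_equal(out$F, unname(f_aov), tolerance = 1e-9)

  # sums of squares are additive
  ss <- attr(out, "ss")
  expect_equal(ss$ss_total,
               ss$ss_a + ss$ss_b + ss$ss_ab + ss$ss_s + ss$ss_as +
                 ss$ss_bs + ss$ss_abs, tolerance = 1e-9)
  # two-level factors: epsilon is exactly 1
  expect_equal(out$gg_epsilon, c(1, 1, 1))
  expect_true(all(out$gen_eta_sq >= 0 & out$gen_eta_sq <= 1))
})

test_that("ANOVA detects a shifted factor and respects the epsilon bounds", {
  set.seed(81)
  d <- expand.grid(participant = 1:12, a = c("x", "y", "z"),
                   b = c("u", "v"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + ifelse(d$a == "z", 3, 0)
  out <- rm_anova_2way(d, dv = "y", factor_a = "a", factor_b = "b")
  expect_gt(out$F[out$effect == "a"], 10)
  expect_lt(out$F[out$effect == "b"], 5)
  eps_a <- out$gg_epsilon[out$effect == "a"]
  expect_gt(eps_a, 1 / 2)  # lower bound 1/(k-1) for k = 3
  expect_lte(eps_a, 1)
  # corrected p uses shrunken dfs
  expect_equal(out$p_gg[1],
               pf(out$F[1], out$df_num[1] * eps_a, out$df_den[1] * eps_a,
                  lower.tail = FALSE))
  # F values agree with aov here too
  d$participant <- factor(d$participant)
  av <- summary(stats::aov(y ~ a * b + Error(participant / (a * b)), data = d))
  expect_equal(out$F[1], av[["Error: participant:a"]][[1]]["a", "F value"],
               tolerance = 1e-9)
  expect_error(rm_anova_2way(d[-1, ], dv = "y", factor_a = "a", factor_b = "b"),
               class = "retrocue_error_balance")
})

test_that("bootstrap CI collapses, narrows and stays seed-stable", {
  a <- c(1.5, 2.5, 3.5, 4.5); b <- a - 0.5
  ci <- bootstrap_mean_diff_ci(a, b, n_boot = 500, seed = 1)
  expect_equal(ci$lower, 0.5)
  expect_equal(ci$upper, 0.5)
  expect_equal(ci$mean_diff, 0.5)

  set.seed(5)
  x20 <- rnorm(20); y20 <- rnorm(20)
  x200 <- rnorm(200); y200 <- rnorm(200)
  w20 <- with(bootstrap_mean_diff_ci(x20, y20, n_boot = 2000, seed = 2),
              upper - lower)
  w200 <- with(bootstrap_mean_diff_ci(x200, y200, n_boot = 2000, seed = 2),
               upper - lower)
  expect_lt(w200, w20)

  expect_identical(bootstrap_mean_diff_ci(x20, y20, seed = 7),
                   bootstrap_mean_diff_ci(x20, y20, seed = 7))
  expect_error(bootstrap_mean_diff_ci(1, 2),
               class = "retrocue_error_insufficient_data")
  # Bonferroni adjustment widens the interval
  wide <- bootstrap_mean_diff_ci(x20, y20, n_boot = 2000, seed = 3,
                                 n_comparisons = 4)
  narrow <- bootstrap_mean_diff_ci(x20, y20, n_boot = 2000, seed = 3)
  expect_gte(wide$upper - wide$lower, narrow$upper - narrow$lower)
  expect_equal(wide$alpha_adjusted, 0.05 / 4)
})

test_that("bootstrap quantiles agree with full enumeration at tiny n", {
  d <- c(0.3, 1.1, 2.2, 4.0)
  # all 4^4 equally likely resample means
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  exact_means <- rowMeans(matrix(d[idx], nrow = nrow(idx)))
  ci <- bootstrap_mean_diff_ci(d + 1, rep(1, 4), n_boot = 20000, seed = 11)
  # implied coverage of the enumerated distribution at the CI endpoints
  expect_lt(abs(mean(exact_means <= ci$lower) - 0.025), 0.02)
  expect_lt(abs(mean(exact_means >= ci$upper) - 0.025), 0.02)
})

test_that("bootstrap CI has near-nominal false-positive rate under the null", {
  set.seed(17)
  n_rep <- 300
  hits <- 0
  for (i in 1:n_rep) {
    a <- rnorm(12); b <- rnorm(12)
    ci <- bootstrap_mean_diff_ci(a, b, n_boot = 600)
    if (ci$lower > 0 || ci$upper < 0) hits <- hits + 1
  }
  rate <- hits / n_rep
  # percentile bootstrap is slightly liberal at small n; allow a wide band
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.15)
})

test_that("a true d-prime boost is detected by the bootstrap contrast", {
  cfg <- design_config(n_participants = 20, rng_seed = 13L)
  cells <- default_observer_cells()
  cells$dprime <- 1.2
  cells$dprime[cells$soa_ms %in% -150] <- 1.7  # +0.5 at the short pre-cue
  obs <- observer_model(cells = cells, dprime_base = 1.2)
  trials <- simulate_behavior(build_design(cfg), obs, seed = 13)
  tab <- dprime_table(assign_cells(exclude_fast_responses(trials)$trials))
  cued <- tab[tab$stratum == "cue" & tab$soa_ms == -150, ]
  cued <- tapply(cued$dprime, cued$participant, mean)
  nocue <- tab$dprime[tab$stratum == "no_cue"][order(tab$participant[tab$stratum == "no_cue"])]
  ci <- bootstrap_mean_diff_ci(as.numeric(cued), as.numeric(nocue),
                               n_boot = 2000, n_comparisons = 4, seed = 14)
  expect_gt(ci$lower, 0)
})
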