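test_that("the density is a proper distribution with the stated moments", {
  expect_equal(dsw(0.3, 3, 1, 0.3), 0)
  expect_equal(dsw(0.3 + 1e-9, 3, 1, 0.3), 0, tolerance = 1e-12)
  total <- integrate(function(x) dsw(x, 3, 1, 0.3), 0.3, Inf,
                     rel.tol = 1e-10)$value
  expect_lt(abs(total - 1), 1e-8)
  m <- sw_moments(3, 1, 0.3)
  expect_equal(m[["mean"]], 0.3 + 1 / 3, tolerance = 1e-12)
  expect_equal(m[["sd"]], sqrt(1 / 27), tolerance = 1e-12)
  # theta is a pure location shift
  m2 <- sw_moments(3, 1, 0.5)
  expect_equal(m2[["mean"]] - m[["mean"]], 0.2)
  expect_equal(m2[["sd"]], m[["sd"]])
  expect_error(sw_params(-1, 1, 0), class = "retrocue_error_domain")
  expect_error(dsw(1, 3, 1, -0.1), class = "retrocue_error_domain")
})

test_that("moment identities hold against numerical integration", {
  set.seed(100)
  for (i in 1:20) {
    g <- runif(1, 1, 8); a <- runif(1, 0.3, 3); th <- runif(1, 0, 0.6)
    mu_num <- integrate(function(x) x * dsw(x, g, a, th), th, Inf,
                        rel.tol = 1e-11)$value
    m2_num <- integrate(function(x) x^2 * dsw(x, g, a, th), th, Inf,
                        rel.tol = 1e-11)$value
    m <- sw_moments(g, a, th)
    expect_equal(mu_num, m[["mean"]], tolerance = 1e-6)
    expect_equal(sqrt(m2_num - mu_num^2), m[["sd"]], tolerance = 1e-5)
  }
})

test_that("pdf, cdf and quantile functions are mutually consistent", {
  g <- 3; a <- 1; th <- 0.3
  expect_equal(psw(th, g, a, th), 0)
  expect_equal(psw(th - 1, g, a, th), 0)
  m <- sw_moments(g, a, th)
  expect_gt(psw(m[["mean"]] + 10 * m[["sd"]], g, a, th), 0.99)
  x <- c(0.35, 0.5, 0.7, 1.2, 2.5)
  expect_equal(qsw(psw(x, g, a, th), g, a, th), x, tolerance = 1e-8)
  p <- c(0.01, 0.1, 0.5, 0.9, 0.999)
  expect_equal(psw(qsw(p, g, a, th), g, a, th), p, tolerance = 1e-8)
  expect_true(all(diff(psw(seq(0.3, 3, by = 0.01), g, a, th)) >= 0))
  # cdf is the numerical integral of the pdf
  expect_equal(psw(0.8, g, a, th),
               integrate(function(x) dsw(x, g, a, th), th, 0.8,
                         rel.tol = 1e-11)$value, tolerance = 1e-8)
  expect_error(qsw(0, g, a, th), class = "retrocue_error_domain")
  expect_error(qsw(1, g, a, th), class = "retrocue_error_domain")
})

test_that("the density mode matches the closed-form inverse-Gaussian mode", {
  set.seed(55)
  for (i in 1:5) {
    g <- runif(1, 1.5, 6); a <- runif(1, 0.5, 2); th <- runif(1, 0, 0.5)
    mu <- a / g; lam <- a^2
    mode_cf <- th + mu * (sqrt(1 + 9 * mu^2 / (4 * lam^2)) - 3 * mu / (2 * lam))
    # grid-plus-refine argmax oracle on the implemented density
    grid <- seq(th + 1e-6, th + 5 * mu, length.out = 2000)
    g0 <- grid[which.max(dsw(grid, g, a, th))]
    opt <- optimize(function(x) dsw(x, g, a, th),
                    interval = c(g0 - 0.01, g0 + 0.01), maximum = TRUE,
                    tol = 1e-10)
    expect_equal(opt$maximum, mode_cf, tolerance = 1e-5)
  }
})

test_that("exact sampling reproduces the distribution deterministically", {
  x <- rsw(1e5, 3, 1, 0.3, seed = 7)
  expect_true(all(x > 0.3))
  m <- sw_moments(3, 1, 0.3)
  expect_lt(abs(mean(x) - m[["mean"]]) / m[["mean"]], 0.02)
  expect_lt(abs(sd(x) - m[["sd"]]) / m[["sd"]], 0.02)
  expect_identical(rsw(100, 3, 1, 0.3, seed = 9), rsw(100, 3, 1, 0.3, seed = 9))
  # sample median agrees with the analytic quantile
  expect_lt(abs(median(x) - qsw(0.5, 3, 1, 0.3)) / qsw(0.5, 3, 1, 0.3), 0.01)
})

test_that("Euler first-passage simulation approaches the analytic law", {
  # deterministic drift limit: rt concentrates at theta + alpha/gamma
  fast <- simulate_diffusion(100, 1, 0.2, n = 500, dt = 1e-5, seed = 3)
  expect_lt(abs(mean(fast) - (0.2 + 0.01)), 0.003)
  expect_equal(attr(fast, "n_flagged"), 0)

  rt <- simulate_diffusion(3, 1, 0.3, n = 2000, dt = 1e-3, seed = 4)
  ks <- max(abs(ecdf(rt)(rt) - psw(rt, 3, 1, 0.3)))
  expect_lt(ks, 0.06)
  # a too-small step bound flags unfinished walks instead of hanging
  capped <- simulate_diffusion(3, 1, 0.3, n = 50, dt = 1e-3, seed = 5,
                               max_steps = 10)
  expect_gt(attr(capped, "n_flagged"), 0)
  expect_true(anyNA(capped))
})

test_that("profile MLE recovers parameters and satisfies its contracts", {
  rts <- rsw(5000, 3, 1, 0.3, seed = 12)
  fit <- fit_sw_mle(rts)
  expect_lt(abs(fit$gamma - 3) / 3, 0.1)
  expect_lt(abs(fit$alpha - 1) / 1, 0.1)
  expect_lt(abs(fit$theta - 0.3) / 0.3, 0.1)
  expect_lt(fit$theta, min(rts))
  expect_true(fit$converged)
  # reported log-likelihood is self-consistent with the density
  expect_equal(fit$loglik,
               sum(dsw(rts, fit$gamma, fit$alpha, fit$theta, log = TRUE)),
               tolerance = 1e-9)
  # optimality spot-check against random feasible triples
  set.seed(13)
  for (i in 1:100) {
    g <- runif(1, 0.5, 10); a <- runif(1, 0.1, 5)
    th <- runif(1, 0, min(rts) - 1e-4)
    expect_gte(fit$loglik, sum(dsw(rts, g, a, th, log = TRUE)))
  }
  expect_error(fit_sw_mle(rts[1:10]),
               class = "retrocue_error_insufficient_data")
  expect_error(fit_sw_mle(rep(0.5, 30)), class = "retrocue_error_domain")
})

test_that("the fit is location-equivariant and consistent in n", {
  rts <- rsw(500, 3, 1, 0.3, seed = 21)
  f0 <- fit_sw_mle(rts)
  f1 <- fit_sw_mle(rts + 0.25)
  expect_equal(f1$theta, f0$theta + 0.25, tolerance = 1e-6)
  expect_equal(f1$gamma, f0$gamma, tolerance = 1e-4)
  expect_equal(f1$alpha, f0$alpha, tolerance = 1e-4)

  rel_err <- function(n, seed) {
    f <- fit_sw_mle(rsw(n, 3, 1, 0.3, seed = seed))
    max(abs(c(f$gamma - 3, f$alpha - 1, f$theta - 0.3)) / c(3, 1, 0.3))
  }
  small <- vapply(1:12, function(s) rel_err(100, s), numeric(1))
  large <- vapply(1:12, function(s) rel_err(3000, 100 + s), numeric(1))
  expect_lt(median(large), median(small))
})

test_that("the quantile-discrepancy objective agrees with the MLE route", {
  rts <- rsw(3000, 3, 1, 0.3, seed = 33)
  f_ml <- fit_sw_mle(rts)
  f_q <- fit_sw_mle(rts, objective = "quantile")
  expect_lt(abs(f_ml$theta - f_q$theta), 0.05)
  expect_lt(abs(f_ml$gamma - f_q$gamma) / f_ml$gamma, 0.1)
})

test_that("per-cell fitting covers the short-SOA cells and skips small ones", {
  cfg <- medium_config()
  trials <- simulate_behavior(build_design(cfg), observer_model(), seed = 41)
  trials <- assign_cells(exclude_fast_responses(trials)$trials)
  fits <- fit_all_cells(trials)
  expect_equal(nrow(fits), 4 * 2 * 2)  # participants x SOA x congruency
  expect_true(all(!fits$skipped))
  one <- fit_all_cells(trials[trials$participant == 1, ])
  expect_equal(nrow(one), 4)
  # theta always below the smallest RT in its cell
  hits <- kept_trials(trials)
  for (i in seq_len(nrow(fits))) {
    cell_min <- min(hits$rt_ms[hits$participant == fits$participant[i] &
                                 !is.na(hits$soa_ms) &
                                 hits$soa_ms == fits$soa_ms[i] &
                                 !is.na(hits$congruency) &
                                 hits$congruency == fits$congruency[i] &
                                 hits$response == "yes" & hits$target_present])
    expect_lt(fits$theta[i], ms_to_s(cell_min))
  }
  skipped <- fit_all_cells(trials, min_n = 1000)
  expect_true(all(skipped$skipped))
  gp <- group_sw_params(fits)
  expect_equal(nrow(gp), 4)
})
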