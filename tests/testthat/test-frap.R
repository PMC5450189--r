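test_that("noiseless traces recover (A, B, C) to 1e-6 relative", {
  sim <- simulate_frap_trace(frap_sim_spec(A = 100, B = -80, C = 0.2))
  fit <- fit_recovery(sim$trace)
  expect_true(fit$converged)
  expect_equal(fit$A, 100, tolerance = 1e-6)
  expect_equal(fit$B, -80, tolerance = 1e-6)
  expect_equal(fit$C, 0.2, tolerance = 1e-6)
  expect_equal(fit$half_time_s, log(2) / 0.2, tolerance = 1e-6)
})

test_that("constant post-bleach traces are flagged unidentifiable", {
  sim <- simulate_frap_trace(frap_sim_spec(A = 60, B = 0, C = 0.2))
  fit <- fit_recovery(sim$trace)
  expect_false(fit$converged)
  expect_true(is.na(fit$C))
})

test_that("trace validation enforces pre/post structure", {
  expect_error(frap_trace("t", 1:10, rep(5, 10), bleach_time_s = 0),
               "no pre-bleach")
  expect_error(frap_trace("t", 0:4, rep(5, 5), bleach_time_s = 2),
               "4 post-bleach")
})

test_that("least-squares fits beat a 50^3 grid search on noisy traces", {
  # grid RSS evaluated exactly through sufficient statistics:
  # rss(A,B,C) = Syy + n A^2 + B^2 See - 2 A Sy - 2 B Sye + 2 A B Se
  grid_best_rss <- function(t, y) {
    n <- length(y)
    Syy <- sum(y * y); Sy <- sum(y)
    As <- seq(min(y), max(y) + 0.25 * diff(range(y)), length.out = 50)
    Bs <- seq(-1.5 * diff(range(y)), 0, length.out = 50)
    Cs <- exp(seq(log(0.01), log(2), length.out = 50))
    best <- Inf
    for (C in Cs) {
      e <- exp(-C * t)
      See <- sum(e * e); Se <- sum(e); Sye <- sum(y * e)
      rss <- outer(As, Bs, function(A, B) {
        Syy + n * A^2 + B^2 * See - 2 * A * Sy - 2 * B * Sye + 2 * A * B * Se
      })
      best <- min(best, min(rss))
    }
    best
  }
  wins <- vapply(1:200, function(s) {
    sim <- simulate_frap_trace(frap_sim_spec(A = 100, B = -80, C = 0.25,
                                             noise_sd = 4), seed = s)
    fit <- fit_recovery(sim$trace)
    oracle <- grid_best_rss(fit$times_post_s, fit$intensities_post)
    fit$rss <= oracle + 1e-9
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("rate recovery stays within 5% median error under 5% noise", {
  for (C_true in c(0.1, 0.25, 0.5)) {
    errs <- vapply(1:60, function(s) {
      sim <- simulate_frap_trace(
        frap_sim_spec(A = 100, B = -80, C = C_true, noise_sd = 4,
                      times_s = seq(-4, 30, by = 0.2)),
        seed = 7000 + s)
      fit <- fit_recovery(sim$trace)
      abs(fit$C - C_true) / C_true
    }, numeric(1))
    expect_lt(stats::median(errs), 0.05)
  }
})

test_that("immobile fraction interpolates between full and no recovery", {
  mk_fit <- function(A) structure(list(A = A), class = "frap_fit")
  tr <- frap_trace("t", c(-2, -1, 0, 1, 2, 3, 4),
                   c(100, 100, 20, 30, 40, 45, 50), bleach_time_s = 0)
  expect_equal(immobile_fraction(mk_fit(100), tr)$raw, 0) # full recovery
  expect_equal(immobile_fraction(mk_fit(20), tr)$raw, 1)  # no recovery
  expect_equal(immobile_fraction(mk_fit(60), tr)$raw, 0.5)
  # clipping retains the raw value
  over <- immobile_fraction(mk_fit(110), tr)
  expect_lt(over$raw, 0)
  expect_identical(over$clipped, 0)

  bad <- frap_trace("t", c(-1, 0, 1, 2, 3), c(10, 50, 50, 50, 50),
                    bleach_time_s = 0)
  expect_error(immobile_fraction(mk_fit(50), bad), "bleach failure")
})

test_that("immobile fraction is invariant to affine intensity rescaling", {
  sim <- simulate_frap_trace(frap_sim_spec(A = 70, B = -50, C = 0.3,
                                           noise_sd = 2), seed = 5)
  tr <- sim$trace
  fit <- fit_recovery(tr)
  base <- immobile_fraction(fit, tr)$raw
  for (gain_offset in list(c(2, 0), c(0.5, 10), c(3, 25))) {
    g <- gain_offset[1]; o <- gain_offset[2]
    tr2 <- frap_trace(tr$trace_id, tr$times_s, g * tr$intensities + o,
                      bleach_time_s = 0)
    fit2 <- fit_recovery(tr2)
    expect_equal(immobile_fraction(fit2, tr2)$raw, base, tolerance = 1e-6)
  }
})

test_that("half-time summaries use the exact geometric-mean pipeline", {
  v <- c(2, 2, 2, 2)
  gs <- summarize_half_times(v)
  expect_equal(gs$geometric_mean_half_time_s, 2)
  expect_equal(gs$ci95_low, 2)
  expect_equal(gs$ci95_high, 2)

  gs2 <- summarize_half_times(c(1, 10, 1, 10))
  expect_equal(gs2$geometric_mean_half_time_s, sqrt(10), tolerance = 1e-12)

  # exp(mean(log(x))) identity on random data
  set.seed(12)
  x <- stats::rlnorm(20, 1, 0.4)
  expect_equal(summarize_half_times(x)$geometric_mean_half_time_s,
               exp(mean(log(x))), tolerance = 1e-12)
  # CI formula against a hand computation
  gs3 <- summarize_half_times(x)
  hw <- stats::qt(0.975, 19) * stats::sd(log(x)) / sqrt(20)
  expect_equal(gs3$ci95_low, exp(mean(log(x)) - hw))
  expect_equal(gs3$ci95_high, exp(mean(log(x)) + hw))
  expect_true(gs3$ci95_low <= gs3$geometric_mean_half_time_s &&
                gs3$geometric_mean_half_time_s <= gs3$ci95_high)

  expect_error(summarize_half_times(c(1, -1, 2)), "positive")
  expect_error(summarize_half_times(c(1, 2)), "at least 3")
})

test_that("group comparisons match t distributions and a permutation oracle", {
  a <- c(1, 2, 3, 4)
  same <- compare_groups(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)

  sep <- compare_groups(c(0, 0, 0, 0), c(1, 1, 1, 1) + 1e-9 * (1:4))
  expect_lt(sep$p_value, 1e-6)

  # constant equal groups: p = 1 by convention
  const <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$p_value, 1)

  # permutation oracle: pooled-variance t on exchangeable data
  set.seed(31)
  x <- stats::rnorm(8, 0, 1)
  y <- stats::rnorm(8, 0.8, 1)
  res <- compare_groups(x, y, mode = "student")
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  P <- 1e4
  perm <- vapply(1:P, function(i) {
    idx <- sample(16, 8)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  }, numeric(1))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_perm - res$p_value), 0.04)

  # Welch uses Satterthwaite df: fractional for unequal variances
  w <- compare_groups(c(1, 2, 3, 4), c(10, 30, 50, 70, 90), mode = "welch")
  expect_false(w$df == round(w$df) && w$df == 7)
})
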