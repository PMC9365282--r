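test_that("linear detrending removes exactly the fitted line", {
  # values orthogonal to (1, t): detrending is the identity
  t <- 1:5
  v <- c(1, -2, 0, 2, -1)
  tr <- new_trace(t, v)
  expect_equal(detrend_trace(tr)$values, v, tolerance = 1e-9)

  # a pure line is removed exactly
  tr2 <- new_trace(0:20, 2 + 3 * (0:20))
  expect_equal(detrend_trace(tr2)$values, rep(0, 21), tolerance = 1e-9)

  # cosine + line: subtracting the closed-form OLS projection recovers the
  # oscillation (projection coefficients computed independently here)
  tt <- seq(0, 71, by = 1)
  osc <- cos(2 * pi * tt / 24)
  slope <- sum((tt - mean(tt)) * osc) / sum((tt - mean(tt))^2)
  icept <- mean(osc) - slope * mean(tt)
  osc_perp <- osc - (icept + slope * tt)
  tr3 <- new_trace(tt, osc_perp + (5 - 0.3 * tt))
  expect_equal(detrend_trace(tr3)$values, osc_perp, tolerance = 1e-6)

  expect_error(detrend_trace(new_trace(1:5, 1:5), method = "spline"),
               "unknown detrend method")
})

test_that("moving-average detrending centers a slow baseline", {
  tt <- seq(0, 96, by = 1)
  tr <- new_trace(tt, 10 + 0.5 * tt + 2 * cos(2 * pi * tt / 24))
  out <- detrend_trace(tr, method = "movavg")
  # interior points lose the drift; oscillation amplitude preserved roughly
  mid <- tt >= 24 & tt <= 72
  expect_lt(abs(mean(out$values[mid])), 0.3)
  expect_gt(max(out$values[mid]), 1.5)
})

test_that("Kendall exact null matches full enumeration", {
  # n = 4: enumerate all 24 permutations against a fixed reference
  perms <- all_perms(4)
  S_all <- apply(perms, 1, function(p) kendall_S_oracle(p, 1:4))
  for (s_obs in unique(abs(S_all))) {
    expect_equal(kendall_exact_pvalue(4, s_obs),
                 mean(abs(S_all) >= s_obs), tolerance = 1e-12)
  }
  # printed anchors
  expect_equal(kendall_exact_pvalue(4, 6), 2 / 24, tolerance = 1e-12)
  expect_identical(kendall_exact_pvalue(4, 0), 1)
  expect_error(kendall_exact_pvalue(4, 8), "exceeds")
})

test_that("Kendall exact null matches a sampled-permutation oracle at n = 10", {
  withr::with_seed(11, {
    x <- sample(10)
    S_obs <- kendall_S_oracle(x, 1:10)
    S_null <- vapply(1:20000, function(i) {
      kendall_S_oracle(sample(10), 1:10)
    }, numeric(1))
    p_mc <- mean(abs(S_null) >= abs(S_obs))
    p_exact <- kendall_exact_pvalue(10, S_obs)
    se <- sqrt(p_exact * (1 - p_exact) / 20000)
    expect_lt(abs(p_mc - p_exact), 4 * se + 1e-6)
  })
})

test_that("jtk_cycle detects a clean cosine and ignores ties and monotone rescaling", {
  # constant trace: every pair tied, no rhythm detectable
  flat <- new_trace(0:23, rep(1, 24))
  jf <- jtk_cycle(flat)
  expect_identical(jf$p_value, 1)
  expect_identical(jf$tau, 0)

  # noiseless 24 h cosine, dt = 2 h over 48 h
  tt <- seq(0, 48, by = 2)
  tr <- new_trace(tt, cos(2 * pi * tt / 24))
  j <- jtk_cycle(tr)
  expect_lt(j$p_value, 1e-4)
  expect_lte(min(j$best_phase_h, 24 - j$best_phase_h), 2)
  expect_equal(j$best_period_h, 24)

  # rank-based: invariant under strictly monotone transforms
  tr_noisy <- new_trace(tt, cos(2 * pi * tt / 24) + 0.3 * sin(7 * tt))
  j1 <- jtk_cycle(tr_noisy)
  j2 <- jtk_cycle(new_trace(tt, exp(2 * tr_noisy$values)))
  expect_identical(j1$p_value, j2$p_value)
  expect_identical(j1$S, j2$S)
})

test_that("fft_nlls_fit recovers parameters and agrees with a grid-search oracle", {
  tt <- 0:72
  tr <- new_trace(tt, 3 * cos(2 * pi * tt / 24))
  f <- fft_nlls_fit(tr)
  expect_true(f$period_h > 23.9 && f$period_h < 24.1)
  expect_true(f$amplitude > 2.97 && f$amplitude < 3.03)
  expect_lt(f$rae, 0.01)

  # grid-search oracle: linear LS of cos/sin components on a period grid
  tr2 <- new_trace(tt, 2.5 * cos(2 * pi * (tt - 5) / 26.5) + 0.3)
  rss_grid <- vapply(seq(20, 32, by = 0.05), function(Tg) {
    X <- cbind(1, cos(2 * pi * tt / Tg), sin(2 * pi * tt / Tg))
    sum(stats::lm.fit(X, tr2$values)$residuals^2)
  }, numeric(1))
  T_oracle <- seq(20, 32, by = 0.05)[which.min(rss_grid)]
  f2 <- fft_nlls_fit(tr2)
  expect_lt(abs(f2$period_h - T_oracle), 0.05)
  expect_lt(abs(f2$period_h - 26.5), 0.05)

  # no Fourier component in band (12 h record: candidate periods 12/k):
  # flagged unusable
  fast <- new_trace(0:11, cos(2 * pi * (0:11) / 4))
  expect_identical(fft_nlls_fit(fast)$period_h, 0)
})

test_that("fft_nlls_fit is accurate under damping and noise, and rae flags pure noise", {
  hits <- 0
  for (s in 1:50) {
    tr <- split_traces(generate_traces(trace_config(
      n_samples = 1, amplitude = 3, damping_per_h = 0.01, noise_sd = 0.3,
      seed = s)))[[1]]
    f <- fft_nlls_fit(detrend_trace(tr))
    hits <- hits + (abs(f$period_h - 24) <= 0.5)
  }
  expect_gte(hits, 48)   # >= 95% of seeds

  noisy_rae <- vapply(1:50, function(s) {
    tr <- split_traces(generate_traces(trace_config(
      n_samples = 1, condition = "arrhythmic", noise_sd = 1, baseline = 0,
      trend_per_h = 0, seed = 1000 + s)))[[1]]
    fft_nlls_fit(detrend_trace(tr))$rae
  }, numeric(1))
  expect_gte(mean(noisy_rae > 0.5), 0.9)
})

test_that("rhythm classification applies the printed thresholds strictly", {
  mk_jtk <- function(p) structure(list(p_value = p, best_phase_h = 0,
                                       best_period_h = 24, tau = 0.5,
                                       S = 100, n_alternatives = 24),
                                  class = "jtk_result")
  mk_fit <- function(T_h) structure(list(period_h = T_h, amplitude = 2,
                                         damping_per_h = 0, phase_h = 0,
                                         rae = 0.1, rss = 1),
                                    class = "rhythm_fit")
  expect_true(classify_rhythm(mk_jtk(5e-4), mk_fit(24.3))$rhythmic)
  c1 <- classify_rhythm(mk_jtk(5e-4), mk_fit(21))
  expect_false(c1$rhythmic); expect_identical(c1$reason, "period_short")
  c2 <- classify_rhythm(mk_jtk(0.002), mk_fit(24))
  expect_false(c2$rhythmic); expect_identical(c2$reason, "p_above_threshold")
  # boundaries: P threshold strict; period gate inclusive at 22 and 30
  expect_false(classify_rhythm(mk_jtk(0.001), mk_fit(24))$rhythmic)
  expect_true(classify_rhythm(mk_jtk(5e-4), mk_fit(22))$rhythmic)
  expect_true(classify_rhythm(mk_jtk(5e-4), mk_fit(30))$rhythmic)
  expect_identical(classify_rhythm(mk_jtk(5e-4), mk_fit(30.001))$reason,
                   "period_long")
  expect_identical(classify_rhythm(mk_jtk(5e-4), mk_fit(21.999))$reason,
                   "period_short")
  # NR calls carry no period/amplitude
  expect_true(is.na(c2$period_h) && is.na(c2$amplitude))
})

test_that("amplitude ratios normalize tumor to matched normal", {
  mk_fit <- function(A, T_h = 24) structure(
    list(period_h = T_h, amplitude = A, damping_per_h = 0, phase_h = 0,
         rae = 0.1, rss = 1), class = "rhythm_fit")
  mk_call <- function(r) structure(list(rhythmic = r, reason = "ok",
                                        p_value = 1e-4, period_h = 24,
                                        amplitude = 1),
                                   class = "rhythm_call")
  fits <- list(n1 = mk_fit(4), t1 = mk_fit(1), n2 = mk_fit(2),
               t2 = mk_fit(2), t3 = mk_fit(1))
  calls <- list(n1 = mk_call(TRUE), t1 = mk_call(TRUE),
                n2 = mk_call(TRUE), t2 = mk_call(FALSE),
                t3 = mk_call(TRUE))
  pairing <- data.frame(patient_id = c("p1", "p2", "p3"),
                        normal_sample = c("n1", "n2", "n3"),
                        tumor_sample = c("t1", "t2", "t3"))
  expect_warning(out <- amplitude_ratio(fits, calls, pairing),
                 "no normal partner")
  expect_equal(out$ratio, c(0.25, 1))
  expect_identical(out$tumor_nr, c(FALSE, TRUE))
})

test_that("damped tumor pairs all show attenuated amplitude ratios", {
  mk <- function(condition, A, seed) generate_traces(trace_config(
    n_samples = 7, amplitude = A, noise_sd = 0.2, condition = condition,
    seed = seed))
  res_n <- rhythm_pipeline(mk("normal", 3, 21))
  res_t <- rhythm_pipeline(mk("tumor", 0.6, 22))
  fits <- c(res_n$fits, res_t$fits)
  calls <- c(res_n$calls, res_t$calls)
  pairing <- data.frame(patient_id = sprintf("PT%03d", 1:7),
                        normal_sample = sprintf("normal_%02d", 1:7),
                        tumor_sample = sprintf("tumor_%02d", 1:7))
  ratios <- amplitude_ratio(fits, calls, pairing)
  expect_identical(nrow(ratios), 7L)
  expect_true(all(ratios$ratio < 1))
})

test_that("signed-rank test matches exact enumeration, base R, and its anchors", {
  # anchors
  expect_identical(wilcoxon_signed_rank(rep(1, 7))$p_value, 1)
  expect_equal(wilcoxon_signed_rank(c(.2, .3, .4, .5, .6, .7, .8))$p_value,
               2 / 128, tolerance = 1e-12)
  expect_identical(wilcoxon_signed_rank(c(0.5, 1.5, 0.8, 1.2))$p_value, 1)

  # random cases incl. ties vs the 2^n enumeration oracle
  withr::with_seed(8, {
    for (rep in 1:5) {
      x <- round(1 + c(rnorm(7, 0, 0.4), 0.2), 1)
      expect_equal(wilcoxon_signed_rank(x)$p_value,
                   wilcoxon_exact_oracle(x - 1), tolerance = 1e-10)
    }
  })
  # no-ties case agrees with stats::wilcox.test exact
  x <- 1 + c(-0.31, 0.47, -0.22, 0.11, 0.64, -0.83, 0.05, 0.29)
  expect_equal(wilcoxon_signed_rank(x)$p_value,
               stats::wilcox.test(x, mu = 1, exact = TRUE)$p.value,
               tolerance = 1e-12)
})
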