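test_that("d-prime matches the normal-quantile closed form", {
  expect_equal(dprime(0.5, 0.5, 100, 100), 0)
  expect_equal(dprime(0.84, 0.5, 1e6, 1e6),
               qnorm(0.84) - qnorm(0.5), tolerance = 1e-9)
  expect_equal(dprime(0.84, 0.5, 1e6, 1e6), 0.9944579, tolerance = 1e-6)
  # monotone increasing in hit rate at fixed false-alarm rate
  hs <- seq(0.2, 0.95, by = 0.05)
  ds <- vapply(hs, dprime, numeric(1), fa_rate = 0.3, n_hit = 200, n_fa = 200)
  expect_true(all(diff(ds) > 0))
  # clipping keeps extreme rates finite
  expect_true(is.finite(dprime(1, 0, 20, 20)))
  expect_error(dprime(0.5, 0.5, 0, 10), "positive")
})

test_that("psychometric threshold is recovered within 5% at n = 2000", {
  tr <- simulateDetectionBehavior(n_trials = 2000, seed = 111)
  fit <- fitPsychometric(tr[!tr$deviant_present, , drop = FALSE])
  expect_true(fit@converged)
  expect_lt(abs(fit@mu - 15) / 15, 0.05)
  # rescaling amplitudes by k rescales the threshold by k
  tr2 <- tr
  tr2$amplitude <- tr2$amplitude * 2.5
  fit2 <- fitPsychometric(tr2[!tr2$deviant_present, , drop = FALSE])
  expect_lt(abs(fit2@mu - 2.5 * fit@mu) / (2.5 * fit@mu), 0.02)
})

test_that("degenerate psychometric data are flagged non-identifiable", {
  allhit <- data.frame(amplitude = runif(300, 10, 20), response = "hit")
  expect_false(fitPsychometric(allhit)@converged)
  few <- data.frame(amplitude = rep(c(10, 20), 80),
                    response = rep(c("miss", "hit"), 80))
  expect_false(fitPsychometric(few)@converged)  # < 4 amplitude levels
})

test_that("trial filters implement the documented exclusion rules", {
  tr <- data.frame(
    amplitude = c(10, 12, 14, 16, 18),
    deviant_present = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    deviant_time_ms = c(NA, 300, 500, NA, NA),
    response = c("hit", "hit", "miss", "hit", "miss"),
    reaction_time_ms = c(30, 250, NA, 400, NA),
    d_prime = c(2, 2, 2, 0.9, 2))
  out <- filterTrials(tr)
  expect_equal(unname(out$audit),
               c(1L, 1L, 1L))  # d' 0.9, RT 30 ms, deviant at 500 ms
  expect_equal(nrow(out$trials), 2L)
  # no rules -> identity
  out0 <- filterTrials(tr, rules = character(0))
  expect_identical(out0$trials, tr)
  expect_error(filterTrials(tr, rules = "bogus"), "unknown rule")
})

test_that("Clopper-Pearson bounds are exact at the edges and cover >= 95%", {
  expect_equal(unname(hitRateCi(0, 20)[1]), 0)
  expect_equal(unname(hitRateCi(20, 20)[2]), 1)
  ci <- hitRateCi(30, 100)
  expect_lt(ci[1], 0.3); expect_gt(ci[2], 0.3)
  expect_error(hitRateCi(3, 0), "positive")
  # coverage simulation at p = 0.3, n = 50
  set.seed(112)
  k <- rbinom(10000, 50, 0.3)
  lo <- ifelse(k == 0, 0, qbeta(0.025, k, 50 - k + 1))
  hi <- ifelse(k == 50, 1, qbeta(0.975, k + 1, 50 - k))
  expect_gte(mean(lo <= 0.3 & 0.3 <= hi), 0.95)
})

test_that("bootstrap rate comparison is symmetric, null-safe and powerful", {
  expect_gt(compareRatesBootstrap(50, 100, 50, 100, seed = 113), 0.9)
  p_ab <- compareRatesBootstrap(80, 100, 50, 100, seed = 114)
  p_ba <- compareRatesBootstrap(50, 100, 80, 100, seed = 114)
  expect_lt(p_ab, 0.01)
  expect_lt(p_ba, 0.01)
  # agreement with an exact test on rejection at this effect size
  expect_lt(stats::fisher.test(matrix(c(80, 20, 50, 50), 2))$p.value, 0.01)
})

test_that("the deviant-benefit pipeline detects a planted benefit and not its absence", {
  db <- deviantBenefit(simulateDetectionBehavior(n_trials = 3000, seed = 115),
                       n_boot = 4000, seed = 116)
  expect_lt(db$p, 0.05)
  expect_gt(db$uplift, 0.05)
  null_tr <- simulateDetectionBehavior(
    psych = list(mu = 15, sigma = 4, guess = 0.08, lapse = 0.02,
                 deviant_benefit = 0),
    n_trials = 3000, seed = 117)
  db0 <- deviantBenefit(null_tr, n_boot = 4000, seed = 118)
  expect_gt(db0$p, 0.05)
})
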