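# Fixture with equal increase/decrease position histograms so matching is the
# identity and a brute-force oracle can be written independently.
balanced_tensor <- function(n_units = 6L, per_sign = 30L, seed = 71L) {
  ct <- simulateCountPopulation(n_units, c_planted = 0.1,
                                n_increase = per_sign, n_decrease = per_sign,
                                n_baseline = 2L * per_sign, positions = 3L,
                                seed = seed)
  ct
}

test_that("change coefficient equals a brute-force per-trial tabulation", {
  ct <- balanced_tensor()
  cc <- coefficientTable(changeCoefficient(ct, seed = 1))
  ti <- ct@train_info
  cnt <- counts(ct)
  # independent double loop: mean deviant-deflection count per sign
  for (u in seq_len(nrow(cc))) {
    inc <- dec <- c()
    for (i in seq_len(nrow(ti))) {
      if (ti$deviant_sign[i] == 1L)
        inc <- c(inc, cnt[u, i, ti$deviant_index[i] + 1L])
      if (ti$deviant_sign[i] == -1L)
        dec <- c(dec, cnt[u, i, ti$deviant_index[i] + 1L])
    }
    expect_equal(cc$coeff[u], mean(inc) - mean(dec))
  }
})

test_that("simple arithmetic cases are exact", {
  # increase counts {1,2,3}, decrease {1,1,1} -> coefficient 1.0
  cnt <- array(0L, dim = c(1, 6, 7))
  cnt[1, 1:3, 4] <- c(1L, 2L, 3L)
  cnt[1, 4:6, 4] <- 1L
  ti <- data.frame(train_id = sprintf("t%d", 1:6),
                   deviant_index = 3L,
                   deviant_sign = c(1L, 1L, 1L, -1L, -1L, -1L),
                   opto_condition = "control", baseline_amplitude = 25,
                   deviant_amplitude = 25)
  ct <- new("CountTensor", counts = cnt, window_ms = 100,
            excluded = matrix(FALSE, 6, 7), train_info = ti)
  dimnames(ct@counts) <- list("u1", ti$train_id, NULL)
  cc <- coefficientTable(changeCoefficient(ct))
  expect_equal(cc$coeff, 1.0)
  expect_error(changeCoefficient(ct, condition = "weak_laser"), "both signs")
})

test_that("negating deviant signs negates coefficients and preserves spread stats", {
  ct <- balanced_tensor(seed = 72L)
  cc1 <- coefficientTable(changeCoefficient(ct, seed = 5))
  ct2 <- ct
  ct2@train_info$deviant_sign <- -ct@train_info$deviant_sign
  cc2 <- coefficientTable(changeCoefficient(ct2, seed = 5))
  expect_equal(cc2$coeff, -cc1$coeff)

  cfg <- readConfig()
  s1 <- surrogatePopulation(ct, n_draws = 100, seed = 6)
  s2 <- surrogatePopulation(ct2, n_draws = 100, seed = 6)
  b1 <- broadeningTest(changeCoefficient(ct, seed = 5), s1, cfg,
                       min_units = 5, seed = 7)
  b2 <- broadeningTest(changeCoefficient(ct2, seed = 5), s2, cfg,
                       min_units = 5, seed = 7)
  expect_equal(b1@iqr_obs, b2@iqr_obs)
  expect_equal(b1@delta_H, b2@delta_H, tolerance = 1e-12)
})

test_that("surrogate populations are centered, deterministic, and variance-monotone", {
  ct <- simulateCountPopulation(8, c_planted = 0, seed = 73)
  s1 <- surrogatePopulation(ct, n_draws = 300, seed = 9)
  expect_equal(dim(surrogateDraws(s1)), c(300L, 8L))
  expect_lt(abs(mean(surrogateDraws(s1))), 0.005)
  s2 <- surrogatePopulation(ct, n_draws = 300, seed = 9)
  expect_identical(surrogateDraws(s1), surrogateDraws(s2))

  # higher per-count variance (higher rate) -> wider surrogate IQR
  ct_hi <- simulateCountPopulation(8, c_planted = 0, base_rate = 8, seed = 73)
  s_hi <- surrogatePopulation(ct_hi, n_draws = 300, seed = 9)
  iqr_of <- function(s) median(apply(surrogateDraws(s), 1, stats::IQR))
  expect_gt(iqr_of(s_hi), iqr_of(s1))
})

test_that("entropy helper matches the closed form", {
  expect_equal(shannonEntropy(rep(5, 8)), 3)
  expect_equal(shannonEntropy(c(10, 0, 0)), 0)
  expect_equal(shannonEntropy(c(1, 1)), 1)
  expect_error(shannonEntropy(c(0, 0)))
})

test_that("broadening test flags a planted two-signed population and the floor works", {
  ct <- simulateCountPopulation(60, c_planted = rep(c(0.08, -0.08), 30),
                                seed = 74)
  obs <- changeCoefficient(ct, seed = 10)
  surr <- surrogatePopulation(ct, n_draws = 300, seed = 11)
  bs <- broadeningTest(obs, surr, seed = 12)
  expect_gt(bs@iqr_obs, bs@iqr_surr)
  expect_lt(bs@p_iqr, 0.05)
  expect_lt(bs@p_entropy, 0.05)
  expect_gt(bs@p_median_shift, 0.05)
  expect_error(broadeningTest(obs, surr, min_units = 100), "units")
})

test_that("entropy-difference sign is stable across bin counts on planted heterogeneity", {
  ct <- simulateCountPopulation(60, c_planted = rep(c(0.08, -0.08), 30),
                                seed = 75)
  obs <- changeCoefficient(ct, seed = 13)
  surr <- surrogatePopulation(ct, n_draws = 200, seed = 14)
  signs <- vapply(c(10L, 15L, 20L, 30L), function(nb) {
    cfg <- readConfig()
    cfg$entropy_bins <- nb
    sign(broadeningTest(obs, surr, cfg, seed = 15)@delta_H)
  }, numeric(1))
  expect_true(all(signs == 1))
})

test_that("grouped deviant effect cancels for symmetric coding and detects uniform shifts", {
  ct <- simulateCountPopulation(40, c_planted = rep(c(0.08, -0.08), 20),
                                seed = 76)
  g <- groupedDeviantEffect(ct, seed = 16)
  expect_gt(g$p_signed_rank, 0.05)
  expect_lte(g$ci_median[1], 0)
  expect_gte(g$ci_median[3], 0)

  # add a uniform +0.2 spikes/deflection to every deviant deflection
  ct2 <- simulateCountPopulation(40, c_planted = 0, seed = 77)
  ti <- ct2@train_info
  set.seed(78)
  for (i in which(ti$deviant_sign != 0L)) {
    j <- ti$deviant_index[i] + 1L
    ct2@counts[, i, j] <- ct2@counts[, i, j] +
      rpois(dim(ct2@counts)[1], 0.2)
  }
  g2 <- groupedDeviantEffect(ct2, seed = 17)
  expect_lt(g2$p_signed_rank, 0.01)
  expect_gt(g2$ci_median[1], 0)
})

test_that("paired sharpening test behaves at the null and under shrinkage", {
  set.seed(79)
  ctrl <- rnorm(60, 0, 0.1)
  same <- pairedConditionTest(ctrl, ctrl, n_boot = 500, seed = 18)
  expect_equal(same$dS, 0)
  expect_equal(same$p_sharpening, 0.5, tolerance = 0.05)

  shrunk <- median(ctrl) + 0.5 * (ctrl - median(ctrl))
  sh <- pairedConditionTest(ctrl, shrunk, n_boot = 2000, seed = 19)
  expect_gt(sh$dS, 0)
  expect_lt(sh$p_sharpening, 0.05)

  expect_error(pairedConditionTest(1.0, 2.0), "two units")
  expect_error(pairedConditionTest(ctrl, ctrl[-1]), "equal-length")
})
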