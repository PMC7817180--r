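test_that("count-level generator plants the change coefficient exactly", {
  # unit with c = 0.05, 2000 deviant trains per sign: empirical increase -
  # decrease difference within 3 SEM of the planted value
  ct <- simulateCountPopulation(4, c_planted = 0.05, n_increase = 2000,
                                n_decrease = 2000, n_baseline = 200,
                                seed = 11)
  cc <- coefficientTable(changeCoefficient(ct, seed = 12))
  sem <- sqrt(2 * 0.2 / 2000)  # var(count) ~ mean ~ 0.2
  expect_true(all(abs(cc$coeff - 0.05) < 3 * sem))

  # null case: difference concentrates at 0
  ct0 <- simulateCountPopulation(4, c_planted = 0, n_increase = 2000,
                                 n_decrease = 2000, n_baseline = 200,
                                 seed = 13)
  cc0 <- coefficientTable(changeCoefficient(ct0, seed = 14))
  expect_true(all(abs(cc0$coeff) < 3 * sem))
})

test_that("spike-level generator agrees with the count-level marginal", {
  # same planted c recovered through spike times + windowed counting
  trains <- simulateTrainSet(1200, p_deviant = 0.6, positions = 1:5,
                             seed = 21)
  cfg <- spikeSimConfig(n_units = c("L2/3" = 4L, L4 = 0L, L5 = 0L, L6 = 0L),
                        driven_fraction = c("L2/3" = 1, L4 = 0, L5 = 0, L6 = 0),
                        change_coeff = list(
                          "L2/3" = list(type = "shifted", c = 0.08),
                          L4 = list(type = "null", c = 0),
                          L5 = list(type = "null", c = 0),
                          L6 = list(type = "null", c = 0)),
                        seed = 22)
  sim <- simulatePopulationSpikes(cfg, trains)
  ct <- perDeflectionCounts(sim$bundle)
  cc <- coefficientTable(changeCoefficient(ct, seed = 23))
  n_per_sign <- min(sum(ct@train_info$deviant_sign > 0),
                    sum(ct@train_info$deviant_sign < 0))
  sem <- sqrt(2 * 0.3 / n_per_sign)
  expect_true(all(abs(cc$coeff - 0.08) < 3.5 * sem))
  # mean per-deflection count is near base*w + gain*adapt at position 0
  m0 <- mean(counts(ct)[, ct@train_info$deviant_sign == 0L, 1])
  expect_equal(m0, 1 * 0.1 + 0.1, tolerance = 0.15)
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulateCountPopulation(5, c_planted = 0.03, seed = 7)
  b <- simulateCountPopulation(5, c_planted = 0.03, seed = 7)
  expect_identical(counts(a), counts(b))
  expect_false(identical(counts(a),
                         counts(simulateCountPopulation(5, c_planted = 0.03,
                                                        seed = 8))))
  trains <- simulateTrainSet(20, seed = 3)
  cfg <- spikeSimConfig(n_units = c("L2/3" = 3L, L4 = 0L, L5 = 0L, L6 = 0L),
                        seed = 4)
  s1 <- simulatePopulationSpikes(cfg, trains)
  s2 <- simulatePopulationSpikes(cfg, trains)
  expect_identical(spikeTable(s1$bundle), spikeTable(s2$bundle))

  tb1 <- simulateDetectionBehavior(n_trials = 200, seed = 5)
  tb2 <- simulateDetectionBehavior(n_trials = 200, seed = 5)
  expect_identical(tb1, tb2)

  c1 <- simulateCalcium(n_roi = 5, n_trials = 6, seed = 6)
  c2 <- simulateCalcium(n_roi = 5, n_trials = 6, seed = 6)
  expect_identical(c1$rts@F, c2$rts@F)
})

test_that("weak-laser ensemble shuffle preserves mean L6 rate while flipping identity", {
  n_l6 <- 100L
  trains <- simulateTrainSet(200, p_deviant = 0,
                             opto_condition = c("control", "weak_laser"),
                             seed = 31)
  cfg <- spikeSimConfig(
    n_units = c("L2/3" = 0L, L4 = 0L, L5 = 0L, L6 = n_l6),
    driven_fraction = c("L2/3" = 0, L4 = 0, L5 = 0, L6 = 0.5),
    response_gain = 0.3, opto_shuffle_fraction = 0.5, seed = 32)
  sim <- simulatePopulationSpikes(cfg, trains)
  # >= 40 of 100 units change driven status under the laser
  expect_gte(sum(sim$truth$laser_label != "unchanged"), 40L)
  # but the layer's mean rate changes by < 2%
  sp <- spikeTable(sim$bundle)
  laser_ids <- trains$train_id[trains$opto_condition == "weak_laser"]
  r_laser <- sum(sp$train_id %in% laser_ids) / length(laser_ids)
  r_ctrl <- sum(!sp$train_id %in% laser_ids) /
    (nrow(trains) - length(laser_ids))
  expect_lt(abs(r_laser - r_ctrl) / r_ctrl, 0.02)
  # swapped pairs exchange their planted response on laser trials:
  # facilitated units respond, suppressed do not
  ct <- perDeflectionCounts(sim$bundle)
  fac <- sim$truth$unit_id[sim$truth$laser_label == "laser_facilitated"]
  las <- ct@train_info$opto_condition == "weak_laser"
  m_fac_laser <- mean(counts(ct)[fac, las, 1])
  m_fac_ctrl <- mean(counts(ct)[fac, !las, 1])
  expect_gt(m_fac_laser - m_fac_ctrl, 0.15)
})

test_that("detection observer matches its psychometric curve", {
  # amp = mu with guess = lapse = 0 -> hit probability 1/2
  ps <- list(mu = 15, sigma = 4, guess = 0, lapse = 0, deviant_benefit = 0)
  tr <- simulateDetectionBehavior(ps, n_trials = 6000, amp_range = c(15, 15),
                                  p_deviant = 0, p_catch = 0, p_max = 0,
                                  seed = 41)
  hr <- mean(tr$response == "hit")
  expect_lt(abs(hr - 0.5), 3 * sqrt(0.25 / 6000))
  expect_error(simulateDetectionBehavior(
    list(mu = 15, sigma = 4, guess = 0.7, lapse = 0.5, deviant_benefit = 0),
    n_trials = 10), "probabilities")
})

test_that("calcium generator plants recoverable transients and artifacts", {
  # noiseless planted transient recovered within 5%
  sim <- simulateCalcium(n_roi = 2, n_trials = 8, trial_period_s = 12,
                         noise_sd = 0, driven_fraction = 1,
                         response_dff = 1.5, amplitude_gain = 0,
                         drift_frac = 0.02, seed = 51)
  r <- suppressWarnings(computeDff(sim$rts@F, 5))
  expect_lt(abs(max(r$dff[1, ]) - 1.5) / 1.5, 0.05)

  # no spikes, no noise, no drift -> dff recovered identically 0
  sim0 <- simulateCalcium(n_roi = 3, n_trials = 8, noise_sd = 0,
                          driven_fraction = 0, drift_frac = 0, seed = 52)
  r0 <- suppressWarnings(computeDff(sim0$rts@F, 5))
  expect_lt(max(abs(r0$dff)), 1e-9)

  # artifact-on vs artifact-off frames differ only on laser frames
  st <- simulateArtifactStack(n_frames = 20, noise_sd = 0.5, seed = 53)
  dmax <- apply(abs(st$frames - st$clean_frames), 3, max)
  expect_true(all(dmax[!st$laser_on] == 0))
  expect_true(all(dmax[st$laser_on] > 0))
})
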