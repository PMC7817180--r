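test_that("dff of a constant trace is zero and gain-invariant", {
  F <- matrix(100, 2, 600)
  r <- computeDff(F, frame_rate = 5, window_s = 60)
  expect_true(all(r$F0 == 100))
  expect_true(all(r$dff == 0))

  set.seed(92)
  F <- matrix(100 + abs(rnorm(2 * 600, 0, 5)), 2, 600)
  r1 <- computeDff(F, 5, window_s = 60)
  r2 <- computeDff(3.7 * F, 5, window_s = 60)
  expect_equal(r2$dff, r1$dff, tolerance = 1e-12)
  expect_equal(r2$F0, 3.7 * r1$F0, tolerance = 1e-12)
  expect_error(computeDff(F - 200, 5, window_s = 60), "non-positive")
})

test_that("the sliding percentile tracks step plateaus within 2%", {
  nf <- 3000
  F <- matrix(100, 1, nf)
  F[1, 1501:nf] <- 200
  spikes_at <- seq(100, nf, by = 250)
  F[1, spikes_at] <- F[1, spikes_at] * 2.5
  r <- computeDff(F, frame_rate = 5, window_s = 200)
  expect_lt(abs(r$F0[1, 700] - 100) / 100, 0.02)
  expect_lt(abs(r$F0[1, 2300] - 200) / 200, 0.02)
  # exact and strided evaluation agree closely away from the step
  r1 <- computeDff(F[, 1:1200, drop = FALSE], 5, window_s = 100, stride = 1)
  rs <- computeDff(F[, 1:1200, drop = FALSE], 5, window_s = 100)
  expect_lt(max(abs(r1$F0 - rs$F0)) / 100, 0.01)
})

test_that("annulus masks match brute-force set algebra and avoid somata", {
  # lone 10 px wide ROI: annulus extends 20 px each side in x, 0 in y
  m <- matrix(FALSE, 30, 80)
  m[15, 31:40] <- TRUE
  ann <- neuropilAnnulus(m, list(m), erode_x_px = 20)
  expect_true(all(ann[15, 11:30]))
  expect_true(all(ann[15, 41:60]))
  expect_false(any(ann[14, ]))
  expect_false(any(ann & m))

  # random masks vs independent pixel-set oracle
  set.seed(93)
  for (rep in 1:4) {
    ny <- 40; nx <- 60
    masks <- lapply(1:3, function(i) {
      mm <- matrix(FALSE, ny, nx)
      cy <- sample(5:(ny - 5), 1); cx <- sample(5:(nx - 5), 1)
      mm[cy + (-2:2), pmin(pmax(cx + (-2:2), 1), nx)] <- TRUE
      mm
    })
    ann <- neuropilAnnulus(masks[[1]], masks, erode_x_px = 7)
    # oracle: enumerate pixels within 7 x-steps of the ROI on the same row
    oracle <- matrix(FALSE, ny, nx)
    idx <- which(masks[[1]], arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      xs <- (idx[k, 2] - 7):(idx[k, 2] + 7)
      xs <- xs[xs >= 1 & xs <= nx]
      oracle[idx[k, 1], xs] <- TRUE
    }
    oracle <- oracle & !Reduce(`|`, masks)
    expect_identical(ann[, ], oracle)
    # never intersects any soma
    for (m2 in masks) expect_false(any(ann & m2))
  }
  # fully surrounded ROI -> empty annulus is flagged
  left <- matrix(FALSE, 10, 30); left[5, 10] <- TRUE
  wall <- matrix(FALSE, 10, 30); wall[5, c(1:9, 11:30)] <- TRUE
  expect_warning(ann2 <- neuropilAnnulus(left, list(left, wall), 20),
                 "flagged")
  expect_false(any(ann2))
})

test_that("scaled neuropil subtraction removes a shared contamination component", {
  set.seed(91)
  shared <- matrix(rnorm(400), 1, 400)
  Fm <- matrix(100, 2, 400) + 0.7 * rbind(shared, shared)
  Fnp <- matrix(40, 2, 400) + rbind(shared, shared)
  out <- subtractNeuropil(Fm, Fnp, r = 0.7)
  expect_lt(max(apply(out, 1, sd)), 1e-9)  # shared component fully removed
  expect_equal(rowMeans(subtractNeuropil(Fm, Fnp)), rowMeans(Fm))
  expect_error(subtractNeuropil(Fm, Fnp[, 1:10]), "shape")
})

test_that("artifact correction is the identity on a constant field", {
  frames <- array(50, dim = c(16, 20, 6))
  masks <- list({m <- matrix(FALSE, 16, 20); m[8, 9:11] <- TRUE; m})
  np <- lapply(masks, neuropilAnnulus, all_roi_masks = masks, erode_x_px = 3)
  res <- correctLightArtifact(frames, affected_lines = c(4, 8, 12),
                              roi_masks = masks, neuropil_masks = np,
                              laser_on = NULL)
  expect_equal(res$frames, frames)
  expect_true(all(res$roi_traces == 50))
})

test_that("two-stage correction removes a planted artifact to < 0.5%", {
  st <- simulateArtifactStack(n_frames = 60, line_artifact = 0.05,
                              diffuse_artifact = 0.3, seed = 94)
  res <- correctLightArtifact(st$frames, st$affected_lines, st$roi_masks,
                              st$neuropil_masks, st$laser_on)
  bias <- rowMeans(res$roi_traces_corrected[, st$laser_on]) -
    rowMeans(res$roi_traces_corrected[, !st$laser_on])
  expect_lt(max(abs(bias)) / 100, 0.005)
  # stage-2 profile on a session without artifacts is ~0
  st0 <- simulateArtifactStack(n_frames = 60, line_artifact = 0,
                               diffuse_artifact = 0, seed = 95)
  res0 <- correctLightArtifact(st0$frames, st0$affected_lines, st0$roi_masks,
                               st0$neuropil_masks, st0$laser_on)
  expect_lt(max(abs(res0$brightening_profile)) / 100, 0.003)
})

test_that("responsiveness needs elevated stimulus-period quantiles", {
  sim <- simulateCalcium(n_roi = 40, n_trials = 40, noise_sd = 0.05,
                         driven_fraction = 0.25, seed = 96)
  rts <- sim$rts
  r <- computeDff(rts@F, 5)
  rts@dff <- r$dff; rts@F0 <- r$F0
  resp <- classifyResponsive(rts)
  expect_true(all(resp[sim$truth$driven]))
  expect_lt(mean(resp[!sim$truth$driven]), 0.15)
  # stimulus window identical to the pre window -> nothing is responsive
  none <- classifyResponsive(rts, pre_window = c(-1.5, 0),
                             stim_window = c(-1.5, 0))
  expect_false(any(none))
})

test_that("cross-validated selection removes the regression-to-mean artifact", {
  # pure-noise ROIs: selecting 'responsive-looking' ROIs on the same trials
  # used for evaluation yields spurious positive evoked signal; selecting on
  # held-out trials does not
  sim <- simulateCalcium(n_roi = 150, n_trials = 60, noise_sd = 0.08,
                         driven_fraction = 0, drift_frac = 0, seed = 97)
  rts <- sim$rts
  r <- suppressWarnings(computeDff(rts@F, 5))
  rts@dff <- r$dff; rts@F0 <- r$F0
  ev <- evokedResponse(rts)
  half_a <- seq_len(30); half_b <- 31:60
  score_a <- rowMeans(ev[, half_a])
  naive_pick <- score_a > quantile(score_a, 0.9)
  # selection bias relative to the population mean evoked level: picking on
  # the evaluation trials inflates the estimate, held-out trials do not
  naive_excess <- mean(ev[naive_pick, half_a]) - mean(ev)
  cv_excess <- mean(ev[naive_pick, half_b]) - mean(ev)
  expect_gt(naive_excess, 0.004)
  expect_lt(abs(cv_excess), naive_excess / 2)
})

test_that("evoked encoding statistics recover a planted amplitude gain", {
  sim <- simulateCalcium(n_roi = 120, n_trials = 60, noise_sd = 0.05,
                         driven_fraction = 1, response_dff = 0.6,
                         amplitude_gain = 0.03, seed = 98)
  rts <- sim$rts
  r <- computeDff(rts@F, 5)
  rts@dff <- r$dff
  ev <- evokedResponse(rts)
  big <- rts@trial_info$condition %in% c("base_large", "dev_up")
  st <- evokedEncodingStats(ev, factor(ifelse(big, "b_large", "a_small")),
                            n_boot = 400, seed = 99)
  expect_gt(median(st$per_roi$diff), 0)
  expect_lt(st$p_signed_rank, 0.01)
  expect_gt(st$ci_median[1], 0)
  # label-shuffled contrast covers zero. Shuffle within stimulus condition so
  # the permuted grouping is orthogonal to amplitude, and use a drift-free
  # session: slow shared baseline drift correlates ROI noise and the ROI-wise
  # CI assumes exchangeable units
  sim0 <- simulateCalcium(n_roi = 120, n_trials = 60, noise_sd = 0.05,
                          driven_fraction = 1, response_dff = 0.6,
                          amplitude_gain = 0.03, drift_frac = 0, seed = 98)
  rts0 <- sim0$rts
  rts0@dff <- computeDff(rts0@F, 5)$dff
  ev0 <- evokedResponse(rts0)
  set.seed(100)
  lab <- rep(NA_character_, nrow(rts0@trial_info))
  for (cond in unique(rts0@trial_info$condition)) {
    i <- sample(which(rts0@trial_info$condition == cond))
    lab[i] <- rep_len(c("a", "b"), length(i))  # exactly balanced halves
  }
  st0 <- evokedEncodingStats(ev0, lab, n_boot = 400, seed = 101)
  expect_lte(st0$ci_median[1], 0)
  expect_gte(st0$ci_median[3], 0)
})
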