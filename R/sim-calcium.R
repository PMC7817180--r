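# Synthetic GCaMP6s ROI traces and a frame stack with a flyback light
# artifact, with planted ground truth.

# double-exponential GCaMP6s kernel normalized to unit peak
.gcamp_kernel <- function(t, rise = 0.18, decay = 1.5) {
  k <- (1 - exp(-pmax(t, 0) / rise)) * exp(-pmax(t, 0) / decay)
  k[t < 0] <- 0
  tp <- rise * log(1 + decay / rise)
  k / ((1 - exp(-tp / rise)) * exp(-tp / decay))
}

#' Simulate a GCaMP6s ROI trace set
#'
#' Sparse driven ROIs (default 13%, the sensory responsiveness of L6 CT
#' cells) respond to each stimulus train with a transient whose peak dF/F is
#' `response_dff` plus `amplitude_gain` times the stimulus amplitude's
#' deviation from the session mean; the transient follows a double-exponential
#' GCaMP6s kernel (rise 0.18 s, decay 1.5 s). `F = F0(t) * (1 + dff + noise)`
#' with a slow sinusoidal baseline drift. Neuropil traces carry a shared
#' contamination component (a scaled copy of the population-mean signal plus
#' noise). On laser trials a fraction of ROIs swap driven identity pairwise
#' ("ensemble shuffle"), preserving the population mean response.
#'
#' Stimulus amplitudes follow the two-baseline / two-deviant design: baseline
#' small or large, or an intermediate baseline with a deviant to 120% or 80%.
#'
#' @param n_roi number of ROIs.
#' @param n_trials number of stimulus trials.
#' @param frame_rate Hz (>= 5).
#' @param trial_period_s seconds between stimulus onsets.
#' @param stim_dur_s stimulus train duration (s).
#' @param driven_fraction fraction of driven ROIs.
#' @param response_dff peak evoked dF/F of a driven ROI.
#' @param amplitude_gain peak dF/F per mm/s of amplitude deviation.
#' @param amps named amplitudes `c(small, large, mid)` (mm/s).
#' @param deviant_frac relative deviant amplitude (0.2 = to 120%/80%).
#' @param noise_sd per-frame dF/F noise SD.
#' @param f0 mean baseline fluorescence (a.u.).
#' @param drift_frac relative amplitude of the slow F0 drift.
#' @param p_laser fraction of laser trials (0 disables the laser arm).
#' @param shuffle_fraction fraction of ROIs whose driven identity flips under
#'   laser.
#' @param seed RNG seed.
#' @return list: `rts` (a [RoiTraceSet-class], `dff` not yet computed) and
#'   `truth` (per-ROI data.frame).
#' @export
simulateCalcium <- function(n_roi = 100L, n_trials = 60L, frame_rate = 5,
                            trial_period_s = 8, stim_dur_s = 0.7,
                            driven_fraction = 0.13, response_dff = 1.0,
                            amplitude_gain = 0.04,
                            amps = c(small = 20, large = 30, mid = 25),
                            deviant_frac = 0.2, noise_sd = 0.05, f0 = 100,
                            drift_frac = 0.05, p_laser = 0,
                            shuffle_fraction = 0.5, seed = 1L) {
  assert_that(frame_rate >= 5, "frame rate must be >= 5 Hz")
  with_seed(seed, {
    total_s <- n_trials * trial_period_s + 4
    ft <- seq(0, total_s, by = 1 / frame_rate)
    nf <- length(ft)
    onset <- (seq_len(n_trials) - 1L) * trial_period_s + 2
    cond <- sample(c("base_small", "base_large", "dev_up", "dev_down"),
                   n_trials, replace = TRUE)
    amp_eff <- c(base_small = amps[["small"]], base_large = amps[["large"]],
                 dev_up = amps[["mid"]] * (1 + deviant_frac),
                 dev_down = amps[["mid"]] * (1 - deviant_frac))[cond]
    laser <- stats::runif(n_trials) < p_laser

    driven <- stats::runif(n_roi) < driven_fraction
    truth <- data.frame(roi = seq_len(n_roi), driven = driven,
                        response_dff = ifelse(driven, response_dff, 0),
                        amplitude_gain = ifelse(driven, amplitude_gain, 0),
                        laser_label = "unchanged",
                        stringsAsFactors = FALSE)
    # pairwise ensemble shuffle under laser
    partner <- rep(NA_integer_, n_roi)
    if (p_laser > 0) {
      dr <- which(driven); nd <- which(!driven)
      k <- min(length(dr), length(nd), floor(shuffle_fraction * n_roi / 2))
      if (k > 0) {
        a <- sample(dr, k); b <- sample(nd, k)
        partner[a] <- b; partner[b] <- a
        truth$laser_label[a] <- "laser_suppressed"
        truth$laser_label[b] <- "laser_facilitated"
      }
    }

    mean_amp <- mean(amp_eff)
    dff_true <- matrix(0, n_roi, nf)
    for (i in seq_len(n_trials)) {
      # response builds during the train: kernel anchored at stimulus onset
      k <- .gcamp_kernel(ft - onset[i])
      idx <- which(k > 1e-4)
      if (!length(idx)) next
      for (r in seq_len(n_roi)) {
        use <- if (laser[i] && !is.na(partner[r])) partner[r] else r
        pk <- truth$response_dff[use] +
          truth$amplitude_gain[use] * (amp_eff[i] - mean_amp)
        if (pk != 0) dff_true[r, idx] <- dff_true[r, idx] + pk * k[idx]
      }
    }
    drift <- 1 + drift_frac * sin(2 * pi * ft / (total_s / 2))
    F0t <- outer(stats::runif(n_roi, 0.9, 1.1) * f0, drift)
    Fm <- F0t * (1 + dff_true + matrix(stats::rnorm(n_roi * nf, 0, noise_sd),
                                       n_roi, nf))
    Fm <- pmax(Fm, 1e-3)
    pop <- colMeans(dff_true)
    Fnp <- outer(rep(f0 * 0.4, n_roi), rep(1, nf)) *
      (1 + 0.2 * matrix(pop, n_roi, nf, byrow = TRUE) +
         matrix(stats::rnorm(n_roi * nf, 0, noise_sd / 2), n_roi, nf))
    rts <- new("RoiTraceSet",
               F = Fm, F_neuropil = Fnp, frame_times = ft,
               F0 = matrix(numeric(0), 0, 0), dff = matrix(numeric(0), 0, 0),
               masks = matrix(integer(0), 0, 0),
               trial_info = data.frame(
                 trial = seq_len(n_trials), stim_onset_s = onset,
                 stim_offset_s = onset + stim_dur_s, condition = cond,
                 amplitude = unname(amp_eff), laser = laser,
                 stringsAsFactors = FALSE),
               responsive = logical(0))
    list(rts = rts, truth = truth)
  })
}

#' Simulate a small frame stack with a flyback light artifact
#'
#' Disk-shaped somatic ROIs on a dim background; on laser-on frames, the
#' affected x-scan lines (every `line_step`-th row) gain `line_artifact`
#' times the local brightness and every pixel gains a diffuse additive
#' `diffuse_artifact` (a.u.), emulating residual image brightening.
#'
#' @param ny,nx image size.
#' @param n_frames frames.
#' @param n_roi number of ROI disks.
#' @param roi_radius ROI radius (px).
#' @param soma_brightness,background brightness levels (a.u.).
#' @param line_step artifact line spacing (default every 4th line).
#' @param line_artifact relative brightening of affected lines.
#' @param diffuse_artifact additive brightening of all pixels (a.u.).
#' @param p_laser fraction of laser-on frames.
#' @param noise_sd pixel noise SD (a.u.).
#' @param seed RNG seed.
#' @return list: `frames`, `affected_lines`, `roi_masks`, `neuropil_masks`,
#'   `laser_on`, `clean_frames` (no artifact, same noise).
#' @export
simulateArtifactStack <- function(ny = 48L, nx = 96L, n_frames = 80L,
                                  n_roi = 3L, roi_radius = 4L,
                                  soma_brightness = 100, background = 20,
                                  line_step = 4L, line_artifact = 0.05,
                                  diffuse_artifact = 0.2, p_laser = 0.5,
                                  noise_sd = 0.5, seed = 1L) {
  with_seed(seed, {
    cy <- round(seq(ny * 0.25, ny * 0.75, length.out = n_roi))
    cx <- round(seq(nx * 0.25, nx * 0.75, length.out = n_roi))
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    roi_masks <- lapply(seq_len(n_roi), function(i)
      (yy - cy[i])^2 + (xx - cx[i])^2 <= roi_radius^2)
    base_img <- matrix(background, ny, nx)
    for (m in roi_masks) base_img[m] <- soma_brightness
    neuropil_masks <- lapply(roi_masks, neuropilAnnulus,
                             all_roi_masks = roi_masks)
    laser_on <- stats::runif(n_frames) < p_laser
    lines <- seq(line_step, ny, by = line_step)
    clean <- frames <- array(0, dim = c(ny, nx, n_frames))
    for (f in seq_len(n_frames)) {
      img <- base_img + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
      clean[, , f] <- img
      if (laser_on[f]) {
        img[lines, ] <- img[lines, ] * (1 + line_artifact)
        img <- img + diffuse_artifact
      }
      frames[, , f] <- img
    }
    list(frames = frames, affected_lines = lines, roi_masks = roi_masks,
         neuropil_masks = neuropil_masks, laser_on = laser_on,
         clean_frames = clean)
  })
}
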