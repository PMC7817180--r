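# dF/F extraction, neuropil annuli, light-artifact correction and evoked
# encoding statistics for ROI traces.

#' Sliding-percentile baseline and dF/F
#'
#' `F0[t]` is the `percentile`-th percentile of the raw trace in a centered
#' `window_s` window (shrinking at the trace edges); `dff = (F - F0) / F0`.
#' The default 30th percentile over 200 s tracks slow baseline drift while
#' ignoring sparse transients. Invariant under global gain: scaling F scales
#' F0 identically and leaves dff unchanged.
#'
#' @param F ROI x frame matrix (or a single trace vector).
#' @param frame_rate frames per second.
#' @param window_s sliding window length (s); if it exceeds the trace the
#'   whole trace is used, with a warning.
#' @param percentile baseline percentile (default 30).
#' @param stride frames between baseline evaluation points; between them F0
#'   is linearly interpolated (the percentile of a 200 s window varies slowly,
#'   so a stride of 1/20 window — the default — is visually indistinguishable
#'   from the exact sliding percentile). Use `stride = 1` for the exact
#'   per-frame computation.
#' @return list with matrices `F0` and `dff` shaped like `F`.
#' @export
computeDff <- function(F, frame_rate, window_s = 200, percentile = 30,
                       stride = NULL) {
  if (is.null(dim(F))) F <- matrix(F, nrow = 1L)
  nf <- ncol(F)
  win <- round(window_s * frame_rate)
  if (win >= nf) {
    warning("baseline window longer than trace; using the whole trace")
    F0 <- matrix(apply(F, 1L, stats::quantile, probs = percentile / 100),
                 nrow(F), nf)
  } else {
    h <- floor(win / 2)
    if (is.null(stride)) stride <- max(1L, win %/% 20L)
    anchors <- unique(c(seq(1L, nf, by = stride), nf))
    q_anch <- vapply(anchors, function(t) {
      lo <- max(1L, t - h); hi <- min(nf, t + h)
      apply(F[, lo:hi, drop = FALSE], 1L, stats::quantile,
            probs = percentile / 100)
    }, numeric(nrow(F)))
    if (nrow(F) == 1L) q_anch <- matrix(q_anch, nrow = 1L)
    F0 <- t(apply(q_anch, 1L, function(q)
      stats::approx(anchors, q, xout = seq_len(nf))$y))
  }
  if (any(F0 <= 0))
    stop("non-positive baseline F0: data pathology", call. = FALSE)
  list(F0 = F0, dff = (F - F0) / F0)
}

#' Neuropil annulus mask for a somatic ROI
#'
#' The annulus is the ROI dilated by `erode_x_px` pixels along the x
#' (fast-scan) direction on each side, minus the ROI itself and minus every
#' other somatic ROI. Dilation along x only guarantees that any per-scan-line
#' light artifact hits soma and annulus equally.
#'
#' @param roi_mask logical matrix (rows = y, cols = x) for the ROI.
#' @param all_roi_masks list of logical masks for every somatic ROI on the
#'   same grid (may include `roi_mask` itself).
#' @param erode_x_px dilation extent along x (default 20 px).
#' @return logical annulus mask; an empty annulus returns all-FALSE with
#'   attribute `flagged = TRUE`.
#' @export
neuropilAnnulus <- function(roi_mask, all_roi_masks, erode_x_px = 20L) {
  dil <- roi_mask
  nx <- ncol(roi_mask)
  for (s in seq_len(erode_x_px)) {
    dil[, seq_len(nx - s)] <- dil[, seq_len(nx - s)] | roi_mask[, seq_len(nx - s) + s]
    dil[, seq_len(nx - s) + s] <- dil[, seq_len(nx - s) + s] | roi_mask[, seq_len(nx - s)]
  }
  somata <- Reduce(`|`, all_roi_masks, init = roi_mask)
  ann <- dil & !somata
  if (!any(ann)) {
    attr(ann, "flagged") <- TRUE
    warning("annulus empty after excluding somata; ROI flagged")
  }
  ann
}

#' Two-stage flyback light-artifact correction
#'
#' Optogenetic light pulses delivered during the scan flyback brighten the
#' x-scan lines that follow them. Stage 1 replaces every affected line in
#' every frame (LED on or off) with the mean of the adjacent lines (one-sided
#' at the image edges). Stage 2 subtracts the residual session-mean
#' brightening profile, estimated per frame as the mean excess fluorescence of
#' all neuropil annuli over their laser-off level, from every somatic ROI
#' trace on laser-on frames.
#'
#' @param frames y by x by frame array.
#' @param affected_lines row (y) indices of artifact lines.
#' @param roi_masks list of somatic ROI masks.
#' @param neuropil_masks list of annulus masks (same order).
#' @param laser_on logical per frame; `NULL` disables stage 2.
#' @return list: `frames` (stage-1 corrected), `roi_traces`,
#'   `neuropil_traces` (ROI x frame, from corrected frames),
#'   `brightening_profile` (per-frame residual estimate; 0 where laser off),
#'   `roi_traces_corrected` (stage-2 output).
#' @export
correctLightArtifact <- function(frames, affected_lines, roi_masks,
                                 neuropil_masks, laser_on = NULL) {
  ny <- dim(frames)[1L]
  out <- frames
  for (ln in affected_lines) {
    nb <- intersect(c(ln - 1L, ln + 1L), setdiff(seq_len(ny), affected_lines))
    if (length(nb) == 0L) next
    out[ln, , ] <- if (length(nb) == 2L)
      (frames[nb[1L], , ] + frames[nb[2L], , ]) / 2
    else frames[nb, , ]
  }
  trace_of <- function(mask) apply(out, 3L, function(fr) mean(fr[mask]))
  roi_tr <- do.call(rbind, lapply(roi_masks, trace_of))
  np_tr <- do.call(rbind, lapply(neuropil_masks, trace_of))

  nf <- dim(frames)[3L]
  profile <- numeric(nf)
  roi_corr <- roi_tr
  if (!is.null(laser_on) && any(laser_on) && any(!laser_on)) {
    base_np <- rowMeans(np_tr[, !laser_on, drop = FALSE])
    excess <- sweep(np_tr, 1L, base_np, `-`)
    profile[laser_on] <- colMeans(excess[, laser_on, drop = FALSE])
    roi_corr <- sweep(roi_tr, 2L, profile, `-`)
  }
  list(frames = out, roi_traces = roi_tr, neuropil_traces = np_tr,
       brightening_profile = profile, roi_traces_corrected = roi_corr)
}

#' Optional scaled neuropil subtraction
#'
#' Subtracts `r` times the (mean-preserving) annulus trace from each somatic
#' trace: `F_corrected = F - r * (F_neuropil - rowMeans(F_neuropil))`. Off by
#' default in the pipeline — annulus traces are primarily the artifact
#' estimate here — but available for contamination-heavy preparations.
#'
#' @param F,F_neuropil ROI x frame matrices, matched rows.
#' @param r contamination coefficient (default 0.7).
#' @return corrected matrix shaped like `F`.
#' @export
subtractNeuropil <- function(F, F_neuropil, r = 0.7) {
  assert_that(identical(dim(F), dim(F_neuropil)),
              "F and F_neuropil must have the same shape")
  F - r * (F_neuropil - rowMeans(F_neuropil))
}

#' Classify stimulus-responsive ROIs
#'
#' An ROI is responsive when the 10% quantile of its dF/F in the stimulus
#' period (default 500-1500 ms after stimulus onset) exceeds the 90% quantile
#' in the pre-stimulus period (-1500-0 ms), pooled over the selected trials:
#' non-overlapping quantiles.
#'
#' @param rts a [RoiTraceSet-class] with `dff` computed; `trial_info` must
#'   carry `stim_onset_s`.
#' @param trials optional trial-row subset (e.g. control-only, or a training
#'   split for cross-validated encoding analyses).
#' @param pre_window,stim_window windows in seconds relative to stimulus onset.
#' @return logical vector per ROI.
#' @export
classifyResponsive <- function(rts, trials = NULL,
                               pre_window = c(-1.5, 0),
                               stim_window = c(0.5, 1.5)) {
  ti <- rts@trial_info
  if (!is.null(trials)) ti <- ti[trials, , drop = FALSE]
  D <- rts@dff
  assert_that(length(D) > 0, "run computeDff first")
  ft <- rts@frame_times
  pick <- function(win) {
    unlist(lapply(ti$stim_onset_s, function(on)
      which(ft >= on + win[1] & ft < on + win[2])))
  }
  ip <- pick(pre_window); is_ <- pick(stim_window)
  assert_that(length(ip) >= 3L * nrow(ti) && length(is_) >= 3L * nrow(ti),
              "fewer than 3 frames per window at this frame rate")
  q_pre <- apply(D[, ip, drop = FALSE], 1L, stats::quantile, probs = 0.9)
  q_stim <- apply(D[, is_, drop = FALSE], 1L, stats::quantile, probs = 0.1)
  unname(q_stim > q_pre)
}

#' Per-trial evoked responses
#'
#' Mean dF/F per ROI in a window anchored at the stimulus offset
#' (default 0-2 s after offset, matching the slow GCaMP6s timescale).
#'
#' @param rts a [RoiTraceSet-class] with `dff`; `trial_info` needs
#'   `stim_offset_s`.
#' @param window seconds relative to stimulus offset.
#' @return ROI x trial matrix.
#' @export
evokedResponse <- function(rts, window = c(0, 2)) {
  ti <- rts@trial_info
  ft <- rts@frame_times
  sapply(seq_len(nrow(ti)), function(i) {
    idx <- which(ft >= ti$stim_offset_s[i] + window[1] &
                 ft < ti$stim_offset_s[i] + window[2])
    rowMeans(rts@dff[, idx, drop = FALSE])
  })
}

#' Evoked encoding statistics across a two-level contrast
#'
#' Per-ROI mean evoked difference between the two groups of `groups`
#' (e.g. large vs small baseline amplitude, increase vs decrease deviants,
#' laser vs control), a population signed-rank p and bootstrap median CI, and
#' a per-ROI trial-bootstrap two-sided p-value (used at level 0.0025 for
#' per-cell laser effects).
#'
#' @param evoked ROI x trial matrix from [evokedResponse()].
#' @param groups two-level factor (or coercible) per trial; the difference is
#'   level2 - level1.
#' @param n_boot trial-bootstrap draws per ROI (default 10000).
#' @param min_trials ROIs need at least this many trials per level (default 5;
#'   with fewer, the function errors since groups are shared across ROIs).
#' @param seed RNG seed.
#' @return list: `per_roi` (data.frame `diff`, `p_boot`), `p_signed_rank`,
#'   `ci_median`.
#' @export
evokedEncodingStats <- function(evoked, groups, n_boot = 10000L,
                                min_trials = 5L, seed = 1L) {
  assert_that(nrow(evoked) > 0, "no ROIs to analyze")
  g <- factor(groups)
  assert_that(nlevels(g) == 2L, "groups must have exactly two levels")
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  assert_that(length(i1) >= min_trials && length(i2) >= min_trials,
              sprintf("need >= %d trials per condition", min_trials))
  d <- rowMeans(evoked[, i2, drop = FALSE]) - rowMeans(evoked[, i1, drop = FALSE])
  p_boot <- with_seed(seed, {
    vapply(seq_len(nrow(evoked)), function(r) {
      x1 <- evoked[r, i1]; x2 <- evoked[r, i2]
      b1 <- matrix(sample(x1, length(x1) * n_boot, replace = TRUE),
                   ncol = n_boot)
      b2 <- matrix(sample(x2, length(x2) * n_boot, replace = TRUE),
                   ncol = n_boot)
      db <- colMeans(b2) - colMeans(b1)
      lo <- (1 + sum(db <= 0)) / (1 + n_boot)
      hi <- (1 + sum(db >= 0)) / (1 + n_boot)
      min(1, 2 * min(lo, hi))
    }, numeric(1))
  })
  ci <- with_seed(seed + 1L, .boot_median_ci(d, 1000L))
  list(per_roi = data.frame(diff = d, p_boot = p_boot),
       p_signed_rank = stats::wilcox.test(d, exact = FALSE)$p.value,
       ci_median = unname(ci))
}
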