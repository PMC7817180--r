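#' Construct a deviant-containing deflection train
#'
#' Builds a train of `n` equal-amplitude deflections at `rate` Hz, optionally
#' replacing one deflection (the deviant) with an amplitude scaled by
#' `1 + deviant_frac`. Onsets are at `k / rate` seconds, 0-based positions.
#'
#' @param baseline_amp baseline deflection velocity (mm/s).
#' @param n number of deflections (default 7).
#' @param rate deflection rate in Hz (default 10).
#' @param deviant_index 0-based deviant position in `1..(n-1)`, or `NULL` for
#'   a no-deviant train. Position 0 is rejected: a deviant needs preceding
#'   baseline deflections.
#' @param deviant_frac relative amplitude change of the deviant, in
#'   `[-0.15, 0.15]`; 0 yields a no-deviant train.
#' @param train_id identifier.
#' @param opto_condition `"control"`, `"weak_laser"` or `"strong_laser"`.
#' @return a [DeflectionTrain-class].
#' @examples
#' buildTrain(25, deviant_index = 3, deviant_frac = 0.12)
#' @export
buildTrain <- function(baseline_amp, n = 7L, rate = 10, deviant_index = NULL,
                       deviant_frac = 0, train_id = "train1",
                       opto_condition = "control") {
  assert_that(baseline_amp > 0, "baseline_amp must be positive")
  assert_that(n >= 1L && rate > 0, "need n >= 1 and rate > 0")
  assert_that(abs(deviant_frac) <= 0.15 + 1e-12,
              "deviant_frac must lie in [-0.15, 0.15]")
  if (!is.null(deviant_index)) {
    deviant_index <- as.integer(deviant_index)
    assert_that(deviant_index != 0L,
                "a deviant at position 0 is invalid: it requires preceding baseline deflections")
    assert_that(deviant_index >= 1L && deviant_index <= n - 1L,
                "deviant_index must lie in 1..(n-1) (0-based)")
  }
  if (deviant_frac == 0) deviant_index <- NULL
  amps <- rep(baseline_amp, n)
  sign <- 0L
  if (!is.null(deviant_index)) {
    amps[deviant_index + 1L] <- baseline_amp * (1 + deviant_frac)
    sign <- as.integer(sign(deviant_frac))
  }
  new("DeflectionTrain",
      train_id = as.character(train_id),
      onsets = (seq_len(n) - 1L) / rate,
      amplitudes = amps,
      baseline_amplitude = baseline_amp,
      deviant_index = deviant_index,
      deviant_sign = sign,
      opto_condition = opto_condition)
}

#' Position histogram matching of deflection sets
#'
#' Subsamples the baseline deflection pool so its histogram of position-in-train
#' exactly equals that of the deviant set, removing adaptation/position
#' confounds from deviant-vs-baseline contrasts. Subsampling is uniform at
#' random under `seed`.
#'
#' @param deviant_deflections data.frame of deflection references with a
#'   `position` column (0-based position in the train).
#' @param baseline_deflections data.frame with the same columns; must contain
#'   at least as many deflections at each position as the deviant set.
#' @param seed RNG seed for the subsampling.
#' @return a [MatchedSets-class] with `set_a` the deviant set and `set_b` the
#'   position-matched baseline subset.
#' @export
histogramMatchPositions <- function(deviant_deflections, baseline_deflections,
                                    seed = 1L) {
  assert_that("position" %in% names(deviant_deflections) &&
              "position" %in% names(baseline_deflections),
              "both sets need a 'position' column")
  if (nrow(deviant_deflections) == 0L) {
    return(new("MatchedSets", set_a = deviant_deflections,
               set_b = baseline_deflections[0, , drop = FALSE],
               matched_on = "position"))
  }
  want <- table(deviant_deflections$position)
  have <- table(factor(baseline_deflections$position, levels = names(want)))
  short <- names(want)[as.integer(have) < as.integer(want)]
  if (length(short))
    stop("insufficient baseline pool at position(s): ",
         paste(short, collapse = ", "), call. = FALSE)
  idx <- with_seed(seed, {
    unlist(lapply(names(want), function(p) {
      pool <- which(baseline_deflections$position == as.numeric(p))
      pool[sample.int(length(pool), want[[p]])]
    }), use.names = FALSE)
  })
  new("MatchedSets",
      set_a = deviant_deflections,
      set_b = baseline_deflections[sort(idx), , drop = FALSE],
      matched_on = "position")
}

#' Match deviant-amplitude distributions between two trial sets
#'
#' Subsamples both sets so the per-bin histograms of deviant amplitude are
#' equal, leaving stimulus history as the only remaining difference. Used to
#' test history-dependent (rather than absolute-amplitude) encoding.
#'
#' @param trials_A,trials_B data.frames with an `amplitude` column.
#' @param bin_width histogram bin width in amplitude units.
#' @param seed RNG seed for the per-bin subsampling.
#' @return a [MatchedSets-class]; `set_a`/`set_b` are the matched subsets.
#' @export
matchAmplitudeDistributions <- function(trials_A, trials_B, bin_width,
                                        seed = 1L) {
  assert_that("amplitude" %in% names(trials_A) &&
              "amplitude" %in% names(trials_B),
              "both trial sets need an 'amplitude' column")
  assert_that(bin_width > 0, "bin_width must be positive")
  lo <- floor(min(trials_A$amplitude, trials_B$amplitude) / bin_width)
  binA <- floor(trials_A$amplitude / bin_width) - lo
  binB <- floor(trials_B$amplitude / bin_width) - lo
  bins <- union(unique(binA), unique(binB))
  keep <- with_seed(seed, {
    lapply(bins, function(b) {
      ia <- which(binA == b); ib <- which(binB == b)
      m <- min(length(ia), length(ib))
      if (m == 0L) return(list(a = integer(), b = integer()))
      list(a = ia[sample.int(length(ia), m)],
           b = ib[sample.int(length(ib), m)])
    })
  })
  ia <- sort(unlist(lapply(keep, `[[`, "a")))
  ib <- sort(unlist(lapply(keep, `[[`, "b")))
  if (length(ia) == 0L)
    stop("no overlapping amplitude support between the two trial sets",
         call. = FALSE)
  new("MatchedSets",
      set_a = trials_A[ia, , drop = FALSE],
      set_b = trials_B[ib, , drop = FALSE],
      matched_on = "amplitude_distribution")
}
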