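#' Map cortical depth to layer
#'
#' Depth (micrometres below the pial surface) is mapped to layers using the
#' barrel-cortex boundaries L2/3: 100-350, L4: 350-450, L5: 450-650,
#' L6: >650; boundary depths are assigned to the deeper layer. Depths above
#' 100 um are labelled `"unassigned"` (L1).
#'
#' @param depth_um non-negative depth in micrometres.
#' @return layer label: `"L2/3"`, `"L4"`, `"L5"`, `"L6"` or `"unassigned"`.
#' @examples
#' assignLayer(400)  # "L4"
#' assignLayer(700)  # "L6"
#' @export
assignLayer <- function(depth_um) {
  assert_that(is.finite(depth_um) && depth_um >= 0,
              "depth_um must be non-negative")
  if (depth_um < 100) "unassigned"
  else if (depth_um < 350) "L2/3"
  else if (depth_um < 450) "L4"
  else if (depth_um < 650) "L5"
  else "L6"
}

#' Classify a unit as regular- or fast-spiking by waveform width
#'
#' @param width_ms trough-to-peak waveform width (ms), positive.
#' @param threshold_ms widths below this are fast-spiking (default 0.4 ms, a
#'   standard cortical cut).
#' @return `"FS"` or `"RS"`.
#' @export
classifyWaveform <- function(width_ms, threshold_ms = 0.4) {
  assert_that(width_ms > 0, "width_ms must be positive")
  if (width_ms < threshold_ms) "FS" else "RS"
}

#' Spike counts per (unit, train, deflection)
#'
#' Counts spikes in the half-open window `[onset_d, onset_d + window)` for
#' every deflection of every train, for every unit. Deflections after a
#' train's first deviant are flagged in the `excluded` slot and are skipped by
#' the change-coding statistics downstream.
#'
#' @param bundle a [SessionBundle-class].
#' @param window_ms count window (ms); must not exceed the inter-deflection
#'   interval.
#' @return a [CountTensor-class].
#' @export
perDeflectionCounts <- function(bundle, window_ms = 100) {
  trains <- bundle@trains
  units <- bundle@units
  pre <- bundle@metadata$pre_window_s
  w <- window_ms / 1000
  nU <- nrow(units); nT <- nrow(trains)
  nD <- max(trains$n_deflections)

  for (i in seq_len(nT)) {
    on <- train_onsets(trains, i)
    if (length(on) > 1L && w > min(diff(on)) + 1e-12)
      stop("window_ms exceeds the inter-deflection interval", call. = FALSE)
  }

  cnt <- array(0L, dim = c(nU, nT, nD),
               dimnames = list(units$unit_id, trains$train_id, NULL))
  sp <- bundle@spikes
  if (nrow(sp)) {
    ui <- match(sp$unit_id, units$unit_id)
    ti <- match(sp$train_id, trains$train_id)
    rel <- sp$t_s - pre
    for (i in unique(ti)) {
      on <- train_onsets(trains, i)
      sel <- which(ti == i)
      pos <- findInterval(rel[sel], on)
      ok <- pos >= 1L & (rel[sel] - on[pmax(pos, 1L)]) < w &
        (rel[sel] - on[pmax(pos, 1L)]) >= 0
      if (any(ok)) {
        tab <- table(ui[sel][ok], pos[ok])
        uu <- as.integer(rownames(tab)); dd <- as.integer(colnames(tab))
        for (j in seq_along(dd))
          cnt[uu, i, dd[j]] <- cnt[uu, i, dd[j]] + as.integer(tab[, j])
      }
    }
  }

  excl <- matrix(FALSE, nT, nD)
  for (i in seq_len(nT)) {
    k <- trains$n_deflections[i]
    if (k < nD) excl[i, seq(k + 1L, nD)] <- TRUE
    di <- trains$deviant_index[i]
    if (!is.na(di) && di + 2L <= nD)
      excl[i, seq(di + 2L, nD)] <- TRUE  # 0-based deviant -> later deflections
  }

  dev_amp <- vapply(seq_len(nT), function(i) {
    di <- trains$deviant_index[i]
    if (is.na(di)) NA_real_ else train_amps(trains, i)[di + 1L]
  }, numeric(1))

  new("CountTensor",
      counts = cnt, window_ms = window_ms, excluded = excl,
      train_info = data.frame(
        train_id = trains$train_id,
        deviant_index = trains$deviant_index,
        deviant_sign = trains$deviant_sign,
        opto_condition = trains$opto_condition,
        baseline_amplitude = trains$baseline_amplitude,
        deviant_amplitude = dev_amp,
        stringsAsFactors = FALSE))
}

#' Trial-averaged peri-stimulus time histogram
#'
#' @param bundle a [SessionBundle-class].
#' @param unit_id unit to analyze.
#' @param window numeric `c(t0, t1)` in seconds, relative to the first
#'   deflection onset (negative times reach into the pre-stimulus window).
#' @param bin_ms bin width; must divide the window length.
#' @param train_ids optional subset of trains (default: all).
#' @return numeric vector of rates (Hz), one per bin, with bin start times
#'   (s) as names.
#' @export
psth <- function(bundle, unit_id, window = c(-0.1, 0.7), bin_ms = 10,
                 train_ids = NULL) {
  pre <- bundle@metadata$pre_window_s
  if (is.null(train_ids)) train_ids <- bundle@trains$train_id
  n_trials <- length(train_ids)
  assert_that(n_trials > 0, "psth needs at least one trial")
  span <- diff(window)
  nbin <- span / (bin_ms / 1000)
  assert_that(abs(nbin - round(nbin)) < 1e-9, "bin_ms must divide the window")
  nbin <- as.integer(round(nbin))
  sp <- bundle@spikes
  t <- sp$t_s[sp$unit_id == unit_id & sp$train_id %in% train_ids] - pre
  t <- t[t >= window[1] & t < window[2]]
  idx <- floor((t - window[1]) / (bin_ms / 1000)) + 1L
  counts <- tabulate(idx, nbins = nbin)
  rate <- counts / n_trials / (bin_ms / 1000)
  names(rate) <- sprintf("%.4f", window[1] + (seq_len(nbin) - 1L) * bin_ms / 1000)
  rate
}
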