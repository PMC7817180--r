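#' Configuration for the synthetic spiking population
#'
#' Defaults encode the qualitative layer structure of deviant encoding in
#' barrel cortex: L4 driven units share a positively shifted change
#' coefficient, L2/3 units split into positive- and negative-coefficient
#' subpopulations (heterogeneous), L5 carries no deviant signal, and L6 is
#' sparsely driven with amplitude coding. Rates are chosen for sparse cortical
#' responses (~0.1 spikes per deflection above a 1 Hz baseline).
#'
#' @param n_units named integer vector of units per layer.
#' @param driven_fraction named numeric vector, fraction of driven units per
#'   layer (L6 default 0.13: sparse sensory responsiveness).
#' @param base_rate spontaneous rate (Hz).
#' @param response_gain expected evoked spikes per deflection for a driven
#'   unit (before adaptation).
#' @param adaptation multiplier per 0-based deflection position applied to the
#'   evoked response; default geometric decay `0.9^position`.
#' @param amplitude_gain evoked spikes per (mm/s) of amplitude above baseline,
#'   per layer (default: only L6 codes amplitude).
#' @param change_coeff named list per layer: `list(type, c)` with type one of
#'   `"shifted"` (all driven units get `+c`), `"heterogeneous"` (half `+c`,
#'   half `-c`), `"null"`.
#' @param opto_shuffle_fraction fraction of L6 units whose driven identity is
#'   swapped (pairwise, rate-preserving) on weak-laser trials.
#' @param kernel_latency_s,kernel_dur_s half-cosine deflection-response kernel
#'   parameters (s).
#' @param seed RNG seed.
#' @return named list of class `spike_sim_config`.
#' @export
spikeSimConfig <- function(n_units = c("L2/3" = 30L, L4 = 15L, L5 = 15L, L6 = 20L),
                           driven_fraction = c("L2/3" = 0.26, L4 = 0.4,
                                               L5 = 0.3, L6 = 0.13),
                           base_rate = 1,
                           response_gain = 0.1,
                           adaptation = function(pos) 0.9^pos,
                           amplitude_gain = c("L2/3" = 0, L4 = 0, L5 = 0,
                                              L6 = 0.002),
                           change_coeff = list(
                             "L2/3" = list(type = "heterogeneous", c = 0.05),
                             "L4" = list(type = "shifted", c = 0.015),
                             "L5" = list(type = "null", c = 0),
                             "L6" = list(type = "null", c = 0)),
                           opto_shuffle_fraction = 0.5,
                           kernel_latency_s = 0.010, kernel_dur_s = 0.025,
                           seed = 1L) {
  assert_that(all(driven_fraction >= 0 & driven_fraction <= 1),
              "driven_fraction values must lie in [0, 1]")
  assert_that(base_rate >= 0 && response_gain >= 0, "rates must be >= 0")
  assert_that(opto_shuffle_fraction >= 0 && opto_shuffle_fraction <= 1,
              "opto_shuffle_fraction must lie in [0, 1]")
  structure(list(
    n_units = n_units, driven_fraction = driven_fraction,
    base_rate = base_rate, response_gain = response_gain,
    adaptation = adaptation, amplitude_gain = amplitude_gain,
    change_coeff = change_coeff,
    opto_shuffle_fraction = opto_shuffle_fraction,
    kernel_latency_s = kernel_latency_s, kernel_dur_s = kernel_dur_s,
    seed = seed), class = "spike_sim_config")
}

#' Simulate a set of deflection trains
#'
#' Writes the wide trains schema consumed by [sessionBundle()]. Half of the
#' trains (by default) contain a single amplitude deviant of random sign with
#' relative magnitude drawn uniformly from `frac_range`, at a position drawn
#' uniformly from `positions` (0-based).
#'
#' @param n_trains number of trains.
#' @param baseline_amp baseline amplitude (mm/s), scalar or vector to sample
#'   from uniformly per train.
#' @param p_deviant probability a train contains a deviant.
#' @param positions allowed 0-based deviant positions.
#' @param frac_range range of the deviant's relative amplitude magnitude.
#' @param opto_condition a single condition, or a vector sampled per train.
#' @param n,rate deflections per train and rate (Hz).
#' @param seed RNG seed.
#' @return wide trains data.frame.
#' @export
simulateTrainSet <- function(n_trains, baseline_amp = 25, p_deviant = 0.5,
                             positions = 1:5, frac_range = c(0.05, 0.15),
                             opto_condition = "control", n = 7L, rate = 10,
                             seed = 1L) {
  with_seed(seed, {
    trains <- lapply(seq_len(n_trains), function(i) {
      ba <- if (length(baseline_amp) > 1L) sample(baseline_amp, 1L) else baseline_amp
      oc <- if (length(opto_condition) > 1L) sample(opto_condition, 1L) else opto_condition
      if (stats::runif(1) < p_deviant) {
        mag <- stats::runif(1, frac_range[1], frac_range[2])
        fr <- sample(c(-1, 1), 1L) * mag
        pos <- if (length(positions) > 1L) sample(positions, 1L) else positions
        buildTrain(ba, n = n, rate = rate, deviant_index = pos,
                   deviant_frac = fr, train_id = sprintf("tr%05d", i),
                   opto_condition = oc)
      } else {
        buildTrain(ba, n = n, rate = rate, train_id = sprintf("tr%05d", i),
                   opto_condition = oc)
      }
    })
    trainsToTable(trains)
  })
}

# Per-unit planted parameters for one layer.
.plant_layer <- function(layer, cfg) {
  nu <- cfg$n_units[[layer]]
  if (is.null(nu) || nu == 0L) return(NULL)
  driven <- rep(FALSE, nu)
  driven[seq_len(round(cfg$driven_fraction[[layer]] * nu))] <- TRUE
  cc <- cfg$change_coeff[[layer]]
  c_planted <- numeric(nu)
  dr <- which(driven)
  if (length(dr) && cc$type == "shifted") c_planted[dr] <- cc$c
  if (length(dr) && cc$type == "heterogeneous") {
    half <- seq_len(ceiling(length(dr) / 2))
    c_planted[dr[half]] <- cc$c
    c_planted[dr[-half]] <- -cc$c
  }
  depth_range <- switch(layer, "L2/3" = c(150, 340), "L4" = c(360, 440),
                        "L5" = c(460, 640), "L6" = c(660, 800))
  data.frame(
    layer = layer,
    depth_um = stats::runif(nu, depth_range[1], depth_range[2]),
    waveform_width_ms = ifelse(stats::runif(nu) < 0.3, 0.25, 0.65),
    driven = driven,
    c_planted = c_planted,
    amplitude_gain = ifelse(driven, cfg$amplitude_gain[[layer]], 0),
    response_gain = ifelse(driven, cfg$response_gain, 0),
    stringsAsFactors = FALSE)
}

# Expected evoked spikes for deflection d of train row i, for one unit.
# The deviant term is not subject to adaptation so that the planted change
# coefficient c equals E[count | +1] - E[count | -1] exactly at any position.
.evoked_mean <- function(gain, amp_gain, c_planted, amps, baseline, dev_idx,
                         dev_sign, adapt) {
  nD <- length(amps)
  m <- adapt * (gain + amp_gain * (amps - baseline))
  if (!is.na(dev_idx))
    m[dev_idx + 1L] <- m[dev_idx + 1L] + (c_planted / 2) * dev_sign
  m
}

#' Simulate population spiking for a train set
#'
#' Spikes are drawn from an inhomogeneous Poisson process: a homogeneous
#' background at `base_rate` plus, for driven units, per-deflection evoked
#' spikes whose expected number is `adaptation(pos) * (response_gain +
#' amplitude_gain * (amp - baseline))`, with `(c/2) * deviant_sign` added on
#' the deviant deflection so the planted change coefficient is exactly `c`.
#' Evoked spike times follow a half-cosine kernel after deflection onset.
#' On weak-laser trains, a fraction of L6 units swap driven identity pairwise,
#' preserving the layer's mean rate ("ensemble shuffle").
#'
#' Negative instantaneous rates cannot occur for the defaults; if a parameter
#' choice produces a negative per-deflection mean it is clipped at 0 and the
#' number of clips is reported via `attr(., "n_clipped")`.
#'
#' @param cfg a [spikeSimConfig()].
#' @param trains wide trains table from [simulateTrainSet()].
#' @param pre_window_s,post_window_s recording window around the train (s).
#' @return list with `bundle` (a [SessionBundle-class]) and `truth`
#'   (per-unit data.frame: driven flag, planted c, gains, laser label).
#' @export
simulatePopulationSpikes <- function(cfg, trains, pre_window_s = 0.5,
                                     post_window_s = 0.5) {
  with_seed(cfg$seed, {
    truth <- do.call(rbind, lapply(names(cfg$n_units), .plant_layer, cfg = cfg))
    nU <- nrow(truth)
    truth$unit_id <- sprintf("u%03d", seq_len(nU))
    truth <- truth[c("unit_id", setdiff(names(truth), "unit_id"))]

    # pairwise L6 ensemble shuffle on weak-laser trials
    truth$laser_label <- "unchanged"
    l6 <- which(truth$layer == "L6")
    n_flip <- floor(cfg$opto_shuffle_fraction * length(l6) / 2) * 2
    swap_from <- integer(0); swap_to <- integer(0)
    if (n_flip >= 2) {
      dr <- l6[truth$driven[l6]]; nd <- l6[!truth$driven[l6]]
      k <- min(length(dr), length(nd), n_flip / 2)
      if (k > 0) {
        swap_from <- sample(dr, k); swap_to <- sample(nd, k)
        truth$laser_label[swap_from] <- "laser_suppressed"
        truth$laser_label[swap_to] <- "laser_facilitated"
      }
    }

    nT <- nrow(trains)
    nD_max <- max(trains$n_deflections)
    trial_len <- pre_window_s + (nD_max - 1) / 10 + 0.1 + post_window_s
    n_clipped <- 0L
    spikes <- vector("list", nU)

    # per-train geometry, precomputed
    geom <- lapply(seq_len(nT), function(i) {
      on <- train_onsets(trains, i)
      list(onsets = on, amps = train_amps(trains, i),
           adapt = cfg$adaptation(seq_along(on) - 1L),
           dev_idx = trains$deviant_index[i],
           dev_sign = trains$deviant_sign[i],
           baseline = trains$baseline_amplitude[i],
           laser = trains$opto_condition[i] == "weak_laser")
    })

    for (u in seq_len(nU)) {
      gain0 <- truth$response_gain[u]; ag0 <- truth$amplitude_gain[u]
      c0 <- truth$c_planted[u]
      # swapped parameters on laser trials
      partner <- if (u %in% swap_from) swap_to[match(u, swap_from)]
                 else if (u %in% swap_to) swap_from[match(u, swap_to)]
                 else NA_integer_
      all_t <- all_id <- vector("list", nT)
      for (i in seq_len(nT)) {
        g <- geom[[i]]
        if (g$laser && !is.na(partner)) {
          gain <- truth$response_gain[partner]
          ag <- truth$amplitude_gain[partner]
          cc <- truth$c_planted[partner]
        } else { gain <- gain0; ag <- ag0; cc <- c0 }
        m <- .evoked_mean(gain, ag, cc, g$amps, g$baseline, g$dev_idx,
                          g$dev_sign, g$adapt)
        if (any(m < 0)) { n_clipped <- n_clipped + sum(m < 0); m[m < 0] <- 0 }
        n_bg <- stats::rpois(1L, cfg$base_rate * trial_len)
        t_bg <- stats::runif(n_bg, 0, trial_len)
        n_ev <- stats::rpois(length(m), m)
        t_ev <- if (sum(n_ev)) {
          pre_window_s + rep(g$onsets, n_ev) +
            sample_kernel_times(sum(n_ev), cfg$kernel_latency_s, cfg$kernel_dur_s)
        } else numeric(0)
        tt <- sort(c(t_bg, t_ev))
        all_t[[i]] <- tt
        all_id[[i]] <- rep(trains$train_id[i], length(tt))
      }
      spikes[[u]] <- data.frame(unit_id = truth$unit_id[u],
                                train_id = unlist(all_id),
                                t_s = unlist(all_t),
                                stringsAsFactors = FALSE)
    }
    if (n_clipped > 0)
      warning(sprintf("%d negative per-deflection means clipped at 0", n_clipped))

    units <- data.frame(unit_id = truth$unit_id, depth_um = truth$depth_um,
                        waveform_width_ms = truth$waveform_width_ms,
                        stringsAsFactors = FALSE)
    bundle <- sessionBundle(
      trains, do.call(rbind, spikes), units,
      metadata = list(session_id = "synthetic", seed = cfg$seed,
                      pre_window_s = pre_window_s,
                      post_window_s = post_window_s))
    list(bundle = bundle, truth = truth)
  })
}

#' Simulate per-deflection counts for a population directly
#'
#' Count-level twin of [simulatePopulationSpikes()]: draws the per-deflection
#' window counts from the Poisson marginal implied by the spike-level model
#' (the deflection kernel lies inside the 100 ms count window, so the evoked
#' mean adds to `base_rate * window`). Used for population-scale calibration
#' and power studies where spike times are irrelevant.
#'
#' @param n_units number of units.
#' @param c_planted per-unit planted change coefficient (recycled).
#' @param n_increase,n_decrease,n_baseline numbers of amplitude-increase,
#'   amplitude-decrease and no-deviant trains.
#' @param response_gain,base_rate,adaptation,window_ms as in [spikeSimConfig()].
#' @param positions allowed 0-based deviant positions.
#' @param n_deflections deflections per train.
#' @param baseline_amps baseline amplitude (mm/s), scalar or vector sampled
#'   uniformly per train.
#' @param amplitude_gain evoked spikes per (mm/s) above the mean baseline
#'   amplitude.
#' @param deviant_frac relative deviant amplitude magnitude.
#' @param deviation_beta if non-`NULL`, the deviant deflection's mean is
#'   multiplied by `exp(deviation_beta * sign)` (a log-link rate-ratio effect)
#'   instead of receiving the additive `c_planted / 2` term.
#' @param seed RNG seed.
#' @return a [CountTensor-class]; planted coefficients in
#'   `attr(., "c_planted")`.
#' @export
simulateCountPopulation <- function(n_units, c_planted = 0,
                                    n_increase = 150L, n_decrease = 150L,
                                    n_baseline = 300L,
                                    response_gain = 0.1, base_rate = 1,
                                    adaptation = function(pos) 0.9^pos,
                                    window_ms = 100, positions = 1:5,
                                    n_deflections = 7L, baseline_amps = 25,
                                    amplitude_gain = 0, deviant_frac = 0.1,
                                    deviation_beta = NULL, seed = 1L) {
  with_seed(seed, {
    c_planted <- rep_len(c_planted, n_units)
    nT <- n_increase + n_decrease + n_baseline
    sign_t <- c(rep(1L, n_increase), rep(-1L, n_decrease), rep(0L, n_baseline))
    pos_draw <- if (length(positions) > 1L)
      sample(positions, nT, replace = TRUE) else rep(positions, nT)
    dev_t <- ifelse(sign_t == 0L, NA_integer_, pos_draw)
    amp_t <- if (length(baseline_amps) > 1L)
      sample(baseline_amps, nT, replace = TRUE) else rep(baseline_amps, nT)
    w <- window_ms / 1000
    adapt <- adaptation(seq_len(n_deflections) - 1L)

    # mean array (unit x train x deflection)
    m <- array(0, dim = c(n_units, nT, n_deflections))
    for (d in seq_len(n_deflections)) {
      md <- base_rate * w + adapt[d] *
        (response_gain + amplitude_gain * (amp_t - mean(amp_t)))
      m[, , d] <- rep(md, each = n_units)
    }
    dev_trains <- which(sign_t != 0L)
    for (i in dev_trains) {
      j <- dev_t[i] + 1L
      if (is.null(deviation_beta))
        m[, i, j] <- m[, i, j] + (c_planted / 2) * sign_t[i]
      else
        m[, i, j] <- m[, i, j] * exp(deviation_beta * sign_t[i])
    }
    m[m < 0] <- 0
    cnt <- array(stats::rpois(length(m), m), dim = dim(m),
                 dimnames = list(sprintf("u%03d", seq_len(n_units)),
                                 sprintf("tr%05d", seq_len(nT)), NULL))
    excl <- matrix(FALSE, nT, n_deflections)
    for (i in dev_trains)
      if (dev_t[i] + 2L <= n_deflections)
        excl[i, seq(dev_t[i] + 2L, n_deflections)] <- TRUE
    ti <- data.frame(
      train_id = dimnames(cnt)[[2]],
      deviant_index = dev_t, deviant_sign = sign_t,
      opto_condition = "control", baseline_amplitude = amp_t,
      deviant_amplitude = ifelse(is.na(dev_t), NA_real_,
                                 amp_t * (1 + deviant_frac * sign_t)),
      stringsAsFactors = FALSE)
    out <- new("CountTensor", counts = cnt, window_ms = window_ms,
               excluded = excl, train_info = ti)
    attr(out, "c_planted") <- c_planted
    out
  })
}
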