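# Shared fixtures, built in code at test time.

# Tiny session with hand-placed spikes: 2 units, 4 trains (one +deviant, one
# -deviant, two baseline), pre-window 0.5 s.
tiny_session <- function() {
  trains <- trainsToTable(list(
    buildTrain(25, train_id = "t1", deviant_index = 2, deviant_frac = 0.10),
    buildTrain(25, train_id = "t2", deviant_index = 2, deviant_frac = -0.10),
    buildTrain(25, train_id = "t3"),
    buildTrain(25, train_id = "t4")))
  # spike times are trial-relative; deflection d is at 0.5 + d/10
  spikes <- data.frame(
    unit_id = c("u1", "u1", "u1", "u2", "u2"),
    train_id = c("t1", "t1", "t2", "t3", "t4"),
    t_s = c(0.51, 0.72, 0.55, 0.62, 0.91))
  units <- data.frame(unit_id = c("u1", "u2"), depth_um = c(400, 700),
                      waveform_width_ms = c(0.6, 0.3))
  sessionBundle(trains, spikes, units,
                metadata = list(session_id = "tiny", pre_window_s = 0.5,
                                post_window_s = 0.5))
}

# Random session through the spike-level generator (small).
random_session <- function(seed = 1L, n_trains = 60L, n_units_l23 = 6L,
                           response_gain = 0.2) {
  trains <- simulateTrainSet(n_trains, seed = seed)
  cfg <- spikeSimConfig(
    n_units = c("L2/3" = n_units_l23, L4 = 2L, L5 = 0L, L6 = 2L),
    response_gain = response_gain, seed = seed + 1L)
  simulatePopulationSpikes(cfg, trains)
}

# Session of stimulus-independent units. rate_fun(t, trial_len) gives the
# instantaneous rate; spikes drawn by thinning. Used for classifier
# calibration (constant rate) and drift false-positive studies (ramp).
poisson_session <- function(n_units, n_trials, rate_fun, seed,
                            trial_len = 1.7, pre = 0.5) {
  set.seed(seed)
  trains <- simulateTrainSet(n_trials, p_deviant = 0, seed = seed)
  rmax <- max(rate_fun(seq(0, trial_len, by = 0.01), trial_len))
  sp <- lapply(seq_len(n_units), function(u) {
    n <- rpois(n_trials, rmax * trial_len)
    tt <- lapply(seq_len(n_trials), function(i) {
      t0 <- runif(n[i], 0, trial_len)
      t0[runif(n[i]) < rate_fun(t0, trial_len) / rmax]
    })
    data.frame(unit_id = sprintf("n%03d", u),
               train_id = rep(trains$train_id, lengths(tt)),
               t_s = unlist(tt))
  })
  units <- data.frame(unit_id = sprintf("n%03d", seq_len(n_units)),
                      depth_um = 300, waveform_width_ms = 0.6)
  sessionBundle(trains, do.call(rbind, sp), units,
                metadata = list(pre_window_s = pre, post_window_s = 0.5))
}

# Brute-force per-deflection counting: double loop over spikes.
naive_counts <- function(bundle, window_ms = 100) {
  trains <- trainTable(bundle); units <- unitTable(bundle)
  pre <- sessionMetadata(bundle)$pre_window_s
  sp <- spikeTable(bundle)
  w <- window_ms / 1000
  nD <- max(trains$n_deflections)
  out <- array(0L, dim = c(nrow(units), nrow(trains), nD),
               dimnames = list(units$unit_id, trains$train_id, NULL))
  for (k in seq_len(nrow(sp))) {
    u <- match(sp$unit_id[k], units$unit_id)
    i <- match(sp$train_id[k], trains$train_id)
    on <- pre + as.numeric(trains[i, sprintf("onset_%d",
                                             seq_len(trains$n_deflections[i]) - 1L)])
    for (d in seq_along(on)) {
      if (sp$t_s[k] >= on[d] && sp$t_s[k] < on[d] + w)
        out[u, i, d] <- out[u, i, d] + 1L
    }
  }
  out
}
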