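#' Simulate a go/no-go detection observer with a deviant benefit
#'
#' Trials carry a stimulus amplitude drawn uniformly over `amp_range` (with a
#' fraction of zero-amplitude catch trials and a fraction at the maximum).
#' The observer's hit probability follows the cumulative-Gaussian psychometric
#' curve; on deviant-containing trials with sub-threshold amplitude
#' (`amp < sub_threshold_frac * mu`) and deviant time within 400 ms, the hit
#' probability gains `deviant_benefit`. Reaction times include a small
#' fraction of impulsive (< 50 ms) licks and deviant times extend past 400 ms
#' so the exclusion rules are exercised.
#'
#' @param psych list with `mu` (threshold, mm/s), `sigma`, `guess`, `lapse`,
#'   `deviant_benefit`.
#' @param n_trials number of trials.
#' @param amp_range stimulus amplitude range (mm/s).
#' @param p_deviant fraction of trials containing a deviant.
#' @param p_catch fraction of zero-amplitude catch trials.
#' @param p_max fraction of maximum-amplitude trials.
#' @param sub_threshold_frac amplitude band (fraction of `mu`) receiving the
#'   deviant benefit.
#' @param seed RNG seed.
#' @return behavior trial data.frame: `amplitude`, `deviant_present`,
#'   `deviant_time_ms`, `response`, `reaction_time_ms`, `laser`, `session_id`,
#'   `d_prime`.
#' @export
simulateDetectionBehavior <- function(psych = list(mu = 15, sigma = 4,
                                                   guess = 0.08, lapse = 0.02,
                                                   deviant_benefit = 0.15),
                                      n_trials = 2000L,
                                      amp_range = c(0, 30), p_deviant = 0.5,
                                      p_catch = 0.1, p_max = 0.1,
                                      sub_threshold_frac = 0.6, seed = 1L) {
  assert_that(psych$mu > 0 && psych$sigma > 0, "mu and sigma must be positive")
  assert_that(psych$guess >= 0 && psych$lapse >= 0 &&
              psych$guess + psych$lapse < 1,
              "guess/lapse rates must be valid probabilities")
  with_seed(seed, {
    kind <- sample(c("catch", "max", "uniform"), n_trials, replace = TRUE,
                   prob = c(p_catch, p_max, 1 - p_catch - p_max))
    amp <- ifelse(kind == "catch", 0,
           ifelse(kind == "max", amp_range[2],
                  stats::runif(n_trials, amp_range[1], amp_range[2])))
    deviant <- stats::runif(n_trials) < p_deviant & amp > 0
    # deviant at train positions 2-6 (10 Hz): 200-600 ms; >400 ms trials
    # exist so the late-deviant filter has work to do
    dev_time <- ifelse(deviant, sample(seq(200, 600, by = 100), n_trials,
                                       replace = TRUE), NA_real_)
    p_hit <- .psy_curve(amp, psych$mu, psych$sigma, psych$guess, psych$lapse)
    boost <- deviant & amp < sub_threshold_frac * psych$mu &
      !is.na(dev_time) & dev_time <= 400
    p_hit <- pmin(p_hit + ifelse(boost, psych$deviant_benefit, 0),
                  1 - psych$lapse)
    licked <- stats::runif(n_trials) < ifelse(amp > 0, p_hit, psych$guess)
    response <- ifelse(amp > 0,
                       ifelse(licked, "hit", "miss"),
                       ifelse(licked, "false_alarm", "correct_reject"))
    rt <- rep(NA_real_, n_trials)
    rt[licked] <- stats::rlnorm(sum(licked), log(300), 0.3)
    impulsive <- licked & stats::runif(n_trials) < 0.02
    rt[impulsive] <- stats::runif(sum(impulsive), 5, 45)

    hits <- sum(response == "hit"); n_stim <- sum(amp > 0)
    fas <- sum(response == "false_alarm"); n_catch <- sum(amp == 0)
    dp <- if (n_catch > 0) dprime(hits / n_stim, fas / n_catch, n_stim, n_catch)
          else NA_real_
    data.frame(amplitude = amp, deviant_present = deviant,
               deviant_time_ms = dev_time, response = response,
               reaction_time_ms = rt, laser = FALSE,
               session_id = "sim", d_prime = dp,
               stringsAsFactors = FALSE)
  })
}
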