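# Psychometric analysis of the go/no-go detection task and proportion
# statistics for crossing behavior.

#' Signal-detection sensitivity d'
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with rates clipped to
#' `[1/(2N), 1 - 1/(2N)]` before the normal quantile.
#'
#' @param hit_rate,fa_rate observed rates.
#' @param n_hit,n_fa trial counts behind each rate (used for clipping);
#'   must be positive.
#' @return d' value.
#' @examples
#' dprime(0.84, 0.5, 100, 100)  # ~ 0.994
#' @export
dprime <- function(hit_rate, fa_rate, n_hit, n_fa) {
  assert_that(n_hit > 0 && n_fa > 0, "trial counts must be positive")
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hit_rate, n_hit)) - stats::qnorm(clip(fa_rate, n_fa))
}

.psy_curve <- function(a, mu, sigma, guess, lapse) {
  guess + (1 - guess - lapse) * stats::pnorm((a - mu) / sigma)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Binomial maximum-likelihood fit of
#' `P(hit | a) = guess + (1 - guess - lapse) * Phi((a - mu) / sigma)` to
#' stimulus trials. The threshold is the curve's median point — the amplitude
#' where the scaled curve crosses halfway between `guess` and `1 - lapse` —
#' which is `mu` under this parameterization. Subsequent analyses normalize
#' amplitudes by the threshold.
#'
#' @param trials data.frame with `amplitude` (> 0 for stimulus trials) and
#'   `response` (`"hit"`/`"miss"`; other responses ignored). If a `d_prime`
#'   column is present, trials below `d_prime_floor` are dropped first.
#' @param d_prime_floor sessions/trials below this d' are excluded
#'   (default 0.8).
#' @param fix_guess,fix_lapse optional fixed values (otherwise fitted, bounded
#'   to `[0, 0.5]` / `[0, 0.2]`).
#' @return a [PsychometricFit-class]; non-identifiable data (single response
#'   class, or < 4 amplitude levels) gives `converged = FALSE`.
#' @export
fitPsychometric <- function(trials, d_prime_floor = 0.8, fix_guess = NULL,
                            fix_lapse = NULL) {
  if ("d_prime" %in% names(trials))
    trials <- trials[trials$d_prime > d_prime_floor, , drop = FALSE]
  trials <- trials[trials$response %in% c("hit", "miss") &
                   trials$amplitude > 0, , drop = FALSE]
  a <- trials$amplitude
  y <- as.numeric(trials$response == "hit")
  bad <- length(unique(y)) < 2L || length(unique(round(a, 6))) < 4L ||
    nrow(trials) < 100L
  if (bad)
    return(new("PsychometricFit", mu = NA_real_, sigma = NA_real_,
               guess = NA_real_, lapse = NA_real_, converged = FALSE,
               loglik = NA_real_))
  nll <- function(par) {
    mu <- par[1]; sigma <- par[2]
    g <- fix_guess %||% par[3]
    l <- fix_lapse %||% par[length(par)]
    p <- .psy_curve(a, mu, sigma, g, l)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  p0 <- c(stats::median(a), stats::sd(a) / 2)
  lo <- c(1e-6, 1e-6); hi <- c(max(a) * 2, max(a))
  if (is.null(fix_guess)) { p0 <- c(p0, 0.05); lo <- c(lo, 0); hi <- c(hi, 0.5) }
  if (is.null(fix_lapse)) { p0 <- c(p0, 0.02); lo <- c(lo, 0); hi <- c(hi, 0.2) }
  opt <- stats::optim(p0, nll, method = "L-BFGS-B", lower = lo, upper = hi)
  g <- fix_guess %||% opt$par[3]
  l <- fix_lapse %||% opt$par[length(opt$par)]
  new("PsychometricFit", mu = opt$par[1], sigma = opt$par[2],
      guess = g, lapse = l, converged = opt$convergence == 0,
      loglik = -opt$value)
}

#' Apply the behavioral trial filters
#'
#' Named exclusion rules, each returning an audit count:
#' `dprime` — drop trials whose session d' is at or below `d_prime_floor`
#' (default 1.2); `early_response` — drop responses within `rt_min_ms` of
#' stimulus onset (licks not elicited by the stimulus); `late_deviant` — drop
#' trials whose deviant occurs after `deviant_max_ms` (too late to aid
#' detection).
#'
#' @param trials behavior trial data.frame (columns used: `d_prime`,
#'   `reaction_time_ms`, `deviant_time_ms` as applicable).
#' @param rules character subset of the rules to apply (default all present).
#' @param d_prime_floor,rt_min_ms,deviant_max_ms rule parameters.
#' @return list `trials` (filtered) and `audit` (named removal counts).
#' @export
filterTrials <- function(trials,
                         rules = c("dprime", "early_response", "late_deviant"),
                         d_prime_floor = 1.2, rt_min_ms = 50,
                         deviant_max_ms = 400) {
  audit <- stats::setNames(integer(length(rules)), rules)
  for (r in rules) {
    keep <- switch(r,
      dprime = if ("d_prime" %in% names(trials))
        trials$d_prime > d_prime_floor else TRUE,
      early_response = !(trials$response %in% c("hit", "false_alarm") &
                         !is.na(trials$reaction_time_ms) &
                         trials$reaction_time_ms < rt_min_ms),
      late_deviant = !(!is.na(trials$deviant_time_ms) &
                       trials$deviant_time_ms > deviant_max_ms),
      stop("unknown rule: ", r, call. = FALSE))
    keep[is.na(keep)] <- TRUE
    audit[r] <- sum(!keep)
    trials <- trials[keep, , drop = FALSE]
  }
  list(trials = trials, audit = audit)
}

#' Clopper-Pearson exact binomial interval
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, positive.
#' @param level confidence level (default 0.95).
#' @return `c(lo, hi)`.
#' @export
hitRateCi <- function(k, n, level = 0.95) {
  assert_that(n > 0, "n must be positive")
  assert_that(k >= 0 && k <= n, "need 0 <= k <= n")
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Bootstrap comparison of two binomial rates
#'
#' Two-sided p-value for a difference between `kA/nA` and `kB/nB` from
#' `n_boot` parametric bootstrap draws of each binomial; used for the
#' deviant-benefit and gap-crossing probability contrasts. Symmetric in A/B.
#'
#' @param kA,nA,kB,nB successes and trials per group.
#' @param n_boot bootstrap samples (default 10000).
#' @param seed RNG seed.
#' @return two-sided p-value.
#' @export
compareRatesBootstrap <- function(kA, nA, kB, nB, n_boot = 10000L, seed = 1L) {
  assert_that(nA > 0 && nB > 0, "trial counts must be positive")
  d <- with_seed(seed, {
    stats::rbinom(n_boot, nA, kA / nA) / nA -
      stats::rbinom(n_boot, nB, kB / nB) / nB
  })
  pl <- (sum(d < 0) + 0.5 * sum(d == 0) + 0.5) / (n_boot + 1)
  pg <- (sum(d > 0) + 0.5 * sum(d == 0) + 0.5) / (n_boot + 1)
  min(1, 2 * min(pl, pg))
}

#' Deviant detection benefit on sub-threshold stimuli
#'
#' Full pipeline for the head-fixed contrast: filter trials, fit the
#' psychometric curve on deviant-free trials, normalize amplitudes by the
#' threshold, and bootstrap-compare hit rates between deviant and deviant-free
#' trials at normalized amplitudes below `sub_threshold_frac`.
#'
#' @param trials behavior trial table (see [simulateDetectionBehavior()]).
#' @param sub_threshold_frac analysis band: amplitudes below this fraction of
#'   threshold (default 0.6).
#' @param n_boot,seed bootstrap controls.
#' @param ... passed to [filterTrials()].
#' @return list: `fit`, `uplift` (hit-rate difference), `p`,
#'   `rates` (k/n per group), `audit`.
#' @export
deviantBenefit <- function(trials, sub_threshold_frac = 0.6, n_boot = 10000L,
                           seed = 1L, ...) {
  flt <- filterTrials(trials, ...)
  tr <- flt$trials
  fit <- fitPsychometric(tr[!tr$deviant_present, , drop = FALSE])
  if (!fit@converged) stop("psychometric fit non-identifiable", call. = FALSE)
  tr$norm_amp <- tr$amplitude / fit@mu
  band <- tr$norm_amp > 0 & tr$norm_amp < sub_threshold_frac &
    tr$response %in% c("hit", "miss")
  dev <- tr[band & tr$deviant_present, ]
  bas <- tr[band & !tr$deviant_present, ]
  kA <- sum(dev$response == "hit"); nA <- nrow(dev)
  kB <- sum(bas$response == "hit"); nB <- nrow(bas)
  p <- compareRatesBootstrap(kA, nA, kB, nB, n_boot = n_boot, seed = seed)
  list(fit = fit, uplift = kA / nA - kB / nB, p = p,
       rates = c(k_deviant = kA, n_deviant = nA, k_baseline = kB,
                 n_baseline = nB),
       audit = flt$audit)
}
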