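# Core change-coding statistics: per-unit change coefficients, grouped deviant
# effects, surrogate-null populations and broadening tests.

# First-deviant deflection references (train row, 0-based position) by sign.
.deviant_refs <- function(ti, condition = NULL) {
  keep <- ti$deviant_sign != 0L & !is.na(ti$deviant_index)
  if (!is.null(condition)) keep <- keep & ti$opto_condition == condition
  data.frame(train = which(keep), position = ti$deviant_index[keep],
             sign = ti$deviant_sign[keep])
}

# Baseline deflection references: all non-excluded deflections of no-deviant
# trains (one row per train x position).
.baseline_refs <- function(ti, excluded, condition = NULL) {
  keep <- ti$deviant_sign == 0L
  if (!is.null(condition)) keep <- keep & ti$opto_condition == condition
  rows <- which(keep)
  nD <- ncol(excluded)
  out <- data.frame(
    train = rep(rows, each = nD),
    position = rep(seq_len(nD) - 1L, times = length(rows)))
  out[!excluded[cbind(out$train, out$position + 1L)], , drop = FALSE]
}

# Flatten (train, 0-based position) refs to column indices of the unit x
# (train*deflection) matrix view of the count tensor.
.ref_cols <- function(refs, nT) refs$train + nT * refs$position

.count_matrix <- function(ct) {
  d <- dim(ct@counts)
  matrix(ct@counts, d[1L], d[2L] * d[3L], dimnames = list(dimnames(ct@counts)[[1L]], NULL))
}

# Subsample both ref sets so their per-position histograms both equal the
# per-position minimum.
.match_pair_positions <- function(refs_a, refs_b) {
  pos <- union(unique(refs_a$position), unique(refs_b$position))
  ia <- ib <- integer(0)
  for (p in pos) {
    a <- which(refs_a$position == p); b <- which(refs_b$position == p)
    m <- min(length(a), length(b))
    if (m == 0L) next
    ia <- c(ia, if (length(a) > m) a[sample.int(length(a), m)] else a)
    ib <- c(ib, if (length(b) > m) b[sample.int(length(b), m)] else b)
  }
  list(a = refs_a[sort(ia), , drop = FALSE], b = refs_b[sort(ib), , drop = FALSE])
}

#' Per-unit change coefficients
#'
#' For each unit, the mean spike count per deflection over amplitude-increase
#' deviant deflections minus the mean over amplitude-decrease deviant
#' deflections. Only the first (and, in these designs, only) deviant of each
#' train enters; the increase and decrease sets are position-matched by
#' per-position subsampling of the larger set so adaptation state is balanced.
#'
#' @param ct a [CountTensor-class].
#' @param condition optional opto condition filter (e.g. `"control"`).
#' @param units optional unit metadata data.frame (joined by `unit_id`).
#' @param seed RNG seed for the position-matching subsample.
#' @return a [ChangeCoefficientSet-class]. Units lacking deviant trials of
#'   either sign are dropped and listed in the provenance.
#' @export
changeCoefficient <- function(ct, condition = NULL, units = NULL, seed = 1L) {
  ti <- ct@train_info
  refs <- .deviant_refs(ti, condition)
  inc <- refs[refs$sign > 0L, ]; dec <- refs[refs$sign < 0L, ]
  if (nrow(inc) == 0L || nrow(dec) == 0L)
    stop("need deviant trains of both signs", call. = FALSE)
  matched <- with_seed(seed, .match_pair_positions(inc, dec))
  nT <- dim(ct@counts)[2L]
  cm <- .count_matrix(ct)
  mi <- rowMeans(cm[, .ref_cols(matched$a, nT), drop = FALSE])
  md <- rowMeans(cm[, .ref_cols(matched$b, nT), drop = FALSE])
  cf <- data.frame(unit_id = rownames(cm), coeff = mi - md,
                   n_increase = nrow(matched$a), n_decrease = nrow(matched$b),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(units))
    cf <- merge(cf, units, by = "unit_id", sort = FALSE)
  new("ChangeCoefficientSet", coefficients = cf,
      condition = condition %||% "all",
      provenance = list(matched_on = "position",
                        n_increase = nrow(matched$a),
                        n_decrease = nrow(matched$b),
                        position_histogram = table(matched$a$position)))
}

#' Grouped deviant effect on firing
#'
#' Groups amplitude increases and decreases together and contrasts deviant
#' deflection counts with position-matched baseline deflections from
#' no-deviant trains: per-unit mean difference, population signed-rank p and
#' bootstrap CI of the median. A population median near zero with symmetric
#' planted coefficients indicates deviants do not change overall rates.
#'
#' @inheritParams changeCoefficient
#' @param n_boot bootstrap resamples for the median CI.
#' @return list with `effects` (per-unit data.frame), `p_signed_rank`,
#'   `ci_median` (`[lo, med, hi]`).
#' @export
groupedDeviantEffect <- function(ct, condition = NULL, n_boot = 1000L,
                                 seed = 1L) {
  ti <- ct@train_info
  dev <- .deviant_refs(ti, condition)
  base <- .baseline_refs(ti, ct@excluded, condition)
  if (nrow(dev) == 0L) stop("no deviant trains", call. = FALSE)
  ms <- histogramMatchPositions(dev, base, seed = seed)
  nT <- dim(ct@counts)[2L]
  cm <- .count_matrix(ct)
  eff <- rowMeans(cm[, .ref_cols(ms@set_a, nT), drop = FALSE]) -
    rowMeans(cm[, .ref_cols(ms@set_b, nT), drop = FALSE])
  p <- stats::wilcox.test(eff, exact = FALSE)$p.value
  ci <- with_seed(seed + 1L, .boot_median_ci(eff, n_boot))
  list(effects = data.frame(unit_id = rownames(cm), effect = eff,
                            row.names = NULL, stringsAsFactors = FALSE),
       p_signed_rank = p, ci_median = ci)
}

.boot_median_ci <- function(x, n_boot) {
  n <- length(x)
  meds <- vapply(seq_len(n_boot), function(b)
    stats::median(x[sample.int(n, n, replace = TRUE)]), numeric(1))
  c(lo = unname(stats::quantile(meds, 0.025)), med = stats::median(x),
    hi = unname(stats::quantile(meds, 0.975)))
}

#' Surrogate null population of pseudo change coefficients
#'
#' Each draw resamples position-matched baseline deflections (from no-deviant
#' trains) into two pseudo-groups with the true increase/decrease position
#' histograms, then computes each unit's pseudo-coefficient from its own
#' counts on those deflections. Sampling is without replacement within a
#' draw. Because the null is built from every cell's own trial-to-trial
#' variability, it inherits cell-dependent count variance exactly as the
#' observed distribution does.
#'
#' @param ct a [CountTensor-class].
#' @param n_draws number of surrogate populations.
#' @param condition optional opto condition filter.
#' @param seed RNG seed.
#' @return a [SurrogatePopulation-class] (`n_draws` x units).
#' @export
surrogatePopulation <- function(ct, n_draws = 1000L, condition = NULL,
                                seed = 1L) {
  ti <- ct@train_info
  dev <- .deviant_refs(ti, condition)
  base <- .baseline_refs(ti, ct@excluded, condition)
  inc <- dev[dev$sign > 0L, ]; dec <- dev[dev$sign < 0L, ]
  matched <- with_seed(seed, .match_pair_positions(inc, dec))
  want <- table(factor(matched$a$position))  # per-position group size (equal for both groups)
  pos_levels <- as.integer(names(want))
  pools <- lapply(pos_levels, function(p) which(base$position == p))
  need <- 2L * as.integer(want)
  short <- pos_levels[vapply(pools, length, integer(1)) < need]
  if (length(short))
    stop("insufficient baseline pool at position(s): ",
         paste(short, collapse = ", "), call. = FALSE)
  nT <- dim(ct@counts)[2L]
  cm <- .count_matrix(ct)
  base_cols <- .ref_cols(base, nT)
  draws <- with_seed(seed + 1L, {
    t(vapply(seq_len(n_draws), function(k) {
      ga <- gb <- integer(0)
      for (j in seq_along(pos_levels)) {
        pick <- pools[[j]][sample.int(length(pools[[j]]), need[j])]
        ga <- c(ga, pick[seq_len(need[j] / 2L)])
        gb <- c(gb, pick[seq(need[j] / 2L + 1L, need[j])])
      }
      rowMeans(cm[, base_cols[ga], drop = FALSE]) -
        rowMeans(cm[, base_cols[gb], drop = FALSE])
    }, numeric(nrow(cm))))
  })
  new("SurrogatePopulation", draws = draws, n_draws = as.integer(n_draws),
      seed = as.integer(seed))
}

#' Population broadening test against the surrogate null
#'
#' Quantifies whether the observed change-coefficient population is broader
#' than its within-cell surrogate null via the interquartile range
#' (75th - 25th percentile) and Shannon entropy in bits,
#' `H(h) = -sum_i P(h_i) log2 P(h_i)`, computed on shared equal-width bin
#' edges spanning the pooled range. One-sided p-values use the add-one
#' surrogate convention `p = (1 + #{draw >= observed}) / (1 + n_draws)`.
#' A median-shift test (signed rank vs 0, with a bootstrap CI of the median)
#' is reported alongside: a uniformly shifted population moves the median
#' without broadening, a heterogeneous two-signed population broadens without
#' shifting.
#'
#' @param obs a [ChangeCoefficientSet-class].
#' @param surr a [SurrogatePopulation-class] built from the same tensor.
#' @param cfg config list from [readConfig()] (uses `entropy_bins`,
#'   `bootstrap_draws`).
#' @param min_units floor on population size (default 20).
#' @param seed RNG seed for the median bootstrap.
#' @return a [BroadeningStats-class].
#' @export
broadeningTest <- function(obs, surr, cfg = readConfig(), min_units = 20L,
                           seed = 1L) {
  x <- obs@coefficients$coeff
  assert_that(length(x) >= min_units,
              sprintf("broadening test needs >= %d units", min_units))
  S <- surr@draws
  assert_that(ncol(S) == length(x),
              "surrogate population does not match the observed units")
  nb <- cfg$entropy_bins
  rng <- range(c(x, S))
  edges <- seq(rng[1] - 1e-12, rng[2] + 1e-12, length.out = nb + 1L)

  iqr_obs <- iqr75_25(x)
  iqr_draws <- apply(S, 1L, iqr75_25)
  h_obs <- entropy_bits(.bin_counts(x, edges))
  h_draws <- apply(S, 1L, function(s) entropy_bits(.bin_counts(s, edges)))
  K <- nrow(S)
  ci <- with_seed(seed, .boot_median_ci(x, cfg$bootstrap_draws))
  new("BroadeningStats",
      iqr_obs = iqr_obs,
      iqr_surr = stats::median(iqr_draws),
      delta_H = h_obs - stats::median(h_draws),
      bin_edges = edges,
      p_iqr = (1 + sum(iqr_draws >= iqr_obs)) / (1 + K),
      p_entropy = (1 + sum(h_draws >= h_obs)) / (1 + K),
      p_median_shift = stats::wilcox.test(x, exact = FALSE)$p.value,
      ci_median = unname(ci))
}

#' Shannon entropy of a histogram, in bits
#'
#' `H(h) = -sum_i P(h_i) log2 P(h_i)` over the bins of `counts`; empty bins
#' contribute zero. A uniform histogram over `k` bins has `H = log2(k)`.
#'
#' @param counts non-negative bin counts.
#' @return entropy in bits.
#' @export
shannonEntropy <- function(counts) {
  assert_that(all(counts >= 0) && sum(counts) > 0,
              "counts must be non-negative with positive total")
  entropy_bits(counts)
}

.bin_counts <- function(x, edges) {
  tabulate(pmin(pmax(findInterval(x, edges), 1L), length(edges) - 1L),
           nbins = length(edges) - 1L)
}

#' Paired sharpening test across conditions
#'
#' For units measured in both conditions, compares the spread statistic
#' `S = median_u |coeff_u - median(coeff)|` between control and laser via a
#' bootstrap over units of `dS = S_control - S_laser`. The one-sided p-value
#' for sharpening (laser narrower than control, `dS > 0`) is the bootstrap
#' fraction of `dS* <= 0`, with ties counted half.
#'
#' @param coeff_control,coeff_laser per-unit coefficients, paired by position.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return list with `dS`, `p_sharpening`, `ci` (95% bootstrap CI of `dS`).
#' @export
pairedConditionTest <- function(coeff_control, coeff_laser, n_boot = 10000L,
                                seed = 1L) {
  assert_that(length(coeff_control) == length(coeff_laser),
              "paired test needs equal-length, unit-paired inputs")
  n <- length(coeff_control)
  assert_that(n >= 2L, "paired test needs at least two units")
  spread <- function(x) stats::median(abs(x - stats::median(x)))
  dS <- spread(coeff_control) - spread(coeff_laser)
  ds_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      spread(coeff_control[idx]) - spread(coeff_laser[idx])
    }, numeric(1))
  })
  p <- (sum(ds_boot < 0) + 0.5 * sum(ds_boot == 0) + 0.5) / (n_boot + 1)
  list(dS = dS, p_sharpening = p,
       ci = unname(stats::quantile(ds_boot, c(0.025, 0.975))))
}
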