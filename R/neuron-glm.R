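# Penalized per-neuron Poisson GLM for deviation encoding.

#' Build the quadratic penalty matrix
#'
#' `Q = ridge_weight * I + diff_weight * D'D`, where the identity part is
#' zeroed on the constant term and `D` is the first-difference operator over
#' adjacent adaptation-position coefficients only. The penalized objective
#' adds `0.5 * w' Q w`, i.e. `0.5 * (ridge * sum w_j^2 + diff * sum (a_k -
#' a_{k+1})^2)`.
#'
#' @param n_params total number of coefficients.
#' @param adaptation_idx column indices of the adaptation block (ordered by
#'   deflection position).
#' @param constant_idx index of the unpenalized constant (default 1).
#' @param ridge_weight,diff_weight penalty weights (defaults 1 and 10).
#' @return symmetric positive semidefinite matrix.
#' @export
buildPenalty <- function(n_params, adaptation_idx, constant_idx = 1L,
                         ridge_weight = 1, diff_weight = 10) {
  assert_that(!constant_idx %in% adaptation_idx,
              "constant and adaptation blocks overlap")
  assert_that(all(adaptation_idx >= 1L & adaptation_idx <= n_params),
              "adaptation block indices out of range")
  Q <- diag(ridge_weight, n_params)
  Q[constant_idx, constant_idx] <- 0
  k <- length(adaptation_idx)
  if (k >= 2L && diff_weight != 0) {
    D <- matrix(0, k - 1L, k)
    D[cbind(seq_len(k - 1L), seq_len(k - 1L))] <- 1
    D[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- -1
    Q[adaptation_idx, adaptation_idx] <-
      Q[adaptation_idx, adaptation_idx] + diff_weight * crossprod(D)
  }
  Q
}

#' Build a per-neuron GLM design from a count tensor
#'
#' One row per analyzed (non-excluded) deflection: constant; signed deviation
#' regressor (-1 decrease, +1 increase, 0 on baseline deflections);
#' session-standardized baseline amplitude; spike-count history of the seven
#' preceding deflection windows (zero-padded before the train start); and one
#' adaptation indicator per deflection position.
#'
#' @param ct a [CountTensor-class].
#' @param unit unit index or id.
#' @param n_history preceding deflections whose counts enter as history
#'   features (default 7).
#' @param ridge_weight,diff_weight penalty weights for [buildPenalty()].
#' @param deviation_mode `"signed"` (one -1/+1 regressor) or `"split"` (one
#'   indicator per deviant direction).
#' @param drop_reference drop the position-0 adaptation indicator (treat it as
#'   the reference level). The penalized default keeps all positions — the
#'   penalty handles the aliasing with the constant — but an unpenalized fit
#'   needs a full-rank design.
#' @return a [GlmDesign-class].
#' @export
buildGlmDesign <- function(ct, unit, n_history = 7L, ridge_weight = 1,
                           diff_weight = 10, deviation_mode = c("signed", "split"),
                           drop_reference = FALSE) {
  deviation_mode <- match.arg(deviation_mode)
  if (is.character(unit)) unit <- match(unit, dimnames(ct@counts)[[1L]])
  ti <- ct@train_info
  cntu <- ct@counts[unit, , , drop = TRUE]   # train x deflection
  nT <- nrow(cntu); nD <- ncol(cntu)
  keep <- !ct@excluded
  tr <- rep(seq_len(nT), times = nD)[keep]
  pos <- rep(seq_len(nD) - 1L, each = nT)[keep]   # 0-based
  Y <- cntu[cbind(tr, pos + 1L)]

  dev_sig <- ifelse(!is.na(ti$deviant_index[tr]) & ti$deviant_index[tr] == pos,
                    ti$deviant_sign[tr], 0)
  amp <- ti$baseline_amplitude[tr]
  amp_std <- if (stats::sd(amp) > 0) (amp - mean(amp)) / stats::sd(amp) else amp * 0
  hist <- sapply(seq_len(n_history), function(h) {
    prev <- pos - h
    out <- numeric(length(tr))
    ok <- prev >= 0L
    out[ok] <- cntu[cbind(tr[ok], prev[ok] + 1L)]
    out
  })
  colnames(hist) <- sprintf("history_%d", seq_len(n_history))
  adapt_pos <- if (drop_reference) seq_len(nD - 1L) else seq_len(nD) - 1L
  adapt <- sapply(adapt_pos, function(p) as.numeric(pos == p))
  colnames(adapt) <- sprintf("adapt_%d", adapt_pos)

  if (deviation_mode == "signed") {
    devX <- matrix(dev_sig, ncol = 1L, dimnames = list(NULL, "deviation"))
  } else {
    devX <- cbind(deviation_up = as.numeric(dev_sig > 0),
                  deviation_down = as.numeric(dev_sig < 0))
  }
  X <- cbind(constant = 1, devX,
             baseline_amplitude = amp_std, hist, adapt)
  blocks <- list(
    constant = 1L,
    deviation = 1L + seq_len(ncol(devX)),
    baseline_amplitude = 1L + ncol(devX) + 1L,
    history = 1L + ncol(devX) + 1L + seq_len(n_history),
    adaptation = 1L + ncol(devX) + 1L + n_history + seq_along(adapt_pos))
  Q <- buildPenalty(ncol(X), blocks$adaptation, blocks$constant,
                    ridge_weight, diff_weight)
  new("GlmDesign", Y = as.numeric(Y), X = X, blocks = blocks, Q = Q)
}

#' Fit the penalized Poisson GLM
#'
#' Minimizes the Poisson negative log-likelihood (log link) plus
#' `0.5 * w' Q w` by damped Newton iteration. The problem is convex, so the
#' objective decreases monotonically (step halving enforces it) and
#' convergence is declared when the L2 norm of the penalized gradient falls
#' below `tol`.
#'
#' @param design a [GlmDesign-class].
#' @param tol gradient-norm tolerance (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @param w0 optional start (default: log mean rate in the constant, 0 else).
#' @return a [GlmFit-class]; a fit that fails to reach `tol` is returned with
#'   `converged = FALSE`, never silently.
#' @export
fitPenalizedGlm <- function(design, tol = 1e-8, max_iter = 200L, w0 = NULL) {
  X <- design@X; Y <- design@Y; Q <- design@Q
  p <- ncol(X)
  w <- if (is.null(w0)) c(log(mean(Y) + 1e-8), rep(0, p - 1L)) else w0
  obj <- function(w) {
    eta <- drop(X %*% w)
    sum(exp(eta)) - sum(Y * eta) + 0.5 * drop(crossprod(w, Q %*% w))
  }
  f <- obj(w)
  trace_obj <- f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% w)
    mu <- exp(eta)
    g <- drop(crossprod(X, mu - Y)) + drop(Q %*% w)
    gn <- sqrt(sum(g^2))
    if (gn < tol) { converged <- TRUE; break }
    H <- crossprod(X * sqrt(mu)) + Q
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, p), g))
    # damped: halve until the objective decreases
    lam <- 1
    repeat {
      w_new <- w - lam * step
      f_new <- obj(w_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-12) { w_new <- w; f_new <- f; break }
    }
    w <- w_new; f <- f_new
    trace_obj <- c(trace_obj, f)
  }
  eta <- drop(X %*% w)
  g <- drop(crossprod(X, exp(eta) - Y)) + drop(Q %*% w)
  fit <- new("GlmFit", w = stats::setNames(w, colnames(X)), objective = f,
             gradient_norm = sqrt(sum(g^2)), converged = converged,
             ci = matrix(numeric(0), 0, 2))
  attr(fit, "objective_trace") <- trace_obj
  fit
}

#' Bootstrap confidence intervals for the penalized GLM
#'
#' Resamples deflection rows with replacement, refits, and reports 2.5/97.5
#' percentile intervals per coefficient. Non-converged bootstrap fits are
#' excluded (with a warning when they exceed 5% of draws).
#'
#' @param design a [GlmDesign-class] with at least 50 rows.
#' @param n_boot bootstrap draws (default 100).
#' @param seed RNG seed.
#' @param tol passed to [fitPenalizedGlm()].
#' @return matrix (coefficients x `c("lo", "hi")`).
#' @export
bootstrapGlmCi <- function(design, n_boot = 100L, seed = 1L, tol = 1e-8) {
  assert_that(n_boot >= 1L, "n_boot must be positive")
  n <- length(design@Y)
  assert_that(n >= 50L, "bootstrap CIs need >= 50 observations")
  W <- with_seed(seed, {
    reps <- lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- new("GlmDesign", Y = design@Y[idx],
               X = design@X[idx, , drop = FALSE],
               blocks = design@blocks, Q = design@Q)
      fit <- fitPenalizedGlm(d, tol = tol)
      if (fit@converged) fit@w else NULL
    })
    do.call(rbind, reps)
  })
  n_fail <- n_boot - nrow(W)
  if (n_fail / n_boot > 0.05)
    warning(sprintf("%d of %d bootstrap fits did not converge", n_fail, n_boot))
  ci <- t(apply(W, 2L, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ci) <- c("lo", "hi")
  ci
}

#' False-positive rate of the deviation coefficient on null designs
#'
#' Fits each null design (baseline-only deflections with relabeled deviants)
#' and reports the fraction whose bootstrap CI for the deviation coefficient
#' excludes zero. Calibrated at ~`1 - level` for honest CIs.
#'
#' @param null_designs list of [GlmDesign-class] built from deviant-free data
#'   with random relabels.
#' @param n_boot,seed,tol as in [bootstrapGlmCi()].
#' @return list `rate`, `n`, per-design exclusion flags.
#' @export
glmFalsePositiveRate <- function(null_designs, n_boot = 100L, seed = 1L,
                                 tol = 1e-8) {
  assert_that(length(null_designs) > 0, "need at least one null design")
  excl <- vapply(seq_along(null_designs), function(i) {
    d <- null_designs[[i]]
    ci <- bootstrapGlmCi(d, n_boot = n_boot, seed = seed + i, tol = tol)
    j <- d@blocks$deviation[1L]
    ci[j, "lo"] > 0 || ci[j, "hi"] < 0
  }, logical(1))
  list(rate = mean(excl), n = length(excl), excluded_zero = excl)
}

#' Relabel a deviant-free tensor with fake deviants (null designs)
#'
#' Assigns random deviant positions/signs to no-deviant trains so the
#' deviation regressor is pure noise; used to calibrate false-positive rates.
#'
#' @param ct a [CountTensor-class] (only its no-deviant trains are used).
#' @param unit unit index or id.
#' @param seed RNG seed.
#' @param positions allowed 0-based fake-deviant positions.
#' @param ... passed to [buildGlmDesign()].
#' @return a [GlmDesign-class].
#' @export
nullRelabelDesign <- function(ct, unit, seed = 1L, positions = 1:5, ...) {
  ti <- ct@train_info
  base_tr <- which(ti$deviant_sign == 0L)
  with_seed(seed, {
    nfake <- floor(length(base_tr) / 2)
    fake <- sample(base_tr, nfake)
    ti$deviant_index[fake] <- sample(positions, nfake, replace = TRUE)
    ti$deviant_sign[fake] <- sample(c(-1L, 1L), nfake, replace = TRUE)
    keep <- ti$deviant_sign != 0L | seq_len(nrow(ti)) %in% base_tr
    ct2 <- ct
    ct2@train_info <- ti[keep, , drop = FALSE]
    ct2@counts <- ct@counts[, keep, , drop = FALSE]
    excl <- ct@excluded[keep, , drop = FALSE]
    # recompute exclusion for the fake deviants
    for (r in seq_len(nrow(ct2@train_info))) {
      di <- ct2@train_info$deviant_index[r]
      if (!is.na(di) && di + 2L <= ncol(excl))
        excl[r, seq(di + 2L, ncol(excl))] <- TRUE
    }
    ct2@excluded <- excl
    buildGlmDesign(ct2, unit, ...)
  })
}
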