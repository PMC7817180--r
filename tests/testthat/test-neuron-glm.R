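glm_tensor <- function(seed = 81L, beta = NULL, n = 150L,
                       response_gain = 0.3) {
  simulateCountPopulation(1, n_increase = n, n_decrease = n,
                          n_baseline = 2L * n, response_gain = response_gain,
                          baseline_amps = c(22, 25, 28),
                          deviation_beta = beta, seed = seed)
}

test_that("penalty matrix expands to ridge plus pairwise differences", {
  # two adaptation parameters a, b: 0.5 w'Qw = 0.5 (a^2 + b^2 + 10 (a-b)^2)
  Q <- buildPenalty(3, adaptation_idx = 2:3)
  w <- c(5, 1.5, -0.5)
  a <- w[2]; b <- w[3]
  expect_equal(0.5 * drop(t(w) %*% Q %*% w),
               0.5 * (1 * (a^2 + b^2) + 10 * (a - b)^2))
  # the constant is unpenalized
  expect_equal(Q[1, 1], 0)
  # diff_weight = 0 leaves a pure ridge off the constant
  Q0 <- buildPenalty(4, adaptation_idx = 3:4, diff_weight = 0)
  expect_equal(Q0, diag(c(0, 1, 1, 1)))
  expect_error(buildPenalty(3, adaptation_idx = 1:2), "overlap")
})

test_that("penalty matrices are positive semidefinite at random sizes", {
  set.seed(82)
  for (k in 1:6) {
    p <- sample(4:20, 1)
    na <- sample(2:(p - 2), 1)
    Q <- buildPenalty(p, adaptation_idx = (p - na + 1):p,
                      ridge_weight = runif(1, 0, 2),
                      diff_weight = runif(1, 0, 20))
    expect_gte(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the zero-penalty fit matches the reference Poisson IRLS fit", {
  ct <- glm_tensor(seed = 83, beta = 0.4)
  d <- buildGlmDesign(ct, 1, n_history = 6, ridge_weight = 0,
                      diff_weight = 0, drop_reference = TRUE)
  fit <- fitPenalizedGlm(d)
  expect_true(fit@converged)
  ref <- stats::glm.fit(d@X, d@Y, family = stats::poisson())
  expect_lt(max(abs(fit@w - ref$coefficients)), 1e-6)
})

test_that("a huge difference weight forces the adaptation profile flat", {
  ct <- glm_tensor(seed = 84)
  d <- buildGlmDesign(ct, 1, diff_weight = 1e6)
  fit <- fitPenalizedGlm(d)
  a <- fit@w[d@blocks$adaptation]
  expect_lt(max(abs(diff(a))), 1e-3)
})

test_that("the objective decreases monotonically and restarts agree", {
  ct <- glm_tensor(seed = 85, beta = 0.3)
  d <- buildGlmDesign(ct, 1)
  fit <- fitPenalizedGlm(d)
  tr <- attr(fit, "objective_trace")
  expect_true(all(diff(tr) <= 1e-9))
  expect_lt(fit@gradient_norm, 1e-8)
  # convexity: random restarts converge to the same optimum
  set.seed(86)
  for (r in 1:3) {
    f2 <- fitPenalizedGlm(d, w0 = rnorm(ncol(d@X), 0, 0.5))
    expect_lt(max(abs(f2@w - fit@w)), 1e-6)
  }
})

test_that("all-zero counts shrink every non-constant coefficient to zero", {
  ct <- glm_tensor(seed = 87)
  ct@counts[] <- 0L
  d <- buildGlmDesign(ct, 1)
  fit <- fitPenalizedGlm(d)
  expect_lt(max(abs(fit@w[-1])), 1e-4)
  expect_lt(fit@w[1], -5)
  # non-integer counts are rejected by the design contract
  expect_error(new("GlmDesign", Y = c(0.5, 1), X = matrix(1, 2, 1),
                   blocks = list(), Q = matrix(0, 1, 1)),
               "integer")
})

test_that("bootstrap CIs are deterministic, need data, and cover a planted effect", {
  ct <- glm_tensor(seed = 88, beta = 0.4)
  d <- buildGlmDesign(ct, 1)
  expect_error(bootstrapGlmCi(d, n_boot = 0), "positive")
  small <- new("GlmDesign", Y = d@Y[1:20], X = d@X[1:20, ],
               blocks = d@blocks, Q = d@Q)
  expect_error(bootstrapGlmCi(small), "50")
  ci1 <- bootstrapGlmCi(d, n_boot = 40, seed = 89)
  ci2 <- bootstrapGlmCi(d, n_boot = 40, seed = 89)
  expect_identical(ci1, ci2)
  j <- d@blocks$deviation[1]
  expect_lt(ci1[j, "lo"], 0.4)
  expect_gt(ci1[j, "hi"], 0.2)
})

test_that("deviation sign recovery matches the planted direction", {
  for (s in 1:6) {
    bet <- c(0.3, -0.3)[s %% 2 + 1]
    ct <- glm_tensor(seed = 500 + s, beta = bet, n = 300L)
    fit <- fitPenalizedGlm(buildGlmDesign(ct, 1))
    expect_equal(unname(sign(fit@w["deviation"])), sign(bet))
  }
})

test_that("null relabeled designs carry a noise deviation regressor", {
  ct <- glm_tensor(seed = 90)
  d <- nullRelabelDesign(ct, 1, seed = 91)
  expect_true(any(d@X[, "deviation"] != 0))
  fit <- fitPenalizedGlm(d)
  expect_lt(abs(fit@w["deviation"]), 0.3)
  expect_error(glmFalsePositiveRate(list()), "at least one")
})
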