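test_that("logistic fit is the maximiser and matches its information-based SEs", {
  ## tiny dataset: MLE beats a parameter grid around it
  d <- data.frame(y = c(0, 0, 1, 0, 1, 1), x = c(-1.2, -0.4, 0.1, 0.3, 0.8, 1.5))
  f <- fit_logistic(d, "y", "x")
  ll <- function(b) sum(d$y * (b[1] + b[2] * d$x) - log1p(exp(b[1] + b[2] * d$x)))
  at_mle <- ll(coef(f))
  for (d1 in c(-0.01, 0, 0.01)) for (d2 in c(-0.01, 0, 0.01)) {
    expect_gte(at_mle, ll(coef(f) + c(d1, d2)))
  }

  ## symmetric balanced design: slope zero
  ds <- data.frame(y = c(0, 1, 0, 1), x = c(-1, -1, 1, 1))
  expect_equal(unname(coef(fit_logistic(ds, "y", "x"))["x"]), 0, tolerance = 1e-8)

  ## complete separation falls back to the penalised fit without crashing
  dsep <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(-3, -2, -1, 1, 2, 3))
  fs <- fit_logistic(dsep, "y", "x")
  expect_true("separation_penalised" %in% fs$flags)
  expect_true(all(is.finite(coef(fs))))
})

test_that("LDA estimator agrees with logistic regression under a correct LDA model", {
  set.seed(51)
  sc <- scenario("lda_model", gamma1 = 2, gamma2 = 2)
  d <- sc$sample(1e5)
  fl <- fit_lda(d, "Y", c("W1", "W2"))
  zt <- abs(coef(fl) - sc$truth$lda) / sqrt(diag(vcov(fl)))
  expect_true(all(zt < 3))
  fg <- fit_logistic(d, "Y", c("W1", "W2"))
  zd <- abs(coef(fl) - coef(fg)) / sqrt(diag(vcov(fg)))
  expect_true(all(zd < 3))

  ## equal class means: no discriminant slopes
  de <- data.frame(Y = rep(0:1, each = 50),
                   W1 = rep(stats::rnorm(50), 2), W2 = rep(stats::rnorm(50), 2))
  fe <- fit_lda(de, "Y", c("W1", "W2"))
  expect_equal(unname(coef(fe)[c("W1", "W2")]), c(0, 0), tolerance = 1e-10)
})

test_that("LDA delta-method covariance is consistent with the bootstrap", {
  set.seed(52)
  sc <- scenario("lda_model", gamma1 = 2, gamma2 = 2)
  d <- sc$sample(2000)
  f <- fit_lda(d, "Y", c("W1", "W2"))
  B <- 400
  boot <- matrix(0, B, 3)
  for (b in seq_len(B)) {
    i <- sample.int(2000, replace = TRUE)
    boot[b, ] <- coef(fit_lda(d[i, ], "Y", c("W1", "W2")))
  }
  ratio <- diag(vcov(f)) / apply(boot, 2, stats::var)
  expect_true(all(ratio > 0.7 & ratio < 1.4))
})

test_that("linear fit equals the normal equations", {
  set.seed(53)
  d <- data.frame(y = stats::rnorm(40), x1 = stats::rnorm(40), x2 = stats::rnorm(40))
  f <- fit_linear(d, "y", c("x1", "x2"))
  ref <- stats::lm(y ~ x1 + x2, d)
  expect_lt(max(abs(coef(f) - coef(ref))), 1e-10)
  expect_lt(max(abs(vcov(f) - unname(stats::vcov(ref)))), 1e-10)

  ## outcome identical to covariate: exact interpolation
  d2 <- data.frame(y = 1:10, x = 1:10)
  f2 <- fit_linear(d2, "y", "x")
  expect_equal(unname(coef(f2)["x"]), 1, tolerance = 1e-10)
  expect_lt(vcov(f2)[2, 2], 1e-20)
})

test_that("four-way log-linear fit recovers generating parameters", {
  set.seed(54)
  sc0 <- scenario("four_binary", theta_setting = c(0, 0, 0))
  d0 <- sc0$sample(2e4)
  f0 <- fit_loglinear4(d0)
  z0 <- abs(coef(f0)[c("theta12", "theta13", "theta14")]) /
    sqrt(diag(vcov(f0))[c("theta12", "theta13", "theta14")])
  expect_true(all(z0 < 3))

  sc <- scenario("four_binary", theta_setting = c(1, 2, 3))
  d <- sc$sample(1e5)
  f <- fit_loglinear4(d)
  z <- abs(coef(f) - sc$truth$loglinear) / sqrt(diag(vcov(f)))
  expect_true(all(z < 3))

  ## oracle cross-check: an independently specified Poisson model-matrix fit
  key <- as.matrix(d) %*% 2^(0:3)
  counts <- tabulate(key + 1, nbins = 16)
  cfg <- expand.grid(Y1 = 0:1, Y2 = 0:1, Y3 = 0:1, Y4 = 0:1)
  oracle <- stats::glm(counts ~ (Y1 + Y2 + Y3 + Y4)^2, poisson(), data = cfg)
  expect_equal(unname(coef(f)),
               unname(coef(oracle)[c("Y1", "Y1:Y2", "Y1:Y3", "Y1:Y4")]),
               tolerance = 1e-6)

  ## ML dominance: fitted pairwise-model probabilities beat the truth
  tab_ll <- function(p) sum(counts * log(p))
  p_fit <- oracle$fitted.values / sum(oracle$fitted.values)
  p_true <- cell_probabilities(four_binary_model(c(1, 2, 3))$loglin)$prob
  expect_gte(tab_ll(p_fit), tab_ll(p_true))
})

test_that("marginal mean estimator matches the direct formula", {
  d <- data.frame(y = c(rep(1, 30), rep(0, 70)))
  f <- estimate_marginal_mean(d, "y")
  expect_equal(unname(coef(f)), 0.3)
  expect_equal(vcov(f)[1, 1], stats::var(d$y) / 100)
  fc <- estimate_marginal_mean(data.frame(y = rep(2, 10)), "y")
  expect_equal(vcov(fc)[1, 1], 0)
})

test_that("Rubin's rules pooling follows the stated algebra", {
  mk <- function(est, v) rglmi:::mi_fit("toy", c(b = est), matrix(v), 10)
  ## identical estimates: no between-imputation variance
  p1 <- pool_rubin(list(mk(1.5, 2), mk(1.5, 2), mk(1.5, 2)))
  expect_equal(unname(p1$between[1, 1]), 0)
  expect_equal(p1$vcov, p1$within)

  ## M = 2, estimates 1 and 3 with variances 1 and 1
  p2 <- pool_rubin(list(mk(1, 1), mk(3, 1)))
  expect_equal(unname(coef(p2)), 2)
  expect_equal(unname(p2$within[1, 1]), 1)
  expect_equal(unname(p2$between[1, 1]), 2)
  expect_equal(unname(p2$vcov[1, 1]), 1 + (1 + 1 / 2) * 2)

  ## order invariance
  p3 <- pool_rubin(list(mk(3, 1), mk(1, 1)))
  expect_equal(coef(p3), coef(p2))
  expect_equal(p3$vcov, p2$vcov)

  ## single imputation: flagged, total = within
  ps <- pool_rubin(list(mk(1, 4)))
  expect_true(length(ps$flags) > 0)
  expect_equal(ps$vcov, ps$within)
})
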