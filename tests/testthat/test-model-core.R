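test_that("cell probabilities match brute-force enumeration and normalise", {
  ## all parameters zero: uniform by symmetry
  cp <- cell_probabilities(loglinear_spec(c(0, 0)))
  expect_equal(cp$prob, rep(0.25, 4))

  ## random draws against an independent enumeration oracle
  set.seed(101)
  for (r in 1:20) {
    ll <- random_loglinear(4, scale = 1.5)
    cp <- cell_probabilities(ll)
    oracle <- numeric(16)
    i <- 0
    for (y4 in 0:1) for (y3 in 0:1) for (y2 in 0:1) for (y1 in 0:1) {
      i <- i + 1
      y <- c(y1, y2, y3, y4)
      oracle[i] <- exp(sum(ll$theta_main * y) + drop(y %*% ll$theta_pair %*% y))
    }
    oracle <- oracle / sum(oracle)
    expect_lt(max(abs(cp$prob - oracle)), 1e-12)
  }

  ## normalisation over many random specs, L up to 6
  for (r in 1:200) {
    L <- sample(1:6, 1)
    cp <- cell_probabilities(random_loglinear(L, scale = 2))
    expect_lt(abs(sum(cp$prob) - 1), 1e-12)
    expect_true(all(cp$prob >= 0))
  }
})

test_that("solve_main_effect hits the requested marginal", {
  ## independence: marginal is expit of the main effect
  ll <- loglinear_spec(c(0, 0.3, -0.2))
  expect_equal(solve_main_effect(ll, 1, 0.3), logit(0.3), tolerance = 1e-8)

  ## strong interactions, self-check through cell_probabilities
  tp <- matrix(0, 4, 4); tp[1, 2:4] <- 3; tp[2, 3] <- tp[2, 4] <- tp[3, 4] <- 0.5
  ll <- loglinear_spec(c(0, -0.5, -0.5, -0.5), tp)
  ll$theta_main[1] <- solve_main_effect(ll, 1, 0.3)
  cp <- cell_probabilities(ll)
  expect_equal(sum(cp$prob[cp$Y1 == 1]), 0.3, tolerance = 1e-8)

  ## with a third-order interaction present
  m3 <- four_binary_model(c(1, 2, 3), third_order = TRUE)
  cp3 <- cell_probabilities(m3$loglin)
  expect_equal(sum(cp3$prob[cp3$Y1 == 1]), 0.3, tolerance = 1e-8)
})

test_that("four-binary generating model satisfies its marginal constraint", {
  for (s in list(c(0.33, 0.67, 1), c(0.67, 1.33, 2), c(1, 2, 3), c(3, 3, 3))) {
    cp <- cell_probabilities(four_binary_model(s)$loglin)
    expect_equal(sum(cp$prob[cp$Y1 == 1]), 0.3, tolerance = 1e-8)
  }
})

test_that("implied logistic slopes have the known closed form for the LDA-type model", {
  ## slopes must equal (g1/9 - g2/80, 9 g2/80) to machine precision
  for (g1 in 1:4) for (g2 in 1:4) {
    lg <- implied_logistic(lda_model(0.3, g1, g2))
    expect_equal(unname(lg$slopes), c(g1 / 9 - g2 / 80, 9 * g2 / 80),
                 tolerance = 1e-12)
  }
  ## intercept closed form at p = 0.3
  g1 <- 2; g2 <- 3
  lg <- implied_logistic(lda_model(0.3, g1, g2))
  expect_equal(lg$intercept,
               logit(0.3) - 10 * g1 / 9 - 89 * g2 / 80 - g1^2 / 18 - 9 * g2^2 / 160,
               tolerance = 1e-12)

  ## no mean shift for the target: no discriminant information
  ll <- loglinear_spec(c(0.4, -0.1), matrix(c(0, 0, 0, 0), 2, 2))
  g <- gaussian_layer(c(1, 2), matrix(c(0, 0, 1, 2), 2, 2), random_pd_matrix(2))
  lg0 <- implied_logistic(rgl_model(ll, g), target = 1)
  expect_equal(unname(lg0$slopes[c("W1", "W2")]), c(0, 0))
  expect_equal(lg0$intercept, 0.4)
})

test_that("implied logistic matches direct enumeration for random models (compatibility)", {
  set.seed(202)
  for (r in 1:40) {
    L <- sample(1:3, 1); q <- sample(1:3, 1)
    model <- random_rgl_model(L, q)
    tgt <- sample(seq_len(L), 1)
    lg <- implied_logistic(model, tgt)
    y_others <- stats::rbinom(L - 1, 1, 0.5)
    w <- stats::rnorm(q, sd = 2)
    y1 <- y0 <- numeric(L)
    y1[tgt] <- 1
    y1[-tgt] <- y0[-tgt] <- y_others
    direct <- rgl_joint_logdens(model, y1, w) - rgl_joint_logdens(model, y0, w)
    linpred <- lg$intercept +
      sum(lg$slopes[model$loglin$names[-tgt]] * y_others) +
      sum(lg$slopes[model$gaussian$names] * w)
    expect_lt(abs(expit(direct) - expit(linpred)), 1e-10)
  }
})

test_that("implied linear conditional matches multivariate-normal conditioning", {
  ## the known conditional of the second continuous variable
  il <- implied_linear(lda_model(0.3, 1, 2), "W2")
  expect_equal(il$intercept, 9 + 8 / 9, tolerance = 1e-12)
  expect_equal(unname(il$slopes["W1"]), 1 / 9, tolerance = 1e-12)
  expect_equal(unname(il$slopes["Y"]), 2, tolerance = 1e-12)
  expect_equal(il$resid_var, 8 + 8 / 9, tolerance = 1e-12)

  ## diagonal residual covariance: no cross-variable slopes
  g <- gaussian_layer(c(1, 2), matrix(c(1, 0, 0, 1), 2, 2), diag(c(2, 5)))
  ild <- implied_linear(rgl_model(loglinear_spec(c(0, 0)), g), "W2")
  expect_equal(unname(ild$slopes["W1"]), 0)
  expect_equal(ild$resid_var, 5)

  ## random 3x3 PD covariance against a precision-matrix oracle
  set.seed(303)
  for (r in 1:20) {
    model <- random_rgl_model(2, 3)
    il <- implied_linear(model, 2)
    P <- solve(model$gaussian$resid_cov)
    expect_lt(abs(il$resid_var - 1 / P[2, 2]), 1e-10)
    expect_lt(max(abs(il$slopes[c("W1", "W3")] - (-P[2, c(1, 3)] / P[2, 2]))), 1e-10)
  }
})

test_that("simulated data reproduce the model's moments", {
  d0 <- stats::simulate(lda_model(0.3, 1, 1), 0)
  expect_equal(nrow(d0), 0L)
  expect_named(d0, c("Y", "W1", "W2"))

  n <- 2e5
  d <- stats::simulate(lda_model(0.3, 1, 1), n, seed = 404)
  ## mean of Y and mixture variance of W1: 9 + g1^2 p (1 - p)
  expect_lt(abs(mean(d$Y) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  v_true <- 9 + 1 * 0.3 * 0.7
  se_v <- v_true * sqrt(2 / n)
  expect_lt(abs(stats::var(d$W1) - v_true), 3 * se_v)

  ## the gamma-covariate mechanism: P(Y = 1) equals the quadrature value
  sc <- scenario("gamma_misspec", gamma = 1)
  set.seed(405)
  dg <- sc$sample(2e5)
  ey <- sc$truth$mean[["Y"]]
  expect_lt(abs(mean(dg$Y) - ey), 3 * sqrt(ey * (1 - ey) / 2e5))
})

test_that("the margin carries information about conditional parameters when L = 4", {
  fb <- four_binary_model(c(1, 2, 3))
  tv <- margin_dependence(fb$loglin, 1, delta = 0.5)
  expect_true(all(tv > 1e-4))

  ## zero perturbation is the identity
  expect_equal(max(margin_dependence(fb$loglin, 1, delta = 0)), 0)
})

test_that("model specs round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  m <- lda_model(0.3, 2, 1)
  write_model_yaml(m, f)
  m2 <- read_model_yaml(f)
  expect_equal(m2$loglin$theta_main, m$loglin$theta_main)
  expect_equal(m2$gaussian$resid_cov, m$gaussian$resid_cov)
  expect_equal(coef(implied_logistic(m2)), coef(implied_logistic(m)))

  mg <- gamma_misspec_model(3)
  write_model_yaml(mg, f)
  mg2 <- read_model_yaml(f)
  expect_equal(coef(implied_logistic(mg2)), coef(implied_logistic(mg)))
  unlink(f)
})
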