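make_inc <- function(n = 2000, seed = 61, rate = 0.5, scenario_name = "lda_model", ...) {
  sc <- scenario(scenario_name, ...)
  set.seed(seed)
  d <- sc$sample(n)
  inc <- apply_missingness(d, missingness_spec("MCAR", sc$roles$categorical[1],
                                               rate = rate),
                           roles = sc$roles)
  list(sc = sc, complete = d, inc = inc)
}

test_that("joint-model imputation preserves observed data and the seed determines output", {
  x <- make_inc(800)
  r1 <- rgl_impute(x$inc, M = 3, burn_in = 20, thin = 2, seed = 7)
  r2 <- rgl_impute(x$inc, M = 3, burn_in = 20, thin = 2, seed = 7)
  expect_identical(r1$completed, r2$completed)
  obs <- !is.na(x$inc$Y)
  for (d in r1$completed) {
    expect_identical(d$Y[obs], x$complete$Y[obs])
    expect_identical(d$W1, x$complete$W1)
    expect_identical(d$W2, x$complete$W2)
  }
  ## different seed changes the imputed values
  r3 <- rgl_impute(x$inc, M = 3, burn_in = 20, thin = 2, seed = 8)
  expect_false(identical(r1$completed, r3$completed))
})

test_that("with nothing missing the engine returns M copies of the input", {
  sc <- scenario("lda_model")
  set.seed(62)
  d <- sc$sample(100)
  inc <- incomplete_data(d, sc$roles)
  r <- rgl_impute(inc, M = 4, seed = 1)
  expect_length(r$completed, 4)
  for (dd in r$completed) expect_equal(dd$Y, d$Y)
})

test_that("the I-step at the true parameters imputes from the implied conditionals", {
  ## fixed-parameter calibration: no P-step involved
  x <- make_inc(2e4, seed = 63)
  model <- x$sc$model
  truth_beta <- coef(implied_logistic(model))
  info <- list(categorical = "Y", continuous = c("W1", "W2"),
               conditioned = character(),
               groups = list(list(rows = which(is.na(x$inc$Y)),
                                  mis_cat = "Y", mis_cont = character())))
  state <- list(cellp = c(0.7, 0.3), cat_beta = NULL,
                B = rbind(model$gaussian$intercept,
                          t(model$gaussian$cat_loadings)),
                Sigma = model$gaussian$resid_cov)
  cur <- as.data.frame(x$inc)
  cur$Y[is.na(cur$Y)] <- 0
  miss <- attr(x$inc, "miss_mask")
  set.seed(64)
  out <- rglmi:::rgl_istep(cur, miss, info, state)
  imp <- out$Y[miss[, "Y"]]
  lp <- truth_beta[1] + truth_beta["W1"] * out$W1 + truth_beta["W2"] * out$W2
  pr <- expit(lp)[miss[, "Y"]]
  ## calibration within probability bins
  bins <- cut(pr, stats::quantile(pr, 0:4 / 4), include.lowest = TRUE)
  for (b in levels(bins)) {
    i <- bins == b
    expect_lt(abs(mean(imp[i]) - mean(pr[i])),
              3 * sqrt(mean(pr[i]) * (1 - mean(pr[i])) / sum(i)) + 0.01)
  }
})

test_that("the I-step redraws a missing continuous variable from its conditional normal", {
  sc <- scenario("lda_model", gamma1 = 1, gamma2 = 2)
  set.seed(65)
  d <- sc$sample(2e4)
  inc <- apply_missingness(d, missingness_spec("MCAR", "W2", rate = 0.5),
                           roles = sc$roles)
  model <- sc$model
  info <- list(categorical = "Y", continuous = c("W1", "W2"),
               conditioned = character(),
               groups = list(list(rows = which(is.na(inc$W2)),
                                  mis_cat = character(), mis_cont = "W2")))
  state <- list(cellp = c(0.7, 0.3), cat_beta = NULL,
                B = rbind(model$gaussian$intercept,
                          t(model$gaussian$cat_loadings)),
                Sigma = model$gaussian$resid_cov)
  cur <- as.data.frame(inc)
  cur$W2[is.na(cur$W2)] <- 0
  miss <- attr(inc, "miss_mask")
  set.seed(66)
  out <- rglmi:::rgl_istep(cur, miss, info, state)
  il <- implied_linear(model, "W2")
  m <- miss[, "W2"]
  fit <- stats::lm(out$W2[m] ~ out$Y[m] + out$W1[m])
  se <- sqrt(diag(stats::vcov(fit)))
  expect_lt(abs(coef(fit)[1] - il$intercept), 3 * se[1])
  expect_lt(abs(coef(fit)[2] - il$slopes["Y"]), 3 * se[2])
  expect_lt(abs(coef(fit)[3] - il$slopes["W1"]), 3 * se[3])
  rv <- sum(stats::residuals(fit)^2) / (sum(m) - 3)
  expect_lt(abs(rv - il$resid_var), 3 * il$resid_var * sqrt(2 / sum(m)))
})

test_that("P-step draws concentrate on the empirical distribution", {
  ## saturated two-variable table: Dirichlet posterior oracle
  set.seed(67)
  n <- 2e4
  y1 <- stats::rbinom(n, 1, 0.4)
  y2 <- stats::rbinom(n, 1, expit(-0.5 + y1))
  cur <- data.frame(Y1 = y1, Y2 = y2)
  info <- list(categorical = c("Y1", "Y2"), continuous = character(),
               conditioned = character())
  emp <- tabulate(y1 + 2 * y2 + 1, nbins = 4) / n
  draws <- replicate(100, {
    st <- rglmi:::rgl_pstep(cur, info, list(cellp = rep(0.25, 4)), 0.1, 20)
    st$cellp
  })
  expect_lt(mean(abs(rowMeans(draws) - emp)), 0.01)
  ## spread matches the Dirichlet posterior standard deviation
  dir_sd <- sqrt(emp * (1 - emp) / n)
  expect_lt(max(abs(apply(draws, 1, stats::sd) - dir_sd) / dir_sd), 0.6)

  ## Gaussian layer concentration near the generating coefficients
  sc <- scenario("lda_model", gamma1 = 2, gamma2 = 1)
  set.seed(68)
  d <- sc$sample(5e4)
  info2 <- list(categorical = "Y", continuous = c("W1", "W2"),
                conditioned = character())
  st2 <- rglmi:::rgl_pstep(d, info2, list(cellp = c(0.7, 0.3)), 0.1, 20)
  expect_lt(max(abs(st2$B[2, ] - sc$model$gaussian$cat_loadings[, 1])), 0.15)
  expect_lt(max(abs(st2$Sigma - sc$model$gaussian$resid_cov)), 0.5)
})

test_that("full chain is approximately unbiased for the marginal mean under MCAR", {
  x <- make_inc(2000, seed = 69)
  r <- rgl_impute(x$inc, M = 20, burn_in = 50, thin = 5, seed = 70)
  pm <- pool_analysis(r, "mean", "Y")
  expect_lt(abs(coef(pm) - 0.3), 3 * sqrt(vcov(pm)[1, 1]))
})

test_that("CRGL conditioning columns are never modelled or imputed", {
  scg <- scenario("gamma_misspec", gamma = 1)
  set.seed(71)
  d <- scg$sample(3000)
  inc <- apply_missingness(d, missingness_spec("MCAR", c("Y", "W2"), rate = 0.4),
                           roles = list(categorical = "Y", continuous = "W2"))
  r <- rgl_impute(inc, categorical = "Y", continuous = "W2", conditioned = "W1",
                  M = 5, burn_in = 30, thin = 3, seed = 72)
  for (dd in r$completed) expect_identical(dd$W1, d$W1)
  ## imputed Y respects the conditional: logistic refit on imputed data is
  ## close to the implied coefficients
  pooled <- pool_analysis(r, "logistic", "Y", c("W1", "W2"))
  truth <- scg$truth$logistic
  z <- abs(coef(pooled) - truth) / sqrt(diag(vcov(pooled)))
  expect_true(all(z < 4))
})
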