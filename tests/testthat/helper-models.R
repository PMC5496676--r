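## random model generators used by the property-style tests

random_loglinear <- function(L, scale = 1) {
  tp <- matrix(0, L, L)
  tp[upper.tri(tp)] <- stats::rnorm(L * (L - 1) / 2, sd = scale)
  loglinear_spec(stats::rnorm(L, sd = scale), tp)
}

random_pd_matrix <- function(q, scale = 1) {
  A <- matrix(stats::rnorm(q * q, sd = scale), q, q)
  crossprod(A) + diag(q) * 0.5
}

random_rgl_model <- function(L, q, scale = 0.7) {
  ll <- random_loglinear(L, scale)
  g <- if (q > 0) {
    gaussian_layer(stats::rnorm(q), matrix(stats::rnorm(q * L, sd = scale), q, L),
                   random_pd_matrix(q))
  } else NULL
  rgl_model(ll, g)
}

## brute-force joint density of (y, w) under an RGL model
rgl_joint_logdens <- function(model, y, w) {
  cp <- cell_probabilities(model$loglin)
  key <- sum(y * 2^(seq_along(y) - 1)) + 1
  lp <- log(cp$prob[key])
  g <- model$gaussian
  if (!is.null(g)) {
    mu <- g$intercept + drop(g$cat_loadings %*% y)
    lp <- lp + rglmi:::dmvnorm_log(matrix(w, 1), matrix(mu, 1), g$resid_cov)
  }
  lp
}
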