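## ------------------------------------------------------------------
## Analysis estimators and Rubin's-rules pooling
## ------------------------------------------------------------------

mi_fit <- function(label, coef, vcov, n, flags = character()) {
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(names(coef), names(coef))
  structure(list(label = label, coef = coef, vcov = vcov, n = n, flags = flags),
            class = "mi_fit")
}

#' @export
print.mi_fit <- function(x, digits = 4, ...) {
  cat(x$label, "fit on", x$n, "rows\n")
  tab <- cbind(estimate = x$coef, se = sqrt(diag(x$vcov)))
  print(round(tab, digits))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mi_fit <- function(object, ...) object$coef

#' @export
vcov.mi_fit <- function(object, ...) object$vcov

#' Logistic regression estimator
#'
#' Maximum-likelihood logistic regression of a binary outcome on main
#' effects of the covariates, with covariance from the inverse observed
#' information.  If the fit shows signs of separation the Jeffreys-prior
#' penalised fit is returned instead and flagged.
#'
#' @param data data frame.
#' @param outcome name of the binary (0/1) outcome column.
#' @param covariates character vector of covariate columns.
#' @return an object of class `"mi_fit"`.
#' @export
fit_logistic <- function(data, outcome, covariates) {
  y <- data[[outcome]]
  if (length(unique(y)) < 2) stop("outcome takes a single value")
  X <- cbind("(Intercept)" = 1, as.matrix(data[covariates]))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100)))
  flags <- character()
  if (!fit$converged || max(abs(fit$coefficients)) > 15) {
    fr <- firth_logistic(X, y)
    co <- fr$coef; V <- fr$vcov
    flags <- "separation_penalised"
  } else {
    co <- fit$coefficients
    w <- fit$weights
    V <- solve(crossprod(X * sqrt(w)))
  }
  names(co) <- colnames(X)
  mi_fit("logistic", co, V, length(y), flags)
}

#' Linear discriminant analysis estimator of logistic coefficients
#'
#' Fits the two-class normal-mixture (LDA) model by maximum likelihood --
#' class prevalence, class means and pooled ML covariance -- and converts
#' to logistic-regression coefficients through the Bayes-rule
#' (discriminant) formula.  The covariance of the coefficients is obtained
#' by the delta method on the asymptotic covariance of the mixture ML
#' estimates.
#'
#' @inheritParams fit_logistic
#' @return an object of class `"mi_fit"`.
#' @export
fit_lda <- function(data, outcome, covariates) {
  y <- data[[outcome]]
  W <- as.matrix(data[covariates])
  n <- length(y)
  n1 <- sum(y == 1); n0 <- n - n1
  if (n0 < 2 || n1 < 2) stop("need at least two rows per class")
  q <- ncol(W)
  p <- n1 / n
  mu0 <- colMeans(W[y == 0, , drop = FALSE])
  mu1 <- colMeans(W[y == 1, , drop = FALSE])
  C0 <- crossprod(sweep(W[y == 0, , drop = FALSE], 2, mu0))
  C1 <- crossprod(sweep(W[y == 1, , drop = FALSE], 2, mu1))
  S <- (C0 + C1) / n                       # pooled ML covariance
  eta <- c(p, mu0, mu1, S[upper.tri(S, diag = TRUE)])
  co <- lda_beta_from_eta(eta, q)
  V_eta <- lda_eta_avar(eta, q) / n
  J <- num_jacobian(function(e) lda_beta_from_eta(e, q), eta)
  V <- J %*% V_eta %*% t(J)
  names(co) <- c("(Intercept)", covariates)
  mi_fit("lda", co, V, n)
}

## eta = (p, mu0, mu1, vech(Sigma)); beta via the discriminant formula
lda_beta_from_eta <- function(eta, q) {
  p <- eta[1]
  mu0 <- eta[1 + seq_len(q)]
  mu1 <- eta[1 + q + seq_len(q)]
  S <- matrix(0, q, q)
  S[upper.tri(S, diag = TRUE)] <- eta[-(1:(1 + 2 * q))]
  S <- S + t(S) - diag(diag(S), q)
  sl <- solve(S, mu1 - mu0)
  c(logit(p) - 0.5 * sum((mu0 + mu1) * sl), sl)
}

## per-observation asymptotic covariance of the mixture ML estimates:
## blocks for prevalence, the two class means, and the Wishart-type
## covariance of the pooled ML covariance entries
lda_eta_avar <- function(eta, q) {
  p <- eta[1]
  S <- matrix(0, q, q)
  S[upper.tri(S, diag = TRUE)] <- eta[-(1:(1 + 2 * q))]
  S <- S + t(S) - diag(diag(S), q)
  nv <- q * (q + 1) / 2
  V <- matrix(0, 1 + 2 * q + nv, 1 + 2 * q + nv)
  V[1, 1] <- p * (1 - p)
  V[1 + seq_len(q), 1 + seq_len(q)] <- S / (1 - p)
  V[1 + q + seq_len(q), 1 + q + seq_len(q)] <- S / p
  idx <- which(upper.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  for (a in seq_len(nv)) for (b in seq_len(nv)) {
    i <- idx[a, 1]; j <- idx[a, 2]; k <- idx[b, 1]; l <- idx[b, 2]
    V[1 + 2 * q + a, 1 + 2 * q + b] <- S[i, k] * S[j, l] + S[i, l] * S[j, k]
  }
  V
}

num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (m in seq_along(x)) {
    xp <- x; xm <- x
    xp[m] <- xp[m] + h; xm[m] <- xm[m] - h
    J[, m] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Linear regression estimator
#'
#' Ordinary least squares with the classical covariance estimate.
#'
#' @inheritParams fit_logistic
#' @export
fit_linear <- function(data, outcome, covariates) {
  y <- data[[outcome]]
  X <- cbind("(Intercept)" = 1, as.matrix(data[covariates]))
  XtX <- crossprod(X)
  co <- drop(solve(XtX, crossprod(X, y)))
  res <- y - drop(X %*% co)
  s2 <- sum(res^2) / (length(y) - ncol(X))
  mi_fit("linear", stats::setNames(co, colnames(X)), s2 * solve(XtX), length(y))
}

#' Pairwise log-linear estimator for four binary variables
#'
#' Maximum-likelihood fit of the log-linear model with main effects and
#' all pairwise interactions to the 16-cell table of four binary
#' variables, via the equivalent Poisson regression.  Returns the
#' parameters `(theta_1, theta_12, theta_13, theta_14)` -- the main effect
#' of the first variable and its three interactions, which coincide with
#' the implied logistic regression of the first variable on the others --
#' with covariance from the information matrix.  If any cell of the table
#' is empty, 0.5 is added to every cell and the result flagged.
#'
#' @param data data frame whose first four columns (or `vars`) are binary.
#' @param vars the four column names; default the first four columns.
#' @export
fit_loglinear4 <- function(data, vars = names(data)[1:4]) {
  stopifnot(length(vars) == 4)
  Y <- as.matrix(data[vars])
  cells <- cell_grid(4L)
  key <- Y %*% 2^(0:3)
  counts <- tabulate(key + 1L, nbins = 16L)
  flags <- character()
  if (any(counts == 0)) {
    counts <- counts + 0.5
    flags <- "empty_cells_flattened"
  }
  pr <- t(utils::combn(4, 2))
  X <- cbind(1, cells, cells[, pr[, 1]] * cells[, pr[, 2]])
  colnames(X) <- c("(norm)", paste0("theta", 1:4),
                   paste0("theta", pr[, 1], pr[, 2]))
  fit <- suppressWarnings(
    stats::glm.fit(X, counts, family = stats::poisson(),
                   control = list(epsilon = 1e-10, maxit = 100)))
  keep <- c("theta1", "theta12", "theta13", "theta14")
  V <- solve(crossprod(X * sqrt(fit$weights)))
  dimnames(V) <- list(colnames(X), colnames(X))
  mi_fit("loglinear", fit$coefficients[keep], V[keep, keep], nrow(data), flags)
}

#' Marginal mean estimator
#'
#' @param data data frame.
#' @param column column whose mean is estimated.
#' @export
estimate_marginal_mean <- function(data, column) {
  v <- data[[column]]
  m <- mean(v)
  mi_fit("marginal_mean", stats::setNames(m, column),
         matrix(stats::var(v) / length(v)), length(v))
}

## dispatch on an analysis label used by the study functions
run_analysis <- function(analysis, data, outcome, covariates) {
  switch(analysis,
         logistic  = fit_logistic(data, outcome, covariates),
         lda       = fit_lda(data, outcome, covariates),
         linear    = fit_linear(data, outcome, covariates),
         loglinear = fit_loglinear4(data, c(outcome, covariates)),
         mean      = estimate_marginal_mean(data, outcome),
         stop("unknown analysis '", analysis, "'"))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the mean of the `M` per-imputation
#' estimates; the total variance is `T = W + (1 + 1/M) B`, with `W` the
#' mean within-imputation covariance and `B` the between-imputation
#' covariance (denominator `M - 1`).
#'
#' @param fits list of `"mi_fit"` objects with identical parameter names.
#' @return an object of class `"mi_pooled"` with components `coef`,
#'   `within`, `between`, `vcov` (the total) and `M`.
#' @export
pool_rubin <- function(fits) {
  stopifnot(length(fits) >= 1)
  nms <- names(fits[[1]]$coef)
  est <- do.call(rbind, lapply(fits, function(f) {
    if (!identical(names(f$coef), nms)) stop("parameter names differ across imputations")
    f$coef
  }))
  M <- length(fits)
  beta_bar <- colMeans(est)
  Wb <- Reduce(`+`, lapply(fits, vcov)) / M
  if (M > 1) {
    B <- stats::cov(est)
    Tt <- Wb + (1 + 1 / M) * B
    flags <- character()
  } else {
    B <- matrix(NA_real_, length(nms), length(nms))
    Tt <- Wb
    flags <- "single_imputation_no_between_variance"
  }
  structure(list(coef = beta_bar, within = Wb, between = B, vcov = Tt,
                 M = M, label = fits[[1]]$label, flags = flags),
            class = "mi_pooled")
}

#' @export
print.mi_pooled <- function(x, digits = 4, ...) {
  cat("Rubin's-rules pooled", x$label, "estimate (M =", x$M, ")\n")
  print(round(cbind(estimate = x$coef, se = sqrt(diag(x$vcov))), digits))
  invisible(x)
}

#' @export
coef.mi_pooled <- function(object, ...) object$coef

#' @export
vcov.mi_pooled <- function(object, ...) object$vcov

#' @export
summary.mi_pooled <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  data.frame(parameter = names(object$coef), estimate = unname(object$coef),
             se = unname(se),
             within_se = sqrt(diag(object$within)),
             between_var = diag(object$between),
             M = object$M, row.names = NULL)
}

#' Fit an analysis to every imputed dataset and pool
#'
#' @param result an imputation result from [rgl_impute()] or
#'   [fcs_impute()].
#' @param analysis one of `"logistic"`, `"lda"`, `"linear"`,
#'   `"loglinear"`, `"mean"`.
#' @param outcome,covariates analysis-model columns.
#' @param exclude_imputed_outcome drop rows whose outcome value was
#'   imputed before fitting (the strategy of excluding imputed outcomes
#'   from the analysis).
#' @return an `"mi_pooled"` object.
#' @export
pool_analysis <- function(result, analysis, outcome, covariates = NULL,
                          exclude_imputed_outcome = FALSE) {
  stopifnot(inherits(result, "mi_result"))
  keep <- if (exclude_imputed_outcome) !result$miss_mask[, outcome] else NULL
  fits <- lapply(result$completed, function(d) {
    if (!is.null(keep)) d <- d[keep, , drop = FALSE]
    run_analysis(analysis, d, outcome, covariates)
  })
  pool_rubin(fits)
}
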