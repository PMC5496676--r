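## ------------------------------------------------------------------
## Full-conditional-specification (chained equations) imputation
## ------------------------------------------------------------------

## Jeffreys-penalised logistic regression (Firth); used when the plain ML
## fit separates.  Standard modified-score IRLS.
firth_logistic <- function(X, y, maxit = 50, tol = 1e-8) {
  p <- ncol(X)
  b <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    ch <- tryCatch(chol(XtWX), error = function(e) chol(XtWX + 1e-8 * diag(p)))
    H <- backsolve(ch, forwardsolve(t(ch), t(XW)))
    h <- colSums(t(XW) * H)                     # hat diagonal
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- backsolve(ch, forwardsolve(t(ch), U))
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  list(coef = stats::setNames(drop(b), colnames(X)),
       vcov = chol2inv(chol(XtWX)))
}

## Bayesian draw from a normal linear conditional model under the
## noninformative prior p(beta, sigma^2) ~ 1/sigma^2:
## sigma^2 | data ~ SSE / chisq(n - p), beta | sigma^2 ~ N(bhat, sigma^2 (X'X)^-1)
draw_linear_conditional <- function(y, X) {
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) {
    chol(XtX + 1e-8 * diag(p))                   # rank-deficient fallback
  })
  bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y)))
  res <- y - drop(X %*% bhat)
  df <- max(n - p, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  beta <- drop(bhat) + sqrt(sigma2) * backsolve(ch, stats::rnorm(p))
  list(beta = beta, sigma = sqrt(sigma2))
}

## Approximate-posterior draw for a logistic conditional model: penalised
## ML centre with asymptotic normal spread (inverse observed information).
draw_logistic_conditional <- function(y, X) {
  if (length(unique(y)) < 2) stop("single-class response")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 50)))
  separated <- !fit$converged || max(abs(fit$coefficients)) > 15
  if (separated) {
    fr <- firth_logistic(X, y)
    centre <- fr$coef
    V <- fr$vcov
  } else {
    centre <- fit$coefficients
    V <- chol2inv(chol(crossprod(X * sqrt(pmax(fit$weights, 1e-12)))))
  }
  beta <- drop(centre) + drop(stats::rnorm(ncol(X)) %*% chol(V))
  list(beta = beta, separated = separated)
}

## starting values: draws from each column's observed empirical distribution
initial_fill <- function(data, miss) {
  for (k in names(data)) {
    m <- miss[, k]
    if (any(m)) data[[k]][m] <- sample(data[[k]][!m], sum(m), replace = TRUE)
  }
  data
}

#' Multiple imputation by chained equations with compatible conditionals
#'
#' Cycles through the partially observed columns; each step draws the
#' parameters of a main-effects conditional model for that column given
#' all other columns -- a Bayesian linear regression for continuous
#' columns, an approximate-posterior logistic regression for binary
#' columns -- from their posterior based on the rows where the column is
#' observed, then redraws the column's missing values from the fitted
#' conditional.  These conditional families are exactly the conditionals
#' implied by a restricted general location joint model, so the two
#' engines impute from the same distribution asymptotically when that
#' model holds.  Each of the `M` imputations is an independent stream
#' started from fresh marginal draws.
#'
#' @param data an [incomplete_data()] object or data frame with `NA`s.
#' @param categorical,continuous modelled column names; default taken from
#'   the data's roles.
#' @param predictors extra fully observed columns used as predictors in
#'   every conditional model (conditioning variables).
#' @param M number of imputations.
#' @param n_cycles full cycles through the conditionals per imputation.
#' @param order imputation order of the partially observed columns; by
#'   default data order, so put the analysis outcome last.
#' @param seed optional integer seed.
#' @return an object of class `"mi_result"`: a list with `completed` (list
#'   of `M` complete data frames), the original `miss_mask`, the `method`
#'   label, settings, and a count of separation fallbacks.
#' @export
fcs_impute <- function(data, categorical = NULL, continuous = NULL,
                       predictors = character(), M = 50, n_cycles = 10,
                       order = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roles <- attr(data, "roles")
  categorical <- categorical %||% roles$categorical
  continuous <- continuous %||% roles$continuous
  cols <- c(categorical, continuous)
  df <- as.data.frame(data)[c(cols, predictors)]
  miss <- is.na(as.matrix(df))
  if (any(vapply(df, function(v) all(is.na(v)), logical(1))))
    stop("a column is entirely missing")
  if (any(miss[, predictors])) stop("predictor columns must be fully observed")
  part <- cols[colSums(miss[, cols, drop = FALSE]) > 0]
  if (!length(part)) {
    return(structure(list(completed = rep(list(df), M), miss_mask = miss,
                          method = "fcs",
                          settings = list(M = M, n_cycles = n_cycles, seed = seed),
                          n_separation = 0L),
                     class = "mi_result"))
  }
  order <- order %||% part
  stopifnot(setequal(order, part))
  n_sep <- 0L

  completed <- vector("list", M)
  for (m in seq_len(M)) {
    cur <- initial_fill(df, miss)
    for (cyc in seq_len(n_cycles)) {
      for (k in order) {
        oth <- setdiff(c(cols, predictors), k)
        X <- cbind(1, as.matrix(cur[oth]))
        obs <- !miss[, k]
        mis <- miss[, k]
        if (k %in% continuous) {
          dr <- draw_linear_conditional(cur[[k]][obs], X[obs, , drop = FALSE])
          cur[[k]][mis] <- drop(X[mis, , drop = FALSE] %*% dr$beta) +
            dr$sigma * stats::rnorm(sum(mis))
        } else {
          dr <- draw_logistic_conditional(cur[[k]][obs], X[obs, , drop = FALSE])
          if (dr$separated) n_sep <- n_sep + 1L
          pr <- expit(drop(X[mis, , drop = FALSE] %*% dr$beta))
          cur[[k]][mis] <- as.integer(stats::runif(sum(mis)) < pr)
        }
      }
    }
    completed[[m]] <- cur
  }
  structure(list(completed = completed, miss_mask = miss, method = "fcs",
                 settings = list(M = M, n_cycles = n_cycles, order = order,
                                 seed = seed),
                 n_separation = n_sep),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat("Multiple imputation result (", x$method, " engine)\n", sep = "")
  cat("  imputations:  ", length(x$completed), "\n")
  cat("  missing cells:", sum(x$miss_mask), "of",
      length(x$miss_mask), "\n")
  if (!is.null(x$n_separation) && x$n_separation > 0)
    cat("  separation fallbacks:", x$n_separation, "\n")
  invisible(x)
}

#' Extract one completed dataset
#'
#' @param result an `"mi_result"`.
#' @param m which imputation.
#' @export
completed_data <- function(result, m = 1L) {
  stopifnot(inherits(result, "mi_result"))
  result$completed[[m]]
}
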