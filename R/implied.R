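#' Implied logistic conditional of a binary variable
#'
#' Under a (C)RGL model, the conditional distribution of any binary
#' variable given the remaining binary variables, the continuous variables
#' and the conditioning variables is an ordinary logistic regression with
#' main effects only.  The coefficients follow from Bayes' rule: writing
#' \eqn{\Delta} for the shift in the conditional mean of `W` between the
#' target's two levels (its column of `cat_loadings`), the quadratic terms
#' in `W` cancel because the residual covariance \eqn{\theta_v} is shared
#' across cells, leaving
#' * slopes on `W` equal to \eqn{\theta_v^{-1}\Delta},
#' * slopes on the other binary variables equal to the pairwise log-linear
#'   term minus \eqn{\Delta^\top\theta_v^{-1}} times their `W` loading,
#' * slopes on `Z` equal to the log-linear `Z` loading minus
#'   \eqn{\Delta^\top\theta_v^{-1}\theta_{wz}},
#' * intercept equal to the target's main effect minus
#'   \eqn{\Delta^\top\theta_v^{-1}\theta_{w0} + \tfrac12\Delta^\top\theta_v^{-1}\Delta}.
#'
#' When the model carries an explicit `baseline_logit` the intercept and
#' `Z` slopes start from that baseline instead of the log-linear terms.
#'
#' @param model an [rgl_model()].
#' @param target name (or index) of the binary variable; default the first.
#' @return an object of class `"logistic_coefficients"`: a list with
#'   `intercept` and a named vector `slopes` ordered as (other binary
#'   variables, conditioning variables, continuous variables).
#' @examples
#' m <- lda_model(0.3, 1, 1)
#' round(implied_logistic(m)$slopes, 3)   # 0.099, 0.113
#' @export
implied_logistic <- function(model, target = 1L) {
  stopifnot(inherits(model, "rgl_model"))
  ll <- model$loglin
  if (is.character(target)) target <- match(target, ll$names)
  if (is.na(target)) stop("unknown target variable")
  g <- model$gaussian
  if (!is.null(g)) {
    Delta <- g$cat_loadings[, target]
    a <- solve(g$resid_cov, Delta)        # theta_v^{-1} Delta
  } else {
    Delta <- numeric(0)
    a <- numeric(0)
  }

  ## other binary variables
  others <- setdiff(seq_len(ll$L), target)
  cat_slopes <- stats::setNames(numeric(length(others)), ll$names[others])
  for (k in seq_along(others)) {
    j <- others[k]
    lo <- min(target, j); hi <- max(target, j)
    cat_slopes[k] <- ll$theta_pair[lo, hi]
    if (!is.null(g)) cat_slopes[k] <- cat_slopes[k] - sum(a * g$cat_loadings[, j])
  }
  for (tm in ll$extra_terms) {
    if (target %in% tm$idx)
      stop("higher-order terms involving the target are not of logistic main-effects form")
  }

  ## conditioning variables
  d <- length(model$conditioned_names)
  if (!is.null(model$baseline_logit)) {
    base_int <- model$baseline_logit$intercept
    z_slopes <- model$baseline_logit$slopes
  } else {
    base_int <- ll$theta_main[target]
    z_slopes <- if (d) {
      zc <- if (is.null(ll$theta_cov)) numeric(d) else ll$theta_cov[target, ]
      stats::setNames(zc, model$conditioned_names)
    } else NULL
  }
  if (d && !is.null(g) && !is.null(g$cov_loadings))
    z_slopes <- z_slopes - as.numeric(t(g$cov_loadings) %*% a)

  ## continuous variables and intercept
  if (!is.null(g)) {
    w_slopes <- stats::setNames(a, g$names)
    intercept <- base_int - sum(a * g$intercept) - 0.5 * sum(a * Delta)
  } else {
    w_slopes <- NULL
    intercept <- base_int
  }
  structure(list(intercept = unname(intercept),
                 slopes = c(cat_slopes, z_slopes, w_slopes),
                 target = ll$names[target]),
            class = "logistic_coefficients")
}

#' @export
print.logistic_coefficients <- function(x, digits = 4, ...) {
  cat("Implied logistic conditional for", x$target, "\n")
  print(round(c("(Intercept)" = x$intercept, x$slopes), digits))
  invisible(x)
}

#' @export
coef.logistic_coefficients <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$slopes)
}

#' Implied linear conditional of a continuous variable
#'
#' Under a (C)RGL model, the conditional distribution of one continuous
#' variable given the binary variables, the other continuous variables and
#' the conditioning variables is normal with main effects only and
#' cell-independent slopes.  This is standard multivariate-normal
#' conditioning within a cell: the slopes on the other continuous variables
#' are \eqn{\theta_{v,to}\theta_{v,oo}^{-1}} and the residual variance is
#' the Schur complement of the target entry of \eqn{\theta_v}.
#'
#' @param model an [rgl_model()] with a Gaussian layer.
#' @param target name (or index) of the continuous variable.
#' @return a list with `intercept`, named `slopes` (binary variables,
#'   conditioning variables, other continuous variables) and
#'   `resid_var`.
#' @export
implied_linear <- function(model, target = 1L) {
  stopifnot(inherits(model, "rgl_model"))
  g <- model$gaussian
  if (is.null(g)) stop("model has no continuous variables")
  if (is.character(target)) target <- match(target, g$names)
  if (is.na(target)) stop("unknown target variable")
  oth <- setdiff(seq_len(g$q), target)
  V <- g$resid_cov
  if (length(oth)) {
    s <- solve(V[oth, oth, drop = FALSE], V[oth, target])
    resid_var <- V[target, target] - sum(V[target, oth] * s)
    w_slopes <- stats::setNames(as.numeric(s), g$names[oth])
    intercept <- g$intercept[target] - sum(s * g$intercept[oth])
    y_slopes <- g$cat_loadings[target, ] - as.numeric(s %*% g$cat_loadings[oth, , drop = FALSE])
    z_slopes <- if (!is.null(g$cov_loadings))
      g$cov_loadings[target, ] - as.numeric(s %*% g$cov_loadings[oth, , drop = FALSE])
    else NULL
  } else {
    resid_var <- V[target, target]
    w_slopes <- NULL
    intercept <- g$intercept[target]
    y_slopes <- g$cat_loadings[target, ]
    z_slopes <- if (!is.null(g$cov_loadings)) g$cov_loadings[target, ] else NULL
  }
  names(y_slopes) <- model$loglin$names
  if (!is.null(z_slopes)) names(z_slopes) <- model$conditioned_names
  list(target = g$names[target], intercept = unname(intercept),
       slopes = c(y_slopes, z_slopes, w_slopes),
       resid_var = unname(resid_var))
}

#' Simulate complete data from a (C)RGL model
#'
#' Draws the binary cell of each row from the log-linear layer (at the
#' row's conditioning values, if any) and the continuous variables from the
#' Gaussian layer at that cell.
#'
#' @param object an [rgl_model()].
#' @param nsim number of rows.
#' @param seed optional integer seed.
#' @param z data frame (or matrix) of conditioning values, one row per
#'   simulated row; required when the model is conditional.
#' @param ... unused.
#' @return a data frame with the binary columns, conditioning columns (if
#'   supplied) and continuous columns.
#' @export
simulate.rgl_model <- function(object, nsim = 1, seed = NULL, z = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object
  ll <- model$loglin
  L <- ll$L
  d <- length(model$conditioned_names)
  if (d && is.null(z)) stop("conditioning values 'z' required")
  if (!is.null(z)) {
    z <- as.matrix(as.data.frame(z))
    stopifnot(nrow(z) == nsim)
  }
  cells <- cell_grid(L)
  cols <- c(ll$names, model$conditioned_names,
            if (!is.null(model$gaussian)) model$gaussian$names)
  if (nsim == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }

  ## cell draw: row-constant part of the linear predictor, then z loadings
  ll0 <- ll
  ll0$theta_cov <- NULL
  base_lp <- cell_lp(ll0, cells = cells)
  lpm <- matrix(base_lp, nsim, 2^L, byrow = TRUE)
  if (d && !is.null(ll$theta_cov))
    lpm <- lpm + z %*% t(cells %*% ll$theta_cov)
  if (!is.null(model$baseline_logit)) {
    bl <- model$baseline_logit$intercept +
      as.numeric(z[, names(model$baseline_logit$slopes), drop = FALSE] %*%
                   model$baseline_logit$slopes)
    lpm <- cbind(0, bl)                     # L = 1: cells are (0, 1)
  }
  w <- exp(lpm - apply(lpm, 1L, max))
  idx <- sample_rows(w)
  y <- cells[idx, , drop = FALSE]

  out <- as.data.frame(y)
  names(out) <- ll$names
  if (d) out[model$conditioned_names] <- as.data.frame(z)

  g <- model$gaussian
  if (!is.null(g)) {
    mu <- matrix(g$intercept, nsim, g$q, byrow = TRUE) + y %*% t(g$cat_loadings)
    if (!is.null(g$cov_loadings)) mu <- mu + z %*% t(g$cov_loadings)
    wmat <- rmvnorm_chol(nsim, mu, chol(g$resid_cov))
    out[g$names] <- as.data.frame(wmat)
  }
  rownames(out) <- NULL
  out
}
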