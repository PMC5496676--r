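#' Specify the log-linear layer of a general location model
#'
#' The categorical part of the restricted general location (RGL) model is a
#' log-linear model for `L` binary variables with main effects and all
#' pairwise interactions:
#' \deqn{P(Y = y) \propto \exp(\theta_y^\top y + y^\top \theta_{yy} y)}
#' with \eqn{\theta_{yy}} strictly upper triangular.  When the model is
#' conditioned on fully observed variables `Z`, linear loadings of the cells
#' on `Z` are held in `theta_cov`.  Higher-order interactions (used only for
#' data generation, never by the restricted imputation model) may be added
#' through `extra_terms`.
#'
#' @param theta_main numeric vector of main effects, one per binary variable.
#' @param theta_pair strictly upper triangular `L x L` matrix of pairwise
#'   interaction coefficients, or `NULL` for none.
#' @param theta_cov `L x d` matrix of loadings on conditioning variables, or
#'   `NULL`.
#' @param extra_terms list of higher-order interaction terms, each a list
#'   with elements `idx` (integer vector of at least three variable indices)
#'   and `coef` (scalar coefficient).
#' @param names optional character vector of variable names.
#' @return an object of class `"loglinear_spec"`.
#' @export
loglinear_spec <- function(theta_main, theta_pair = NULL, theta_cov = NULL,
                           extra_terms = list(), names = NULL) {
  L <- length(theta_main)
  if (L < 1L || L > 12L)
    stop("between 1 and 12 binary variables are supported")
  if (is.null(theta_pair)) theta_pair <- matrix(0, L, L)
  theta_pair <- as.matrix(theta_pair)
  if (!all(dim(theta_pair) == c(L, L)))
    stop("'theta_pair' must be ", L, " x ", L)
  if (any(theta_pair[lower.tri(theta_pair, diag = TRUE)] != 0))
    stop("'theta_pair' must be strictly upper triangular")
  if (!is.null(theta_cov)) {
    theta_cov <- as.matrix(theta_cov)
    if (nrow(theta_cov) != L) stop("'theta_cov' must have ", L, " rows")
  }
  for (tm in extra_terms) {
    if (length(tm$idx) < 3L || any(tm$idx > L) || anyDuplicated(tm$idx))
      stop("extra terms must reference at least three distinct variables")
  }
  if (!all(is.finite(theta_main)) || !all(is.finite(theta_pair)))
    stop("parameters must be finite")
  if (is.null(names)) names <- paste0("Y", seq_len(L))
  structure(list(L = L, theta_main = stats::setNames(as.numeric(theta_main), names),
                 theta_pair = theta_pair, theta_cov = theta_cov,
                 extra_terms = extra_terms, names = names),
            class = "loglinear_spec")
}

#' Specify the Gaussian layer of a general location model
#'
#' Given the categorical cell `Y` (and conditioning variables `Z`), the
#' continuous variables follow
#' \deqn{W \mid Y, Z \sim N(\theta_{w0} + \theta_{wy} Y + \theta_{wz} Z, \theta_v)}
#' with a residual covariance shared across cells ("homogeneous general
#' location").  Main effects only: cell means are additive in the binary
#' indicators.
#'
#' @param intercept numeric vector of length `q` (cell-0 means).
#' @param cat_loadings `q x L` matrix of mean shifts per binary indicator.
#' @param resid_cov `q x q` symmetric positive definite residual covariance.
#' @param cov_loadings `q x d` matrix of loadings on conditioning variables,
#'   or `NULL`.
#' @param names optional character vector of continuous variable names.
#' @return an object of class `"gaussian_layer"`.
#' @export
gaussian_layer <- function(intercept, cat_loadings, resid_cov,
                           cov_loadings = NULL, names = NULL) {
  q <- length(intercept)
  cat_loadings <- matrix(as.numeric(cat_loadings), nrow = q)
  resid_cov <- as.matrix(resid_cov)
  if (!isTRUE(all.equal(resid_cov, t(resid_cov))))
    stop("'resid_cov' must be symmetric")
  ev <- eigen(resid_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'resid_cov' must be positive definite")
  if (!is.null(cov_loadings)) cov_loadings <- matrix(as.numeric(cov_loadings), nrow = q)
  if (is.null(names)) names <- paste0("W", seq_len(q))
  structure(list(q = q, intercept = stats::setNames(as.numeric(intercept), names),
                 cat_loadings = cat_loadings, cov_loadings = cov_loadings,
                 resid_cov = resid_cov, names = names),
            class = "gaussian_layer")
}

#' Build a (conditional) restricted general location model
#'
#' Combines a log-linear layer for binary variables with an optional
#' Gaussian layer for continuous variables.  When `conditioned_names` is
#' non-empty the model is the RGL model conditional on those fully observed
#' variables (CRGL): their marginal law is left unmodelled and they enter
#' the two layers linearly.  For a model with a single binary variable the
#' cell model given `Z` may instead be supplied as an explicit
#' `baseline_logit` -- a list with elements `intercept` and `slopes` (named
#' by conditioning variable) giving `logit P(Y = 1 | Z)` directly; this is
#' how a conditional model whose `Z` is non-normal is represented.
#'
#' @param loglin a [loglinear_spec()].
#' @param gaussian a [gaussian_layer()], or `NULL` for a purely categorical
#'   model.
#' @param conditioned_names character vector of conditioning variable names
#'   (may be empty).
#' @param baseline_logit optional explicit logit of the single binary
#'   variable given `Z` (see Details).
#' @return an object of class `"rgl_model"`.
#' @examples
#' m <- lda_model(p = 0.3, gamma1 = 1, gamma2 = 1)
#' implied_logistic(m)
#' @export
rgl_model <- function(loglin, gaussian = NULL, conditioned_names = character(),
                      baseline_logit = NULL) {
  stopifnot(inherits(loglin, "loglinear_spec"))
  d <- length(conditioned_names)
  if (d == 0L) {
    if (!is.null(loglin$theta_cov) || (!is.null(gaussian) && !is.null(gaussian$cov_loadings)))
      stop("covariate loadings supplied but no conditioning variables named")
  } else {
    if (!is.null(loglin$theta_cov) && ncol(loglin$theta_cov) != d)
      stop("'theta_cov' has wrong number of columns")
    if (!is.null(gaussian) && !is.null(gaussian$cov_loadings) &&
        ncol(gaussian$cov_loadings) != d)
      stop("'cov_loadings' has wrong number of columns")
  }
  if (!is.null(baseline_logit)) {
    if (loglin$L != 1L)
      stop("'baseline_logit' is supported only for a single binary variable")
    if (is.null(names(baseline_logit$slopes)))
      names(baseline_logit$slopes) <- conditioned_names
  }
  if (!is.null(gaussian)) {
    stopifnot(inherits(gaussian, "gaussian_layer"))
    if (ncol(gaussian$cat_loadings) != loglin$L)
      stop("'cat_loadings' must have one column per binary variable")
  }
  structure(list(loglin = loglin, gaussian = gaussian,
                 conditioned_names = conditioned_names,
                 baseline_logit = baseline_logit),
            class = "rgl_model")
}

#' @export
print.rgl_model <- function(x, ...) {
  L <- x$loglin$L
  q <- if (is.null(x$gaussian)) 0L else x$gaussian$q
  cat(if (length(x$conditioned_names)) "Conditional restricted" else "Restricted",
      "general location model\n")
  cat("  binary variables:    ", paste(x$loglin$names, collapse = ", "), "\n")
  if (q) cat("  continuous variables:", paste(x$gaussian$names, collapse = ", "), "\n")
  if (length(x$conditioned_names))
    cat("  conditioned on:      ", paste(x$conditioned_names, collapse = ", "), "\n")
  if (length(x$loglin$extra_terms))
    cat("  higher-order log-linear terms:", length(x$loglin$extra_terms), "\n")
  invisible(x)
}

## 2^L x L matrix of cell indicator configurations, in a fixed order
cell_grid <- function(L) {
  g <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g
}

## linear predictor of every cell (before normalisation); z a single vector
cell_lp <- function(loglin, z = NULL, cells = cell_grid(loglin$L)) {
  lp <- cells %*% loglin$theta_main +
    rowSums((cells %*% loglin$theta_pair) * cells)
  if (!is.null(loglin$theta_cov)) {
    if (is.null(z)) stop("conditioning values 'z' required")
    lp <- lp + cells %*% (loglin$theta_cov %*% z)
  }
  for (tm in loglin$extra_terms) {
    lp <- lp + tm$coef * apply(cells[, tm$idx, drop = FALSE], 1L, prod)
  }
  as.numeric(lp)
}

#' Cell probabilities of the log-linear layer
#'
#' Enumerates all `2^L` configurations of the binary variables and returns
#' their probabilities under the log-linear model, optionally at a fixed
#' value of the conditioning variables.  The exponent is max-subtracted
#' before exponentiation so extreme parameter values do not overflow.
#'
#' @param loglin a [loglinear_spec()].
#' @param z numeric vector of conditioning values (required when the spec
#'   has covariate loadings).
#' @return a data frame with one row per cell: the `L` indicator columns and
#'   a `prob` column summing to one.
#' @export
cell_probabilities <- function(loglin, z = NULL) {
  cells <- cell_grid(loglin$L)
  lp <- cell_lp(loglin, z, cells)
  e <- exp(lp - max(lp))
  out <- as.data.frame(cells)
  names(out) <- loglin$names
  out$prob <- e / sum(e)
  out
}

## marginal P(Y_index = 1)
marginal_one <- function(loglin, index, z = NULL) {
  cp <- cell_probabilities(loglin, z)
  sum(cp$prob[cp[[index]] == 1])
}

#' Solve a main effect for a target marginal probability
#'
#' Finds the main-effect value for one binary variable such that its
#' marginal probability of being one equals `target`, holding all other
#' log-linear parameters fixed.  The marginal is strictly increasing in the
#' main effect, so a bracketed root search on `[-50, 50]` finds the unique
#' solution.
#'
#' @param loglin a [loglinear_spec()].
#' @param index which variable's main effect to solve (integer position).
#' @param target the desired marginal probability, in (0, 1).
#' @param z conditioning values, if any.
#' @return the solved main-effect value (scalar).
#' @export
solve_main_effect <- function(loglin, index, target, z = NULL) {
  stopifnot(target > 0, target < 1)
  nm <- loglin$names[index]
  f <- function(th) {
    loglin$theta_main[index] <- th
    marginal_one(loglin, nm, z) - target
  }
  stats::uniroot(f, c(-50, 50), tol = 1e-12)$root
}

#' Dependence of the margin on conditional-model parameters
#'
#' In a pairwise log-linear model with `L >= 4` binary variables, the
#' parameters of the conditional distribution of one variable given the
#' others also move the marginal distribution of the others: the margin
#' carries information about the conditional.  This function quantifies
#' that by perturbing each interaction involving `index` in turn and
#' measuring the total-variation change in the marginal distribution of the
#' remaining variables (computed by exact enumeration).
#'
#' @param loglin a [loglinear_spec()] with pairwise terms only.
#' @param index the variable whose conditional parameters are perturbed.
#' @param delta perturbation added to each interaction parameter.
#' @return named numeric vector: for each other variable `j`, the TV
#'   distance of the marginal of the remaining variables after perturbing
#'   the `index`-`j` interaction by `delta`.
#' @export
margin_dependence <- function(loglin, index, delta = 0.5) {
  L <- loglin$L
  if (length(loglin$extra_terms))
    stop("pairwise-only specifications required")
  others <- setdiff(seq_len(L), index)
  cells <- cell_grid(L)
  marg <- function(ll) {
    p <- cell_probabilities(ll)$prob
    key <- cells[, others, drop = FALSE] %*% 2^(seq_along(others) - 1)
    as.numeric(rowsum(p, key))
  }
  base <- marg(loglin)
  out <- stats::setNames(numeric(length(others)), loglin$names[others])
  for (k in seq_along(others)) {
    j <- others[k]
    ll <- loglin
    lo <- min(index, j); hi <- max(index, j)
    ll$theta_pair[lo, hi] <- ll$theta_pair[lo, hi] + delta
    out[k] <- 0.5 * sum(abs(marg(ll) - base))
  }
  out
}
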