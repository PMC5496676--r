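## ------------------------------------------------------------------
## Synthetic data-generating mechanisms and missingness
## ------------------------------------------------------------------

#' The binary-plus-two-continuous (LDA) generating model
#'
#' Builds the restricted general location model with a single binary
#' variable and two continuous variables
#' \deqn{Y \sim Bernoulli(p),\quad W_1 | Y \sim N(10 + \gamma_1 Y, 9),}
#' \deqn{W_2 | Y, W_1 \sim N(9 + 8/9 + W_1/9 + \gamma_2 Y,\; 8 + 8/9)}
#' expressed in joint form: `theta_w0 = (10, 11)`,
#' `theta_wy = (gamma1, gamma1/9 + gamma2)` and
#' `theta_v = [[9, 1], [1, 9]]`.  With one binary variable this is the
#' classical linear discriminant analysis (LDA) model.
#'
#' @param p marginal probability that `Y = 1`.
#' @param gamma1,gamma2 mean-shift parameters of the two continuous
#'   variables.
#' @return an [rgl_model()].
#' @export
lda_model <- function(p = 0.3, gamma1 = 1, gamma2 = 1) {
  stopifnot(p > 0, p < 1)
  ll <- loglinear_spec(logit(p), names = "Y")
  g <- gaussian_layer(intercept = c(10, 11),
                      cat_loadings = c(gamma1, gamma1 / 9 + gamma2),
                      resid_cov = matrix(c(9, 1, 1, 9), 2, 2),
                      names = c("W1", "W2"))
  rgl_model(ll, g)
}

#' The four-binary pairwise log-linear generating model
#'
#' Log-linear model for four binary variables with main effects
#' `theta_j = -0.5` for `j = 2, 3, 4`, pairwise interactions 0.5 among
#' variables 2--4, interactions of variable 1 with the others given by
#' `theta_setting`, and the main effect of variable 1 solved so that
#' `P(Y1 = 1) = 0.3`.  With `third_order = TRUE` an additional interaction
#' `-2 * Y2 * Y3 * Y4` is included (and the main effect of variable 1
#' re-solved), so the pairwise log-linear family no longer contains the
#' truth while the conditional of `Y1` given the others is still a
#' main-effects logistic regression.
#'
#' @param theta_setting numeric vector `(theta_12, theta_13, theta_14)`.
#' @param third_order add the `-2 * Y2 * Y3 * Y4` term?
#' @return an [rgl_model()] (no Gaussian layer).
#' @export
four_binary_model <- function(theta_setting = c(3, 3, 3), third_order = FALSE) {
  stopifnot(length(theta_setting) == 3)
  tp <- matrix(0, 4, 4)
  tp[1, 2:4] <- theta_setting
  tp[2, 3] <- tp[2, 4] <- tp[3, 4] <- 0.5
  extra <- if (third_order) list(list(idx = 2:4, coef = -2)) else list()
  ll <- loglinear_spec(c(0, -0.5, -0.5, -0.5), tp, extra_terms = extra)
  ll$theta_main[1] <- solve_main_effect(ll, 1L, 0.3)
  rgl_model(ll)
}

#' The gamma-covariate conditional model
#'
#' The conditional general location model used to study misspecification:
#' \deqn{W_1 \sim Gamma(2, 2)\;(shape, rate),\quad
#'       Y | W_1 \sim Bernoulli(expit(-1.9 + W_1)),}
#' \deqn{W_2 | Y, W_1 \sim N(10 + \gamma Y + W_1, 9).}
#' Because `W_1` is not normal given `Y`, this is a CRGL model conditional
#' on `W_1` but not an RGL model.  The cell model given `W_1` is carried as
#' an explicit baseline logit.
#'
#' @param gamma mean shift of `W_2` per unit of `Y`.
#' @return an [rgl_model()] conditioned on `W1`.
#' @export
gamma_misspec_model <- function(gamma = 1) {
  ll <- loglinear_spec(0, names = "Y")
  g <- gaussian_layer(intercept = 10, cat_loadings = gamma, resid_cov = matrix(9),
                      cov_loadings = 1, names = "W2")
  rgl_model(ll, g, conditioned_names = "W1",
            baseline_logit = list(intercept = -1.9, slopes = c(W1 = 1)))
}

#' Construct a data-generating scenario
#'
#' Returns a scenario object bundling a complete-data sampler with the
#' analytic true values of every analysis the scenario supports, so that
#' bias is always measurable against a closed-form (or quadrature) target.
#'
#' Supported scenarios:
#' \describe{
#'   \item{`lda_model`}{[lda_model()]; analyses: logistic / LDA regression
#'     of `Y` on `(W1, W2)`, linear regression of `W2` on `(Y, W1)`,
#'     marginal mean of `Y`.}
#'   \item{`four_binary`}{[four_binary_model()]; analyses: logistic
#'     regression of `Y1` on `(Y2, Y3, Y4)` and the pairwise log-linear
#'     fit, both estimating `(theta_1, theta_12, theta_13, theta_14)`.}
#'   \item{`gamma_misspec`}{[gamma_misspec_model()]; analyses as
#'     `lda_model`, with `W1` the gamma covariate.}
#'   \item{`third_order`}{[four_binary_model()] with the third-order
#'     interaction; analyses as `four_binary`.}
#' }
#'
#' @param name scenario name (see Details).
#' @param p,gamma1,gamma2 parameters of the `lda_model` scenario.
#' @param gamma parameter of the `gamma_misspec` scenario.
#' @param theta_setting parameter triple of the four-binary scenarios.
#' @return an object of class `"mi_scenario"`: a list with the generating
#'   `model`, a `sample(n)` function, column `roles`, and a `truth` list of
#'   named coefficient vectors.
#' @examples
#' sc <- scenario("lda_model", gamma1 = 2, gamma2 = 2)
#' round(sc$truth$logistic, 3)
#' @export
scenario <- function(name = c("lda_model", "four_binary", "gamma_misspec",
                              "third_order"),
                     p = 0.3, gamma1 = 1, gamma2 = 1, gamma = 1,
                     theta_setting = c(3, 3, 3)) {
  name <- match.arg(name)
  if (name == "lda_model") {
    model <- lda_model(p, gamma1, gamma2)
    lg <- implied_logistic(model)
    truth <- list(
      logistic = c("(Intercept)" = lg$intercept, lg$slopes),
      lda      = c("(Intercept)" = lg$intercept, lg$slopes),
      linear   = c("(Intercept)" = 9 + 8 / 9, Y = gamma2, W1 = 1 / 9),
      mean     = c(Y = p))
    sampler <- function(n) stats::simulate(model, n)
    roles <- list(categorical = "Y", continuous = c("W1", "W2"))
  } else if (name %in% c("four_binary", "third_order")) {
    model <- four_binary_model(theta_setting, third_order = name == "third_order")
    th <- c(model$loglin$theta_main[1], model$loglin$theta_pair[1, 2:4])
    names(th) <- c("(Intercept)", "Y2", "Y3", "Y4")
    truth <- list(
      logistic  = th,
      loglinear = stats::setNames(th, c("theta1", "theta12", "theta13", "theta14")),
      mean      = c(Y1 = 0.3))
    sampler <- function(n) stats::simulate(model, n)
    roles <- list(categorical = paste0("Y", 1:4), continuous = character())
  } else {
    model <- gamma_misspec_model(gamma)
    lg <- implied_logistic(model)
    ey <- stats::integrate(function(w) expit(-1.9 + w) * stats::dgamma(w, 2, 2),
                           0, Inf, rel.tol = 1e-10)$value
    truth <- list(
      logistic = c("(Intercept)" = lg$intercept, lg$slopes),
      linear   = c("(Intercept)" = 10, Y = gamma, W1 = 1),
      mean     = c(Y = ey))
    sampler <- function(n) {
      w1 <- stats::rgamma(n, shape = 2, rate = 2)
      out <- stats::simulate(model, n, z = data.frame(W1 = w1))
      out[c("Y", "W1", "W2")]
    }
    roles <- list(categorical = "Y", continuous = c("W1", "W2"))
  }
  structure(list(name = name, model = model, sample = sampler,
                 truth = truth, roles = roles),
            class = "mi_scenario")
}

#' @export
print.mi_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  cat("  columns:", paste(c(x$roles$categorical, x$roles$continuous), collapse = ", "), "\n")
  cat("  analyses with analytic truth:", paste(names(x$truth), collapse = ", "), "\n")
  invisible(x)
}

## ------------------------------------------------------------------
## Missingness mechanisms
## ------------------------------------------------------------------

#' Specify a missingness mechanism
#'
#' MCAR masks each target column independently with probability `rate`.
#' MAR masks each target column independently given a fully observed
#' predictor, with `P(missing) = expit(intercept + slope * predictor)`.
#' When `intercept = NULL` it is solved so that the marginal missingness
#' probability equals `rate` (see [solve_mar_intercept()]).
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param targets character vector of columns subject to missingness.
#' @param rate target marginal probability of missingness.
#' @param predictor fully observed column driving MAR missingness.
#' @param slope coefficient on the predictor in the logistic missingness
#'   model.
#' @param intercept intercept of the logistic missingness model, or `NULL`
#'   to solve it from `rate` when the mechanism is applied.
#' @return an object of class `"missingness_spec"`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR"), targets,
                             rate = 0.5, predictor = NULL, slope = NULL,
                             intercept = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(rate >= 0, rate < 1)
  if (mechanism == "MAR") {
    if (rate == 0) stop("MAR requires a positive rate")
    if (is.null(predictor) || is.null(slope))
      stop("MAR requires 'predictor' and 'slope'")
    if (predictor %in% targets)
      stop("the MAR predictor cannot itself be a missingness target")
  }
  structure(list(mechanism = mechanism, targets = targets, rate = rate,
                 predictor = predictor, slope = slope, intercept = intercept),
            class = "missingness_spec")
}

#' Solve the intercept of a logistic missingness model
#'
#' Finds `c` such that the Monte-Carlo estimate of
#' `E[expit(c + slope * predictor)]` equals `rate`.  The same predictor
#' draws are reused across evaluations (common random numbers), so the
#' Monte-Carlo average is monotone and smooth in `c` and a bracketed root
#' search applies.
#'
#' @param slope coefficient on the predictor.
#' @param predictor numeric vector of predictor draws, or a function `n ->
#'   draws`.
#' @param rate target marginal probability.
#' @param mc_n number of draws when `predictor` is a function.
#' @return the solved intercept.
#' @export
solve_mar_intercept <- function(slope, predictor, rate = 0.5, mc_n = 1e5) {
  w <- if (is.function(predictor)) predictor(mc_n) else predictor
  f <- function(c0) mean(expit(c0 + slope * w)) - rate
  stats::uniroot(f, c(-60, 60), tol = 1e-10)$root
}

#' Impose missingness on a complete dataset
#'
#' Masks the target columns of `data` (independently across columns, given
#' the predictor) according to a [missingness_spec()].  Values are never
#' altered, only replaced by `NA`; the returned data frame carries the
#' column roles and the missingness indicators as attributes.
#'
#' @param data complete data frame.
#' @param spec a [missingness_spec()].
#' @param roles list with elements `categorical` and `continuous`; defaults
#'   to classifying columns with more than two distinct observed values as
#'   continuous.
#' @param seed optional integer seed.
#' @return `data` with `NA`s inserted, of class `"incomplete_data"`, with
#'   attributes `roles` and `miss_mask` (logical matrix, `TRUE` = missing).
#' @export
apply_missingness <- function(data, spec, roles = NULL, seed = NULL) {
  stopifnot(inherits(spec, "missingness_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(data[spec$targets])) stop("'data' must be complete")
  n <- nrow(data)
  if (spec$mechanism == "MCAR") {
    pmiss <- rep(spec$rate, n)
  } else {
    w <- data[[spec$predictor]]
    c0 <- spec$intercept %||% solve_mar_intercept(spec$slope, w, spec$rate)
    pmiss <- expit(c0 + spec$slope * w)
  }
  out <- data
  mask <- matrix(FALSE, n, ncol(data), dimnames = list(NULL, names(data)))
  for (tg in spec$targets) {
    mis <- stats::runif(n) < pmiss
    out[[tg]][mis] <- NA
    mask[, tg] <- mis
  }
  if (is.null(roles)) roles <- guess_roles(data)
  incomplete_data(out, roles, mask)
}

guess_roles <- function(data) {
  is_cat <- vapply(data, function(v) {
    u <- unique(v[!is.na(v)])
    length(u) <= 2 && all(u %in% c(0, 1))
  }, logical(1))
  list(categorical = names(data)[is_cat], continuous = names(data)[!is_cat])
}

#' Mark a data frame as an incomplete dataset
#'
#' @param data data frame, possibly containing `NA`s.
#' @param roles list with character elements `categorical` and
#'   `continuous` naming the modelled columns.
#' @param miss_mask optional logical matrix of missingness indicators;
#'   defaults to `is.na(data)`.
#' @return `data` with class `"incomplete_data"` and the roles attached.
#' @export
incomplete_data <- function(data, roles = NULL, miss_mask = NULL) {
  if (is.null(roles)) roles <- guess_roles(data)
  if (is.null(miss_mask)) miss_mask <- is.na(as.matrix(data))
  obs <- data[roles$categorical]
  ok <- vapply(obs, function(v) all(v[!is.na(v)] %in% c(0, 1)), logical(1))
  if (!all(ok)) stop("categorical columns must be coded 0/1")
  structure(data, roles = roles, miss_mask = miss_mask,
            class = c("incomplete_data", "data.frame"))
}

## ------------------------------------------------------------------
## Plain-text round trips
## ------------------------------------------------------------------

#' Write/read an (incomplete) dataset as CSV
#'
#' Missing cells are written as empty fields.
#'
#' @param data data frame.
#' @param file path.
#' @return `read_incomplete_csv` returns an [incomplete_data()] object.
#' @export
write_incomplete_csv <- function(data, file) {
  utils::write.csv(as.data.frame(data), file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_incomplete_csv
#' @param roles optional column roles (see [incomplete_data()]).
#' @export
read_incomplete_csv <- function(file, roles = NULL) {
  df <- utils::read.csv(file, na.strings = "")
  incomplete_data(df, roles)
}
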