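## ------------------------------------------------------------------
## Relative-efficiency and bias studies
## ------------------------------------------------------------------

#' Complete-data asymptotic RE of LDA versus logistic regression
#'
#' For the binary-plus-two-continuous generating model, computes the
#' asymptotic relative efficiency (percentage variance ratio, logistic
#' over LDA) of the two complete-data estimators of the logistic
#' coefficients.  The logistic asymptotic variance is the inverse expected
#' information under the true two-component normal mixture, evaluated by
#' Monte-Carlo integration; the LDA asymptotic variance is the delta-method
#' transform of the analytic asymptotic covariance of the mixture ML
#' estimates (prevalence, class means, pooled covariance).  Monte-Carlo
#' standard errors are obtained by sectioning the Monte-Carlo sample.
#'
#' @param p,gamma1,gamma2 generating-model parameters.
#' @param mc_n Monte-Carlo draws for the expected logistic information.
#' @param sections number of sections for the Monte-Carlo standard error.
#' @param seed optional integer seed.
#' @return a data frame of class `"re_report"`: one row per coefficient
#'   with columns `parameter`, `re` (percent) and `mc_se`.
#' @export
asymptotic_re_lda_logistic <- function(p, gamma1, gamma2, mc_n = 1e6,
                                       sections = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- lda_model(p, gamma1, gamma2)
  lg <- implied_logistic(model)
  beta <- c(lg$intercept, lg$slopes)

  ## analytic LDA asymptotic covariance (delta method on the mixture MLEs)
  g <- model$gaussian
  S <- g$resid_cov
  mu0 <- g$intercept
  mu1 <- mu0 + g$cat_loadings[, 1L]
  eta <- c(p, mu0, mu1, S[upper.tri(S, diag = TRUE)])
  q <- 2L
  J <- num_jacobian(function(e) lda_beta_from_eta(e, q), eta)
  avar_lda <- diag(J %*% lda_eta_avar(eta, q) %*% t(J))

  ## MC expected logistic information, sectioned
  dat <- stats::simulate(model, mc_n)
  X <- cbind(1, dat$W1, dat$W2)
  v <- expit(drop(X %*% beta))
  v <- v * (1 - v)
  sec <- rep(seq_len(sections), length.out = mc_n)
  re_sec <- matrix(0, sections, 3L)
  for (s in seq_len(sections)) {
    i <- sec == s
    info <- crossprod(X[i, , drop = FALSE] * sqrt(v[i])) / sum(i)
    re_sec[s, ] <- diag(solve(info)) / avar_lda * 100
  }
  info_all <- crossprod(X * sqrt(v)) / mc_n
  re <- diag(solve(info_all)) / avar_lda * 100
  mc_se <- apply(re_sec, 2L, stats::sd) / sqrt(sections)
  structure(data.frame(parameter = c("(Intercept)", "W1", "W2"),
                       re = re, mc_se = mc_se),
            class = c("re_report", "data.frame"),
            scenario = sprintf("lda_model p=%g gamma1=%g gamma2=%g", p, gamma1, gamma2),
            comparison = "LDA vs logistic, complete data (asymptotic)")
}

#' Exact complete-data RE of the log-linear versus logistic estimators
#'
#' For the four-binary pairwise log-linear generating model, computes the
#' asymptotic relative efficiency (percentage variance ratio, logistic
#' over log-linear) of estimating `(theta_1, theta_12, theta_13,
#' theta_14)` by fitting the pairwise log-linear model versus the implied
#' logistic regression of the first variable on the others.  Both expected
#' information matrices are evaluated exactly by summation over the 16
#' cells; no simulation is involved.
#'
#' @param theta_setting the `(theta_12, theta_13, theta_14)` triple.
#' @return a data frame of class `"re_report"` with columns `parameter`
#'   and `re`.
#' @export
exact_re_loglinear_logistic <- function(theta_setting = c(3, 3, 3)) {
  model <- four_binary_model(theta_setting)
  ll <- model$loglin
  cells <- cell_grid(4L)
  prob <- cell_probabilities(ll)$prob
  pr <- t(utils::combn(4, 2))
  X <- cbind(cells, cells[, pr[, 1]] * cells[, pr[, 2]])
  colnames(X) <- c(paste0("theta", 1:4), paste0("theta", pr[, 1], pr[, 2]))
  ## multinomial expected information for the log-linear parameters
  Xp <- crossprod(X, prob)
  info_ll <- crossprod(X, X * prob) - Xp %*% t(Xp)
  v_ll <- diag(solve(info_ll))[c("theta1", "theta12", "theta13", "theta14")]
  ## logistic expected information, summed over covariate configurations
  th1 <- ll$theta_main[1]
  th1j <- ll$theta_pair[1, 2:4]
  info_lr <- matrix(0, 4L, 4L)
  for (r in which(cells[, 1] == 0)) {
    y234 <- cells[r, 2:4]
    x <- c(1, y234)
    pc <- prob[r] + prob[r + 1L]     # first indicator varies fastest
    pi1 <- expit(th1 + sum(th1j * y234))
    info_lr <- info_lr + pc * pi1 * (1 - pi1) * tcrossprod(x)
  }
  v_lr <- diag(solve(info_lr))
  structure(data.frame(parameter = c("theta1", "theta12", "theta13", "theta14"),
                       re = unname(v_lr / v_ll * 100)),
            class = c("re_report", "data.frame"),
            scenario = sprintf("four_binary (%s)", paste(theta_setting, collapse = ",")),
            comparison = "log-linear vs logistic, complete data (exact)")
}

#' @export
print.re_report <- function(x, digits = 1, ...) {
  cat("Relative efficiency (%):", attr(x, "comparison"), "\n")
  cat("  scenario:", attr(x, "scenario"), "\n")
  print.data.frame(round_df(x, digits))
  invisible(x)
}

round_df <- function(x, digits) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], round, digits = digits)
  as.data.frame(x)
}

## shared replicate loop for the simulation studies: generate, mask,
## impute with both engines on the same incomplete data, pool analyses
run_mi_replicates <- function(sc, miss_spec, analyses, n, M, reps, seed,
                              methods = c("fcs", "rgl"),
                              exclude_imputed_outcome = FALSE,
                              include_complete = FALSE,
                              engine_args = list()) {
  if (is.null(names(methods))) names(methods) <- methods
  res <- list()
  failures <- 0L
  for (r in seq_len(reps)) {
    set.seed(child_seed(seed, r))
    out_r <- tryCatch({
      dat <- sc$sample(n)
      inc <- apply_missingness(dat, miss_spec, roles = sc$roles)
      imps <- list()
      for (nm in names(methods)) {
        fn <- if (methods[[nm]] == "rgl") rgl_impute else fcs_impute
        imps[[nm]] <- do.call(fn, c(list(inc, M = M), engine_args[[methods[[nm]]]]))
      }
      one <- list()
      for (a in analyses) {
        for (meth in names(imps)) {
          pooled <- pool_analysis(imps[[meth]], a$analysis, a$outcome, a$covariates,
                                  exclude_imputed_outcome = exclude_imputed_outcome)
          one[[paste(a$analysis, meth, sep = ".")]] <- coef(pooled)
        }
        if (include_complete)
          one[[paste(a$analysis, "complete", sep = ".")]] <-
            coef(run_analysis(a$analysis, dat, a$outcome, a$covariates))
      }
      one
    }, error = function(e) e)
    if (inherits(out_r, "error")) {
      failures <- failures + 1L
      if (failures > 0.05 * reps)
        stop("more than 5% of replicates failed; last error: ",
             conditionMessage(out_r))
      next
    }
    res[[length(res) + 1L]] <- out_r
  }
  list(res = res, failures = failures)
}

#' Simulation-based RE of RGL MI versus FCS MI
#'
#' Estimates, by repeated simulation, the relative efficiency of the
#' Rubin's-rules estimator under joint-model (RGL) imputation versus
#' chained-equations (FCS) imputation.  Each replicate generates a
#' complete dataset from the scenario, applies the missingness mechanism,
#' imputes the same incomplete data with both engines (common random
#' numbers across arms), and pools each requested analysis.  The RE per
#' coefficient is the ratio of empirical variances across replicates (FCS
#' over RGL) times 100; its Monte-Carlo standard error is obtained by
#' jackknifing over replicates.
#'
#' @param sc an [scenario()] object.
#' @param miss_spec a [missingness_spec()].
#' @param analyses list of analyses, each a list with elements `analysis`,
#'   `outcome`, `covariates`.
#' @param n sample size per replicate.
#' @param M imputations per engine.
#' @param reps number of replicates (at least 50).
#' @param seed master seed; replicate seeds are derived from it.
#' @param arms the two imputation arms to compare (each `"fcs"` or
#'   `"rgl"`); the reported RE is the variance of the first arm's pooled
#'   estimator over that of the second.  Using the same engine in both
#'   arms gives a self-RE identity check.
#' @param engine_args optional list with elements `rgl` and `fcs` of extra
#'   engine arguments.
#' @return a data frame of class `"re_report"`: `analysis`, `parameter`,
#'   `re`, `mc_se`, plus attributes recording the design.
#' @export
mi_re_simulation <- function(sc, miss_spec, analyses, n = 1000, M = 25,
                             reps = 200, seed = 1, arms = c("fcs", "rgl"),
                             engine_args = list()) {
  stopifnot(reps >= 50, length(arms) == 2)
  if (is.null(names(arms))) names(arms) <- make.unique(arms)
  run <- run_mi_replicates(sc, miss_spec, analyses, n, M, reps, seed,
                           methods = arms, engine_args = engine_args)
  out <- NULL
  for (a in analyses) {
    fcs <- do.call(rbind, lapply(run$res, `[[`, paste(a$analysis, names(arms)[1], sep = ".")))
    rgl <- do.call(rbind, lapply(run$res, `[[`, paste(a$analysis, names(arms)[2], sep = ".")))
    R <- nrow(fcs)
    re <- apply(fcs, 2L, stats::var) / apply(rgl, 2L, stats::var) * 100
    ## leave-one-replicate-out jackknife
    jk <- vapply(seq_len(R), function(i) {
      apply(fcs[-i, , drop = FALSE], 2L, stats::var) /
        apply(rgl[-i, , drop = FALSE], 2L, stats::var) * 100
    }, numeric(ncol(fcs)))
    jk <- matrix(jk, nrow = ncol(fcs))
    mc_se <- sqrt((R - 1) / R * rowSums((jk - rowMeans(jk))^2))
    out <- rbind(out, data.frame(analysis = a$analysis, parameter = colnames(fcs),
                                 re = unname(re), mc_se = unname(mc_se)))
  }
  structure(out, class = c("re_report", "data.frame"),
            scenario = sc$name,
            comparison = sprintf("%s MI vs %s MI (simulation, n=%d, M=%d, reps=%d, %d failures)",
                                 toupper(arms[2]), toupper(arms[1]),
                                 n, M, length(run$res), run$failures))
}

#' Bias study of the imputation engines under a misspecified joint model
#'
#' For each replicate, fits every requested analysis to the complete data
#' and to the data imputed by each engine, and reports the mean estimates
#' against the scenario's analytic truth.
#'
#' @inheritParams mi_re_simulation
#' @param methods imputation arms to run (subset of `"fcs"`, `"rgl"`).
#' @param exclude_imputed_outcome drop rows with imputed outcome before
#'   each pooled analysis.
#' @return a data frame of class `"bias_report"`: `method`, `analysis`,
#'   `parameter`, `mean`, `truth`, `bias`, `mc_se`.
#' @export
bias_study <- function(sc, miss_spec, analyses, n = 1000, M = 25, reps = 200,
                       seed = 1, methods = c("fcs", "rgl"),
                       exclude_imputed_outcome = FALSE, engine_args = list()) {
  run <- run_mi_replicates(sc, miss_spec, analyses, n, M, reps, seed,
                           methods = methods,
                           exclude_imputed_outcome = exclude_imputed_outcome,
                           include_complete = TRUE,
                           engine_args = engine_args)
  out <- NULL
  for (a in analyses) {
    truth <- sc$truth[[a$analysis]]
    for (meth in c("complete", methods)) {
      est <- do.call(rbind, lapply(run$res, `[[`, paste(a$analysis, meth, sep = ".")))
      mn <- colMeans(est)
      se <- apply(est, 2L, stats::sd) / sqrt(nrow(est))
      tr <- if (!is.null(truth)) unname(truth[colnames(est)]) else NA_real_
      out <- rbind(out, data.frame(method = meth, analysis = a$analysis,
                                   parameter = colnames(est), mean = unname(mn),
                                   truth = tr, bias = unname(mn) - tr,
                                   mc_se = unname(se)))
    }
  }
  structure(out, class = c("bias_report", "data.frame"),
            scenario = sc$name,
            design = sprintf("n=%d, M=%d, reps=%d, %d failures%s", n, M,
                             length(run$res), run$failures,
                             if (exclude_imputed_outcome) ", imputed outcomes excluded" else ""))
}

#' @export
print.bias_report <- function(x, digits = 3, ...) {
  cat("Bias study --", attr(x, "scenario"), "\n")
  cat("  design:", attr(x, "design"), "\n")
  print.data.frame(round_df(x, digits))
  invisible(x)
}
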