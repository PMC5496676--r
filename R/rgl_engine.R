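## ------------------------------------------------------------------
## Joint-model imputation under the (C)RGL model: data augmentation
## ------------------------------------------------------------------

## One Bayesian-IPF sweep sequence for the pairwise log-linear model.
## 'tab' is the current 2^L cell-probability vector (the Markov-chain
## state), 'counts' the observed cell counts of the completed data,
## 'flatten' the Dirichlet-type flattening count per joint cell.  Each
## cycle visits every two-way margin: the margin distribution is redrawn
## from its Dirichlet posterior and the table rescaled to match it,
## preserving the within-margin conditional structure.  The kernel leaves
## the constrained posterior invariant; 'cycles' sweeps are run per P-step.
bipf_margins <- function(L) {
  cells <- cell_grid(L)
  pairs <- t(utils::combn(L, 2))
  lapply(seq_len(nrow(pairs)), function(r) {
    key <- cells[, pairs[r, 1]] + 2L * cells[, pairs[r, 2]] + 1L
    ind <- matrix(0, 2L^L, 4L)
    ind[cbind(seq_len(2L^L), key)] <- 1
    list(key = key, ind = ind)
  })
}

bipf_draw <- function(tab, counts, margins, flatten, cycles) {
  L <- round(log2(length(tab)))
  prior_margin <- flatten * 2^(L - 2)
  shape <- lapply(margins, function(m) drop(crossprod(m$ind, counts)) + prior_margin)
  for (cy in seq_len(cycles)) {
    for (r in seq_along(margins)) {
      m <- margins[[r]]
      g <- stats::rgamma(4L, shape[[r]])
      g <- g / sum(g)
      cur <- drop(crossprod(m$ind, tab))
      tab <- tab * (g / cur)[m$key]
    }
  }
  tab / sum(tab)
}

## P-step for the Gaussian layer: multivariate regression of W on
## (1, Y, Z) under the noninformative prior |Sigma|^{-(q+1)/2}:
## Sigma | data ~ inverse Wishart(n - p, SSE), vec(B) | Sigma matrix-normal.
draw_gaussian_layer <- function(W, X) {
  n <- nrow(X); p <- ncol(X); q <- ncol(W)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) chol(XtX + 1e-8 * diag(p)))
  Bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(X, W)))
  E <- W - X %*% Bhat
  SSE <- crossprod(E)
  df <- max(n - p, q + 2L)
  Sigma <- tryCatch({
    Prec <- stats::rWishart(1L, df, chol2inv(chol(SSE)))[, , 1L]
    chol2inv(chol(Prec))
  }, error = function(e) SSE / df)           # near-singular fallback
  ## vec(B - Bhat) ~ N(0, Sigma (x) (X'X)^-1)
  Z <- matrix(stats::rnorm(p * q), p, q)
  B <- Bhat + backsolve(ch, Z) %*% chol(Sigma)
  list(B = B, Sigma = Sigma)
}

## P-step: draw all joint-model parameters given currently completed data
rgl_pstep <- function(cur, info, state, prior_flatten, bipf_cycles) {
  L <- length(info$categorical)
  Ymat <- as.matrix(cur[info$categorical])
  if (is.null(info$conditioned) || length(info$conditioned) == 0L) {
    counts <- tabulate(drop(Ymat %*% 2^(seq_len(L) - 1L)) + 1L, nbins = 2L^L)
    if (L <= 2L) {
      state$cellp <- {
        g <- stats::rgamma(2L^L, counts + prior_flatten)
        g / sum(g)
      }
    } else {
      state$cellp <- bipf_draw(state$cellp, counts, info$margins,
                               prior_flatten, bipf_cycles)
    }
  } else {
    ## conditional cell model: logistic regression of the single binary
    ## variable on the conditioning columns
    X <- cbind(1, as.matrix(cur[info$conditioned]))
    state$cat_beta <- draw_logistic_conditional(Ymat[, 1L], X)$beta
  }
  if (length(info$continuous)) {
    X <- cbind(1, Ymat,
               if (length(info$conditioned)) as.matrix(cur[info$conditioned]))
    dr <- draw_gaussian_layer(as.matrix(cur[info$continuous]), X)
    state$B <- dr$B
    state$Sigma <- dr$Sigma
  }
  state
}

## log P(cells) for every row (n x 2^L), under either parameterisation
cell_logp_rows <- function(cur, info, state, n) {
  L <- length(info$categorical)
  if (is.null(state$cat_beta)) {
    matrix(log(pmax(state$cellp, 1e-300)), n, 2L^L, byrow = TRUE)
  } else {
    eta <- drop(cbind(1, as.matrix(cur[info$conditioned])) %*% state$cat_beta)
    cbind(-log1p(exp(eta)), eta - log1p(exp(eta)))   # cells (0, 1)
  }
}

## I-step: redraw every missing value from its conditional given all
## currently observed/imputed values and the drawn parameters; exact
## joint draw (cell first, then continuous given cell)
rgl_istep <- function(cur, miss, info, state) {
  catv <- info$categorical; contv <- info$continuous
  L <- length(catv); q <- length(contv)
  has_z <- length(info$conditioned) > 0L
  Zmat <- if (has_z) as.matrix(cur[info$conditioned]) else NULL
  logp_all <- NULL

  for (grp in info$groups) {
    rows <- grp$rows
    mis_cat <- grp$mis_cat
    mis_cont <- grp$mis_cont
    nr <- length(rows)
    obs_cont <- setdiff(contv, mis_cont)

    ## -- categorical part: enumerate candidate completions
    if (length(mis_cat)) {
      kc <- length(mis_cat)
      cand <- cell_grid(kc)
      ncand <- 2L^kc
      if (is.null(logp_all))
        logp_all <- cell_logp_rows(cur, info, state, nrow(cur))
      Yobs <- as.matrix(cur[rows, catv, drop = FALSE])
      logw <- matrix(0, nr, ncand)
      keybase <- 2^(seq_len(L) - 1L)
      mis_idx <- match(mis_cat, catv)
      for (j in seq_len(ncand)) {
        Yc <- Yobs
        Yc[, mis_idx] <- matrix(cand[j, ], nr, kc, byrow = TRUE)
        key <- drop(Yc %*% keybase) + 1L
        logw[, j] <- logp_all[cbind(rows, key)]
        if (length(obs_cont)) {
          mu <- gauss_mean(Yc, Zmat, rows, info, state)[, match(obs_cont, contv), drop = FALSE]
          logw[, j] <- logw[, j] +
            dmvnorm_log(as.matrix(cur[rows, obs_cont, drop = FALSE]), mu,
                        state$Sigma[match(obs_cont, contv), match(obs_cont, contv), drop = FALSE])
        }
      }
      rowmax <- do.call(pmax, lapply(seq_len(ncand), function(j) logw[, j]))
      pick <- sample_rows(exp(logw - rowmax))
      for (v in seq_len(kc))
        cur[[mis_cat[v]]][rows] <- cand[pick, v]
    }

    ## -- continuous part: conditional normal given cell and observed W
    if (length(mis_cont)) {
      Yc <- as.matrix(cur[rows, catv, drop = FALSE])
      mu <- gauss_mean(Yc, Zmat, rows, info, state)
      im <- match(mis_cont, contv)
      io <- match(obs_cont, contv)
      S <- state$Sigma
      if (length(io)) {
        sl <- t(solve(S[io, io, drop = FALSE], S[io, im, drop = FALSE]))
        condS <- S[im, im, drop = FALSE] - sl %*% S[io, im, drop = FALSE]
        dev <- as.matrix(cur[rows, obs_cont, drop = FALSE]) - mu[, io, drop = FALSE]
        cmean <- mu[, im, drop = FALSE] + dev %*% t(sl)
      } else {
        condS <- S[im, im, drop = FALSE]
        cmean <- mu[, im, drop = FALSE]
      }
      condS <- (condS + t(condS)) / 2
      draw <- rmvnorm_chol(nr, cmean, chol(condS))
      for (v in seq_along(mis_cont))
        cur[[mis_cont[v]]][rows] <- draw[, v]
    }
  }
  cur
}

## cell means of the Gaussian layer for given cat values / rows
gauss_mean <- function(Ymat, Zmat, rows, info, state) {
  X <- cbind(1, Ymat, if (!is.null(Zmat)) Zmat[rows, , drop = FALSE])
  X %*% state$B
}

#' Joint-model multiple imputation under the (C)RGL model
#'
#' Data-augmentation Gibbs sampler for the restricted general location
#' model.  Each iteration alternates a P-step -- drawing the joint-model
#' parameters from their posterior given the currently completed data
#' (Bayesian iterative proportional fitting for the pairwise log-linear
#' cell probabilities, conjugate matrix-normal / inverse-Wishart draws for
#' the Gaussian layer) -- with an I-step that redraws every missing value
#' from its exact conditional given the drawn parameters: the cell of each
#' row is drawn with probability proportional to cell probability times
#' the normal density of its observed continuous values at that cell, and
#' missing continuous values from the conditional normal.  After burn-in,
#' every `thin`-th completed dataset is retained, giving `M` imputations
#' from one chain.
#'
#' Conditioning columns (`conditioned`) are never modelled or imputed:
#' they enter the Gaussian layer as regressors, and (for a single binary
#' variable) the cell model given them is a logistic regression.
#'
#' @param data an [incomplete_data()] object or data frame with `NA`s.
#' @param categorical,continuous modelled column names; default taken from
#'   the data's roles.
#' @param conditioned fully observed conditioning columns (CRGL).
#' @param M number of imputations.
#' @param burn_in iterations discarded before the first retained draw.
#' @param thin iterations between retained draws.
#' @param prior_flatten Dirichlet-type flattening count per cell for the
#'   log-linear layer (a proper, near-flat prior).
#' @param bipf_cycles Bayesian-IPF sweeps per P-step.
#' @param seed optional integer seed.
#' @return an object of class `"mi_result"` (see [fcs_impute()]), with a
#'   `trace` matrix of per-iteration column means of the modelled columns
#'   as a convergence diagnostic.
#' @export
rgl_impute <- function(data, categorical = NULL, continuous = NULL,
                       conditioned = character(), M = 50, burn_in = 100,
                       thin = 10, prior_flatten = 0.1, bipf_cycles = 20,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roles <- attr(data, "roles")
  categorical <- categorical %||% roles$categorical
  continuous <- continuous %||% roles$continuous
  L <- length(categorical)
  if (L < 1L) stop("at least one binary variable is required")
  if (length(conditioned) && L > 1L)
    stop("conditioning columns are supported with a single binary variable only")
  cols <- c(categorical, continuous, conditioned)
  df <- as.data.frame(data)[cols]
  miss <- is.na(as.matrix(df))
  if (any(vapply(df[c(categorical, continuous)], function(v) all(is.na(v)), logical(1))))
    stop("a column is entirely missing")
  if (any(miss[, conditioned])) stop("conditioning columns must be fully observed")
  info <- list(categorical = categorical, continuous = continuous,
               conditioned = conditioned,
               margins = if (L > 2L) bipf_margins(L))

  ## group rows by missingness pattern once
  pat_cols <- c(categorical, continuous)
  patkey <- do.call(paste, c(as.data.frame(miss[, pat_cols, drop = FALSE]), sep = ""))
  groups <- list()
  for (pt in unique(patkey)) {
    rows <- which(patkey == pt)
    m <- miss[rows[1L], pat_cols]
    mis_cat <- categorical[m[categorical]]
    mis_cont <- continuous[m[continuous]]
    if (!length(mis_cat) && !length(mis_cont)) next
    groups[[length(groups) + 1L]] <- list(rows = rows, mis_cat = mis_cat,
                                          mis_cont = mis_cont)
  }
  info$groups <- groups

  any_missing <- any(miss[, c(categorical, continuous)])
  if (!any_missing) {
    return(structure(list(completed = rep(list(df), M), miss_mask = miss,
                          method = "rgl",
                          settings = list(M = M, burn_in = burn_in, thin = thin,
                                          seed = seed),
                          trace = NULL),
                     class = "mi_result"))
  }
  cur <- initial_fill(df, miss)
  state <- list(cellp = rep(1 / 2^L, 2^L), cat_beta = NULL, B = NULL, Sigma = NULL)
  n_iter <- burn_in + M * thin
  trace <- matrix(NA_real_, n_iter, length(c(categorical, continuous)),
                  dimnames = list(NULL, c(categorical, continuous)))
  completed <- vector("list", M)
  got <- 0L
  for (it in seq_len(n_iter)) {
    state <- rgl_pstep(cur, info, state, prior_flatten, bipf_cycles)
    cur <- rgl_istep(cur, miss, info, state)
    trace[it, ] <- colMeans(as.matrix(cur[c(categorical, continuous)]))
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      got <- got + 1L
      completed[[got]] <- cur
    }
  }
  structure(list(completed = completed, miss_mask = miss, method = "rgl",
                 settings = list(M = M, burn_in = burn_in, thin = thin,
                                 prior_flatten = prior_flatten,
                                 bipf_cycles = bipf_cycles, seed = seed),
                 trace = trace),
            class = "mi_result")
}

#' @export
plot.mi_result <- function(x, ...) {
  if (is.null(x$trace)) stop("no trace available for this engine")
  nc <- ncol(x$trace)
  op <- graphics::par(mfrow = c(nc, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(nc)) {
    graphics::plot(x$trace[, j], type = "l", ylab = colnames(x$trace)[j],
                   xlab = "iteration", ...)
    graphics::abline(v = x$settings$burn_in, lty = 2)
  }
  invisible(x)
}
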