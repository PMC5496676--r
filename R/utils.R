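#' Inverse logit
#'
#' @param x numeric vector of log odds.
#' @return `1 / (1 + exp(-x))`, computed stably for large `|x|`.
#' @export
expit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

#' Logit
#'
#' @param p numeric vector of probabilities in (0, 1).
#' @return log odds `log(p / (1 - p))`.
#' @export
logit <- function(p) log(p) - log1p(-p)

## multivariate normal draws: mean matrix (n x q) + chol(Sigma) noise
rmvnorm_chol <- function(n, mean, chol_upper) {
  q <- ncol(chol_upper)
  z <- matrix(stats::rnorm(n * q), n, q)
  mean + z %*% chol_upper
}

## row-wise log density of an MVN with common covariance; x and mean n x q
dmvnorm_log <- function(x, mean, sigma) {
  q <- ncol(sigma)
  ch <- chol(sigma)
  dev <- backsolve(ch, t(x - mean), transpose = TRUE)
  -0.5 * q * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(dev^2)
}

## categorical draw: one index per row of a matrix of (unnormalised) weights
sample_rows <- function(w) {
  cw <- w %*% upper.tri(diag(ncol(w)), diag = TRUE)
  u <- stats::runif(nrow(w)) * cw[, ncol(w)]
  ncol(w) + 1L - rowSums(cw >= u)
}

## derive a child seed (< 2^31) from a master seed and an index
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + index * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
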