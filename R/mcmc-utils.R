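# Small MCMC helpers: multivariate normal draws from a precision matrix,
# split-chain potential scale reduction, and effective sample size.

# draw x ~ N(A^{-1} b, A^{-1}) given precision matrix A (adds a tiny ridge
# retry if the Cholesky fails)
.draw_mvn_prec <- function(A, b) {
  R <- tryCatch(chol(A), error = function(e) {
    chol(A + diag(1e-8 * max(diag(A)), nrow(A)))
  })
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  as.numeric(mu + backsolve(R, rnorm(length(b))))
}

# scalar Gaussian draw given precision and precision-weighted mean numerator
.draw_norm_prec <- function(prec, num) {
  if (any(prec <= 0)) stop("non-positive conditional precision")
  num / prec + rnorm(length(num)) / sqrt(prec)
}

#' Split-chain potential scale reduction factor
#'
#' Classic R-hat computed after splitting each chain in half, so that
#' within-chain trends register as disagreement.
#'
#' @param x iterations x chains matrix of draws for one scalar parameter.
#' @return R-hat (NA for constant parameters).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  if (sd(sub) < 1e-13 * (1 + mean(abs(sub)))) return(NA_real_)
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  B <- nn * var(means)
  W <- mean(apply(sub, 2, var))
  if (W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size
#'
#' Sum over chains of the initial-positive-sequence autocorrelation estimate.
#'
#' @param x iterations x chains matrix of draws for one scalar parameter.
#' @return estimated effective number of draws.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  per_chain <- function(v) {
    n <- length(v)
    if (sd(v) < 1e-13 * (1 + mean(abs(v)))) return(NA_real_)
    lag_max <- min(n - 1, 500)
    rho <- as.numeric(stats::acf(v, lag.max = lag_max, plot = FALSE,
                                 demean = TRUE)$acf)[-1]
    s <- 0; k <- 1
    while (k <= length(rho) - 1) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    n / (1 + 2 * s)
  }
  sum(apply(x, 2, per_chain))
}

# summarize a draws matrix (rows = iterations, one chain stacked per block)
.diagnose <- function(draws, n_chains) {
  it <- nrow(draws) / n_chains
  out <- data.frame(parameter = colnames(draws), rhat = NA_real_,
                    ess = NA_real_)
  for (j in seq_len(ncol(draws))) {
    m <- matrix(draws[, j], nrow = it, ncol = n_chains)
    out$rhat[j] <- rhat(m)
    out$ess[j] <- ess(m)
  }
  out
}
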