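# Independent oracles used across the suite. These deliberately avoid the
# package's own likelihood code paths: dense multivariate-normal algebra
# via Cholesky, and autocovariances from stats' ARMA recursions.

# log N(y | mu, Sigma) via Cholesky
mvn_loglik <- function(y, mu, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# stationary ARMA autocovariance matrix (T x T)
arma_autocov_matrix <- function(ar, ma, sigma, T_) {
  psi <- stats::ARMAtoMA(ar = ar, ma = ma, lag.max = 5000)
  gamma0 <- sigma^2 * (1 + sum(psi^2))
  acf <- c(1, unname(stats::ARMAacf(ar = ar, ma = ma, lag.max = T_)[-1]))
  gamma0 * matrix(acf[abs(outer(seq_len(T_), seq_len(T_), "-")) + 1], T_, T_)
}

# covariance of an AR(1) process started at eps(0) = 0:
# eps = L nu with L[i, j] = rho^(i - j), so Sigma = sigma^2 L L'
ar1_zero_start_cov <- function(rho, sigma, T_) {
  idx <- outer(seq_len(T_), seq_len(T_), "-")
  L <- ifelse(idx >= 0, rho^idx, 0)
  sigma^2 * tcrossprod(L)
}

# conditional ARMA(1,1) oracle: density of eps(3..T) given eps(1), eps(2)
# under nu(1) = nu(2) = 0. eps(t) = rho eps(t-1) + nu(t) + phi nu(t-1) for
# t >= 3; mean vector by propagating with nu = 0, covariance sigma^2 B B'
# with B the impulse-response matrix of nu(3..T) -> eps(3..T).
arma11_conditional_oracle <- function(eps, rho, phi, sigma) {
  T_ <- length(eps)
  n <- T_ - 2
  mean_vec <- numeric(n)
  prev <- eps[2]
  for (t in seq_len(n)) {
    prev <- rho * prev
    mean_vec[t] <- prev
  }
  B <- matrix(0, n, n)
  for (j in seq_len(n)) {
    # impulse in nu at time j+2: eps response at times j+2..T
    resp <- numeric(n)
    resp[j] <- 1
    if (j < n) {
      resp[j + 1] <- rho * resp[j] + phi
      if (j + 2 <= n) for (t in seq.int(j + 2, n)) resp[t] <- rho * resp[t - 1]
    }
    B[, j] <- resp
  }
  mvn_loglik(eps[3:T_], mean_vec, sigma^2 * tcrossprod(B))
}

logistic_closed_form <- function(times, r, kappa, x0) {
  kappa * x0 * exp(r * times) / (kappa + x0 * (exp(r * times) - 1))
}
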