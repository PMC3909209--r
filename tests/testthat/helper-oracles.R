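# Independent dense-matrix oracles for the state-space code, plus small
# fixture factories. Everything here is built directly from the model's
# joint Gaussian distribution, without touching the Kalman recursions.

# Regression design of the diffuse states: trend initial value propagates as
# phi^(t-1); the seasonal coefficients enter through the harmonic basis.
oracle_design <- function(n, phi) {
  B <- shelfcope:::harmonic_basis(seq_len(n), 6, 3)
  cbind(trend0 = phi^(0:(n - 1)), B)
}

# Covariance of the non-deterministic part: accumulated AR(1) trend
# innovations (entering from t = 2) plus white observation noise.
oracle_trend_cov <- function(n, phi, s2_eta) {
  V <- matrix(0, n, n)
  for (t in seq_len(n)) {
    for (s in seq_len(n)) {
      if (min(t, s) >= 2) {
        k <- 2:min(t, s)
        V[t, s] <- s2_eta * sum(phi^(t - k) * phi^(s - k))
      }
    }
  }
  V
}

# Diffuse (marginal) log-likelihood from the dense joint density:
# -((n-d)/2) log 2pi - 0.5 log|Sigma| - 0.5 log|X' Sigma^-1 X|
# - 0.5 r' Sigma^-1 r with r the GLS residual, on the observed subset.
oracle_loglik <- function(y, phi, s2_eta, s2_eps) {
  n <- length(y)
  X <- oracle_design(n, phi)
  Sig <- oracle_trend_cov(n, phi, s2_eta) + diag(s2_eps, n)
  obs <- which(!is.na(y))
  Xo <- X[obs, , drop = FALSE]
  So <- Sig[obs, obs, drop = FALSE]
  Si <- solve(So)
  XtSX <- t(Xo) %*% Si %*% Xo
  bh <- solve(XtSX, t(Xo) %*% Si %*% y[obs])
  r <- y[obs] - Xo %*% bh
  d <- ncol(X)
  as.numeric(
    -0.5 * ((length(obs) - d) * log(2 * pi)
            + determinant(So, logarithm = TRUE)$modulus
            + determinant(XtSX, logarithm = TRUE)$modulus
            + t(r) %*% Si %*% r))
}

# GLS projection of the trend path: E[mu | y] with the diffuse vector at its
# GLS estimate (the linear-Gaussian posterior mean under a flat prior).
oracle_smoothed_trend <- function(y, phi, s2_eta, s2_eps) {
  n <- length(y)
  X <- oracle_design(n, phi)
  V <- oracle_trend_cov(n, phi, s2_eta)
  Sig <- V + diag(s2_eps, n)
  obs <- which(!is.na(y))
  Xo <- X[obs, , drop = FALSE]
  Si <- solve(Sig[obs, obs, drop = FALSE])
  XtSX <- t(Xo) %*% Si %*% Xo
  bh <- solve(XtSX, t(Xo) %*% Si %*% y[obs])
  r <- y[obs] - Xo %*% bh
  as.numeric(phi^(0:(n - 1)) * bh[1] + V[, obs, drop = FALSE] %*% Si %*% r)
}

# Brute-force simple linear regression via the normal equations.
oracle_ols <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * syy)
  se <- sqrt((syy - slope * sxy) / (n - 2) / sxx)
  tstat <- slope / se
  list(n = n, slope = slope, intercept = intercept, r = r,
       p_value = 2 * pt(-abs(tstat), df = n - 2))
}

# Small, fast synthetic truth for pipeline-level tests.
small_truth <- function(seed = 1, ...) {
  synthetic_truth(seed = seed, years = c(1995L, 2004L),
                  velocity_years = c(1995L, 2004L),
                  stations_per_bin = 2L, gap_spec = list(), ...)
}
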