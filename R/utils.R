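#' Spectral radius of a square matrix
#'
#' @param m Square numeric matrix.
#' @return Largest eigenvalue modulus.
#' @export
spectral_radius <- function(m) {
  max(Mod(eigen(m, only.values = TRUE)$values))
}

# Stationary covariance of a VAR(1): solves vec(P) = (I - Phi (x) Phi)^-1 vec(Sigma)
stationary_cov <- function(phi, sigma) {
  d <- nrow(phi)
  if (spectral_radius(phi) >= 1) {
    stop("stationary covariance undefined: spectral radius >= 1")
  }
  p <- solve(diag(d * d) - kronecker(phi, phi), as.vector(sigma))
  m <- matrix(p, d, d)
  (m + t(m)) / 2
}

# one draw from MVN(mean, cov) using the current RNG state
rmvn1 <- function(mean, cov) {
  d <- length(mean)
  ch <- chol((cov + t(cov)) / 2)
  as.vector(mean + t(ch) %*% stats::rnorm(d))
}

quantile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), names = FALSE, type = 7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
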