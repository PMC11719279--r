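# Independent numerical oracles, written against the definitions rather
# than against the package's implementation paths.

# Mutual information of a standard bivariate normal by nested adaptive
# quadrature of the defining KL integral (domain truncated at +-9 sd;
# neglected mass < 1e-17).
quad_gaussian_mi <- function(rho, lim = 9) {
  integrand <- function(x, y) {
    den <- exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
    v <- den * log(den / (dnorm(x) * dnorm(y)))
    v[!is.finite(v)] <- 0
    v
  }
  outer_f <- function(xv) vapply(xv, function(x)
    integrate(function(y) integrand(x, y), -lim, lim,
              rel.tol = 1e-12, abs.tol = 1e-13, subdivisions = 400L)$value, 0)
  integrate(outer_f, -lim, lim, rel.tol = 1e-12, abs.tol = 1e-13,
            subdivisions = 400L)$value
}

# Eigen-decomposition route to the PCA quantities, independent of the SVD
# path used by the package.
eigen_oracle <- function(Z) {
  C <- tcrossprod(Z) / (ncol(Z) - 1)
  eigen(C, symmetric = TRUE)
}

# Row standardization written out longhand.
standardize_oracle <- function(G) {
  t(apply(G, 1, function(r) (r - mean(r)) / sd(r)))
}

# Student-t correction from the entropy difference 2*h1 - h2 of the
# univariate/bivariate t at rho = 0, using log-gamma directly.
lambda_entropy_oracle <- function(a) {
  h <- function(nu, p) {
    (p / 2) * log(nu * pi) + lgamma(nu / 2) - lgamma((nu + p) / 2) +
      ((nu + p) / 2) * (digamma((nu + p) / 2) - digamma(nu / 2))
  }
  2 * h(a, 1) - h(a, 2)
}
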