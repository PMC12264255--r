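# Independent oracles used across the suite. These re-derive quantities by a
# different route than the package code (term-by-term formula evaluation,
# brute-force simulation, direct log-density sums) so that agreement is
# evidence, not tautology.

# term-by-term evaluation of the observed-variable variance of an MI-PGM:
# lam^2 psi11 + lam^2 a^2 psi22 + lam^2 b^2 psi33
#   + 2 lam^2 a psi12 + 2 lam^2 a b psi23 + 2 lam^2 b psi13
#   + lam^2 zeta_t + eps_it,  a = min(t, knot), b = max(t - knot, 0)
oracle_indicator_variance <- function(t, knot, lam, Psi, zeta_t, eps_it) {
  a <- min(t, knot)
  b <- max(t - knot, 0)
  unname(
    lam^2 * Psi[1, 1] + lam^2 * a^2 * Psi[2, 2] + lam^2 * b^2 * Psi[3, 3] +
      2 * lam^2 * a * Psi[1, 2] + 2 * lam^2 * a * b * Psi[2, 3] +
      2 * lam^2 * b * Psi[1, 3] +
      lam^2 * zeta_t + eps_it)
}

# the trait (consistency) numerator of the same decomposition
oracle_trait_part <- function(t, knot, lam, Psi) {
  a <- min(t, knot)
  b <- max(t - knot, 0)
  unname(lam^2 * (Psi[1, 1] + a^2 * Psi[2, 2] + b^2 * Psi[3, 3] +
                    2 * a * Psi[1, 2] + 2 * a * b * Psi[2, 3] +
                    2 * b * Psi[1, 3]))
}

# multivariate normal log-likelihood by direct density summation
oracle_mvn_loglik <- function(y, mu, Sigma) {
  R <- chol(Sigma)
  p <- ncol(y)
  z <- forwardsolve(t(R), t(y) - mu)
  -0.5 * nrow(y) * (p * log(2 * pi) + 2 * sum(log(diag(R)))) -
    0.5 * sum(z^2)
}

# random PSD growth covariance with nonzero cross-terms
random_growth_cov <- function() {
  A <- matrix(stats::rnorm(9, sd = 0.5), 3, 3)
  crossprod(A) + diag(c(0.5, 0.1, 0.1))
}

# a small MI model with loadings/intercepts free of the tau-parallel
# special case, for exercising the general moment structure
general_mi_model <- function(Psi = random_growth_cov()) {
  d <- pgm_design(time_codes = 0:6, knot = 3)
  g <- growth_parameters(c(8, 1.5, -0.5), Psi)
  m <- measurement_parameters(
    n_indicators = 2, n_occasions = 7,
    loadings = matrix(c(1, 0.8), 2, 7),
    intercepts = matrix(c(0, 0.3), 2, 7),
    state_var = seq(0.2, 0.8, length.out = 7),
    error_var = matrix(rep(c(0.4, 0.6), 7), 2, 7))
  pgm_model(d, g, m)
}

# build a dataset whose sample mean and ML covariance EXACTLY equal given
# moments: whiten an arbitrary draw, then color it with chol(Sigma)
exact_moment_data <- function(n, mu, Sigma, seed = 1) {
  set.seed(seed)
  p <- length(mu)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Sz <- crossprod(Z) / n
  Z <- Z %*% solve(chol(Sz))
  Y <- Z %*% chol(Sigma) + matrix(mu, n, p, byrow = TRUE)
  colnames(Y) <- names(mu)
  Y
}
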