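#' Model-implied moments of a PGM
#'
#' Computes the mean vector and covariance matrix of the observed indicators
#' implied by an SI-PGM or MI-PGM. Observed variables are ordered
#' occasion-major with indicators varying fastest
#' (\code{y1_t1, y2_t1, ..., y1_t2, ...}).
#'
#' The mean of indicator (i, t) is the intercept plus the loading times the
#' basis-weighted growth means. The covariance of (i, t) with (i', t')
#' combines three orthogonal sources: the growth factors (through the
#' quadratic form of the basis rows in the growth covariance), the
#' occasion-specific state residual (shared by indicators of the same
#' occasion, absent across occasions), and the measurement error (on the
#' diagonal only). State residuals are mutually uncorrelated across
#' occasions and uncorrelated with the growth factors; errors are
#' uncorrelated with everything.
#'
#' @param model A [pgm_model()].
#' @return List with \code{mean} (named vector, length I*J) and \code{cov}
#'   (symmetric PSD matrix, I*J x I*J).
#' @examples
#' d <- pgm_design()
#' g <- growth_parameters(c(10, 2, 1), c(1, 0.25, 0.25))
#' m <- measurement_parameters(2, 7, state_var = 0.5, error_var = 0.4)
#' im <- implied_moments(pgm_model(d, g, m))
#' im$mean[1:4]
#' @export
implied_moments <- function(model) {
  stopifnot(inherits(model, "pgm_model"))
  I <- model$n_indicators
  J <- model$design$n_occasions
  B <- growth_basis(model$design)              # J x 3
  lam <- model$measurement$loadings            # I x J
  occ <- rep(seq_len(J), each = I)             # occasion of each variable
  lam_vec <- as.vector(lam)                    # column-major: i fastest
  Lambda <- lam_vec * B[occ, , drop = FALSE]   # (I*J) x 3 growth loadings
  mu <- as.vector(model$measurement$intercepts) +
    as.vector(Lambda %*% model$growth$means)
  Sigma <- Lambda %*% model$growth$cov %*% t(Lambda)
  # state residuals: within-occasion blocks lam_i lam_i' sigma2_zeta_t
  zeta <- model$measurement$state_var
  for (j in seq_len(J)) {
    idx <- which(occ == j)
    Sigma[idx, idx] <- Sigma[idx, idx] +
      zeta[j] * tcrossprod(lam_vec[idx])
  }
  diag(Sigma) <- diag(Sigma) + as.vector(model$measurement$error_var)
  Sigma <- (Sigma + t(Sigma)) / 2
  nms <- variable_names(I, J)
  names(mu) <- nms
  dimnames(Sigma) <- list(nms, nms)
  list(mean = mu, cov = Sigma)
}
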