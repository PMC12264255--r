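#' Normal-theory ML discrepancy between implied and sample moments
#'
#' The standard structural-equation maximum-likelihood fit function
#' \deqn{F = \log|\Sigma| + tr(S\Sigma^{-1}) - \log|S| - p +
#'       (m-\mu)'\Sigma^{-1}(m-\mu),}
#' where \eqn{(\mu, \Sigma)} are the model-implied mean and covariance,
#' \eqn{(m, S)} the sample mean and (ML, divisor n) covariance, and p the
#' number of observed variables. F is nonnegative and zero exactly at
#' saturation (\eqn{\Sigma = S}, \eqn{\mu = m}); minimizing F maximizes the
#' multivariate-normal likelihood, with \eqn{F = -2/n (\ell - \ell_{sat})}.
#'
#' @param implied_mean,implied_cov Model-implied mean vector and covariance.
#' @param sample_mean,sample_cov Sample mean vector and covariance (ML
#'   divisor-n form); \code{sample_cov} must be symmetric positive definite.
#' @return Nonnegative scalar discrepancy.
#' @examples
#' ml_discrepancy(0, matrix(1), 0, matrix(2))  # log(1/2) + 2 - 1
#' @export
ml_discrepancy <- function(implied_mean, implied_cov, sample_mean, sample_cov) {
  implied_cov <- as.matrix(implied_cov); sample_cov <- as.matrix(sample_cov)
  p <- length(implied_mean)
  stopifnot(length(sample_mean) == p, all(dim(implied_cov) == p),
            all(dim(sample_cov) == p))
  Rs <- tryCatch(chol(sample_cov), error = function(e)
    stop("sample covariance is not positive definite", call. = FALSE))
  R <- tryCatch(chol(implied_cov), error = function(e)
    stop("implied covariance is not positive definite", call. = FALSE))
  Sinv <- chol2inv(R)
  d <- as.numeric(sample_mean) - as.numeric(implied_mean)
  val <- 2 * sum(log(diag(R))) + sum(Sinv * sample_cov) -
    2 * sum(log(diag(Rs))) - p + drop(crossprod(d, Sinv %*% d))
  max(val, 0)
}

# ---- internal parameter packing ------------------------------------------
#
# Free parameters, in packing order:
#   growth means (3)                          identity scale
#   growth variances (3)                      log scale
#   growth covariances (3)                    identity scale, only if free
#   state-residual variances (J)              log scale, MI only
#   error variances (J)                       log scale
#     (SI: one per occasion; MI: shared within occasion under tau-parallel)
pgm_packing <- function(family, J, free_growth_cov) {
  k <- 0L
  idx <- list(means = k + 1:3); k <- k + 3L
  idx$logvar <- k + 1:3; k <- k + 3L
  if (free_growth_cov) { idx$cov <- k + 1:3; k <- k + 3L }
  if (family == "mi") { idx$logzeta <- k + seq_len(J); k <- k + J }
  idx$logeps <- k + seq_len(J); k <- k + J
  idx$n_free <- k
  idx
}

pgm_unpack <- function(theta, packing, family, J) {
  Psi <- diag(exp(theta[packing$logvar]))
  if (!is.null(packing$cov)) {
    cv <- theta[packing$cov]                      # (1,2), (1,3), (2,3)
    Psi[1, 2] <- Psi[2, 1] <- cv[1]
    Psi[1, 3] <- Psi[3, 1] <- cv[2]
    Psi[2, 3] <- Psi[3, 2] <- cv[3]
  }
  list(means = theta[packing$means],
       Psi = Psi,
       zeta = if (family == "mi") exp(theta[packing$logzeta]) else rep(0, J),
       eps = exp(theta[packing$logeps]))
}

# objective + analytic gradient of F_ML over the packed parameters.
# Lambda = basis rows replicated per indicator (unit loadings); `occ` maps
# observed variables to occasions. Returns list(value, gradient).
pgm_objective <- function(theta, packing, family, B, occ, m, S) {
  J <- nrow(B); I <- length(occ) / J; p <- length(occ)
  par <- pgm_unpack(theta, packing, family, J)
  Lambda <- B[occ, , drop = FALSE]
  Sigma <- Lambda %*% par$Psi %*% t(Lambda)
  if (family == "mi") {
    for (j in seq_len(J)) {
      idx <- which(occ == j)
      Sigma[idx, idx] <- Sigma[idx, idx] + par$zeta[j]
    }
  }
  diag(Sigma) <- diag(Sigma) + par$eps[occ]
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    # infeasible (possible only with free growth covariances): quadratic
    # pull-back toward zero covariances keeps the optimizer in-bounds
    g <- numeric(packing$n_free)
    pen <- 1e8
    if (!is.null(packing$cov)) {
      cv <- theta[packing$cov]
      pen <- pen * (1 + sum(cv^2))
      g[packing$cov] <- 2e8 * cv
    }
    return(list(value = pen, gradient = g))
  }
  Sinv <- chol2inv(R)
  d <- m - as.vector(Lambda %*% par$means)
  Sid <- Sinv %*% d
  val <- 2 * sum(log(diag(R))) + sum(Sinv * S) - p +
    drop(crossprod(d, Sid)) - attr(S, "logdet")
  # G = Sinv - Sinv (S + d d') Sinv, the derivative of F wrt Sigma
  G <- Sinv - Sinv %*% S %*% Sinv - tcrossprod(Sid)
  g <- numeric(packing$n_free)
  GL <- G %*% Lambda                               # p x 3
  LGL <- crossprod(Lambda, GL)                     # 3 x 3
  g[packing$means] <- -2 * crossprod(Lambda, Sid)
  g[packing$logvar] <- diag(LGL) * exp(theta[packing$logvar])
  if (!is.null(packing$cov))
    g[packing$cov] <- 2 * c(LGL[1, 2], LGL[1, 3], LGL[2, 3])
  dG <- diag(G)
  if (family == "mi") {
    zg <- vapply(seq_len(J), function(j) {
      idx <- which(occ == j); sum(G[idx, idx])
    }, numeric(1))
    g[packing$logzeta] <- zg * par$zeta
    eg <- vapply(seq_len(J), function(j) sum(dG[occ == j]), numeric(1))
  } else {
    eg <- dG
  }
  g[packing$logeps] <- eg * par$eps
  list(value = val, gradient = g)
}

# moment/OLS start values on the composite trajectory
pgm_start <- function(theta_len, packing, family, B, occ, data) {
  J <- nrow(B); I <- length(occ) / J
  ybar <- vapply(seq_len(J), function(j)
    rowMeans(data[, occ == j, drop = FALSE]), numeric(nrow(data)))
  H <- solve(crossprod(B), t(B))                   # 3 x J projector
  coefs <- ybar %*% t(H)                           # n x 3 per-subject OLS
  resid <- ybar - coefs %*% t(B)
  rvar <- mean(resid^2)
  theta <- numeric(theta_len)
  theta[packing$means] <- colMeans(coefs)
  theta[packing$logvar] <- log(pmax(0.5 * apply(coefs, 2, stats::var), 0.05))
  if (family == "mi") {
    # within-occasion indicator contrasts isolate error variance
    evar <- vapply(seq_len(J), function(j) {
      cols <- data[, occ == j, drop = FALSE]
      mean(apply(cols, 1, stats::var))
    }, numeric(1))
    theta[packing$logeps] <- log(pmax(evar, 0.05))
    theta[packing$logzeta] <- log(pmax(rvar - mean(evar) / I, 0.02))
  } else {
    theta[packing$logeps] <- log(pmax(apply(resid, 2, stats::var) + rvar / 2,
                                      0.05))
  }
  theta
}

#' Fit a piecewise growth model by maximum likelihood
#'
#' Fits an SI-PGM or tau-parallel MI-PGM to wide-format data by minimizing
#' the normal-theory discrepancy [ml_discrepancy()] between model-implied
#' and sample moments. Variances are optimized on the log scale so iterates
#' stay feasible without a constrained solver; growth means (and growth
#' covariances, when freed) are untransformed. Start values come from
#' per-subject least-squares trajectories; up to three jittered restarts are
#' attempted on non-convergence, after which the best point is returned with
#' \code{converged = FALSE} (never an error).
#'
#' @param data A \code{"pgm_data"} matrix (or numeric matrix with
#'   \code{"y{i}_t{j}"} columns). One indicator per occasion fits an SI-PGM;
#'   two or more fit an MI-PGM with unit loadings, zero intercepts, equal
#'   error variances within occasion, and free state-residual variances.
#' @param design A [pgm_design()] matching the data's occasion count.
#' @param family \code{"auto"} (from the data layout), \code{"si"}, or
#'   \code{"mi"}. Requesting \code{"si"} on multi-indicator data is an
#'   error; aggregate first with [aggregate_indicators()].
#' @param free_growth_cov Logical; free the three growth-factor covariances
#'   (default \code{FALSE}: fixed at zero).
#' @param control Optional list: \code{max_iter} (default 2000),
#'   \code{grad_tol} (gradient max-norm for the convergence flag, 1e-6),
#'   \code{rel_tol} (relative F tolerance, 1e-10), \code{restarts} (3).
#' @return Object of class \code{"pgm_fit"}: a list with \code{model} (the
#'   fitted [pgm_model()]), \code{discrepancy}, \code{loglik},
#'   \code{converged}, \code{n_iterations}, \code{gradient_norm},
#'   \code{n}, \code{family}, \code{sample_moments}.
#' @examples
#' gd <- generating_design(target_os = 0.25)
#' y <- simulate_pgm(gd, n = 300, seed = 7)
#' fit <- fit_pgm(y)
#' coef(fit)
#' @export
fit_pgm <- function(data, design = pgm_design(),
                    family = c("auto", "si", "mi"),
                    free_growth_cov = FALSE, control = list()) {
  family <- match.arg(family)
  data <- as.matrix(data)
  if (anyNA(data)) stop("complete data required", call. = FALSE)
  layout <- parse_layout(colnames(data))
  I <- layout$n_indicators; J <- layout$n_occasions
  if (J != design$n_occasions)
    stop("data have ", J, " occasions but the design has ",
         design$n_occasions, call. = FALSE)
  if (family == "auto") family <- if (I == 1L) "si" else "mi"
  if (family == "si" && I > 1L)
    stop("SI-PGM requires one indicator per occasion; aggregate first with ",
         "aggregate_indicators()", call. = FALSE)
  if (family == "mi" && I < 2L)
    stop("MI-PGM requires at least two indicators per occasion", call. = FALSE)
  ctrl <- utils::modifyList(
    list(max_iter = 2000L, grad_tol = 1e-6, rel_tol = 1e-10, restarts = 3L),
    control)

  n <- nrow(data); p <- I * J
  packing <- pgm_packing(family, J, free_growth_cov)
  if (n <= packing$n_free)
    stop("need more subjects (", n, ") than free parameters (",
         packing$n_free, ")", call. = FALSE)
  m <- colMeans(data)
  S <- stats::cov(data) * (n - 1) / n              # ML divisor-n covariance
  Rs <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is rank deficient", call. = FALSE))
  attr(S, "logdet") <- 2 * sum(log(diag(Rs)))
  occ <- rep(seq_len(J), each = I)
  B <- growth_basis(design)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!identical(cache$theta, theta))
      { cache$res <- pgm_objective(theta, packing, family, B, occ, m, S)
        cache$theta <- theta }
    cache$res
  }
  obj <- function(theta) evaluate(theta)$value
  grd <- function(theta) evaluate(theta)$gradient

  theta0 <- pgm_start(packing$n_free, packing, family, B, occ, data)
  best <- NULL
  for (try in 0:ctrl$restarts) {
    start <- if (try == 0) theta0 else
      theta0 + stats::rnorm(length(theta0), sd = 0.1 * try)
    opt <- stats::nlminb(start, obj, grd,
                         control = list(iter.max = ctrl$max_iter,
                                        eval.max = 4L * ctrl$max_iter,
                                        rel.tol = ctrl$rel_tol))
    gnorm <- max(abs(grd(opt$par)))
    ok <- opt$convergence == 0 || gnorm < ctrl$grad_tol ||
      gnorm < 1e-4 * max(1, abs(opt$objective))
    cand <- list(opt = opt, gnorm = gnorm, ok = ok)
    if (is.null(best) || opt$objective < best$opt$objective) best <- cand
    if (ok) { best <- cand; break }
  }
  opt <- best$opt
  par <- pgm_unpack(opt$par, packing, family, J)
  growth <- growth_parameters(par$means, par$Psi)
  meas <- measurement_parameters(
    n_indicators = I, n_occasions = J,
    state_var = if (family == "mi") par$zeta else 0,
    error_var = par$eps)
  model <- pgm_model(design, growth, meas)
  Fval <- max(opt$objective, 0)
  loglik_sat <- -n / 2 * (p * log(2 * pi) + attr(S, "logdet") + p)
  structure(
    list(model = model, discrepancy = Fval,
         loglik = loglik_sat - n * Fval / 2,
         converged = best$ok, n_iterations = opt$iterations,
         gradient_norm = best$gnorm, n = n, family = family,
         free_growth_cov = free_growth_cov,
         sample_moments = list(mean = m, cov = S)),
    class = "pgm_fit"
  )
}

#' @export
print.pgm_fit <- function(x, ...) {
  cat(toupper(x$family), "-PGM maximum-likelihood fit, n = ", x$n, "\n",
      sep = "")
  cat("  discrepancy F =", format(x$discrepancy, digits = 6),
      " logLik =", format(x$loglik, digits = 8), "\n")
  cat("  converged:", x$converged,
      " (", x$n_iterations, "iterations, max |grad| =",
      format(x$gradient_norm, digits = 3), ")\n")
  cat("growth means:\n")
  print(round(x$model$growth$means, 4))
  invisible(x)
}

#' @export
coef.pgm_fit <- function(object, ...) {
  g <- object$model$growth
  out <- c(g$means,
           var_level = unname(g$cov[1, 1]),
           var_change1 = unname(g$cov[2, 2]),
           var_change2 = unname(g$cov[3, 3]))
  names(out)[1:3] <- paste0("mean_", names(g$means))
  if (object$free_growth_cov)
    out <- c(out, cov_level_change1 = unname(g$cov[1, 2]),
             cov_level_change2 = unname(g$cov[1, 3]),
             cov_change1_change2 = unname(g$cov[2, 3]))
  out
}

#' @export
logLik.pgm_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "nobs") <- object$n
  attr(val, "df") <- pgm_packing(object$family,
                                 object$model$design$n_occasions,
                                 object$free_growth_cov)$n_free
  class(val) <- "logLik"
  val
}
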