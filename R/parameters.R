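#' Growth factor parameters
#'
#' Means and covariance matrix of the three growth factors of a
#' linear-linear PGM: the initial trait level, the first trait change
#' (pre-knot slope), and the second trait change (post-knot slope).
#'
#' @param means Numeric 3-vector of growth factor means.
#' @param cov 3 x 3 symmetric positive-semidefinite covariance matrix of the
#'   growth factors. A length-3 vector is taken as the diagonal of a
#'   covariance matrix with zero covariances.
#' @return Object of class \code{"growth_parameters"} with elements
#'   \code{means} and \code{cov}.
#' @examples
#' growth_parameters(means = c(10, 2, 1), cov = c(1, 0.25, 0.25))
#' @export
growth_parameters <- function(means, cov) {
  means <- as.numeric(means)
  if (length(means) != 3L || anyNA(means) || any(!is.finite(means)))
    stop("`means` must be a finite numeric 3-vector", call. = FALSE)
  if (is.vector(cov) && length(cov) == 3L) cov <- diag(as.numeric(cov))
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(3L, 3L)) || anyNA(cov) || any(!is.finite(cov)))
    stop("`cov` must be a finite 3 x 3 matrix (or length-3 diagonal)",
         call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("`cov` must be symmetric", call. = FALSE)
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop("`cov` must be positive semidefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  nm <- c("level", "change1", "change2")
  names(means) <- nm
  dimnames(cov) <- list(nm, nm)
  structure(list(means = means, cov = cov), class = "growth_parameters")
}

#' Measurement model parameters
#'
#' Loadings, intercepts, state-residual variances and measurement-error
#' variances of a PGM. For a single-indicator model (SI-PGM) the loading is
#' fixed at 1, the intercept at 0, and the state-residual variances at 0:
#' with one indicator per occasion, occasion-specific state variance cannot
#' be separated from measurement error. For a multiple-indicator model
#' (MI-PGM) under the tau-parallel constraint all loadings are 1 and all
#' intercepts are 0, and indicators within an occasion share one error
#' variance.
#'
#' @param n_indicators Number of indicators per occasion (1 for SI).
#' @param n_occasions Number of measurement occasions J.
#' @param loadings Indicators x occasions matrix of factor loadings; a
#'   scalar is recycled. Default 1 (tau-parallel).
#' @param intercepts Indicators x occasions matrix of intercepts; scalar
#'   recycled. Default 0.
#' @param state_var Length-J vector of state-residual variances (one per
#'   occasion, shared by indicators); scalar recycled. Must be 0 for SI.
#' @param error_var Indicators x occasions matrix of measurement-error
#'   variances; a length-J vector is recycled across indicators.
#' @return Object of class \code{"measurement_parameters"}.
#' @export
measurement_parameters <- function(n_indicators, n_occasions,
                                   loadings = 1, intercepts = 0,
                                   state_var = 0, error_var) {
  I <- as.integer(n_indicators); J <- as.integer(n_occasions)
  if (I < 1L) stop("`n_indicators` must be >= 1", call. = FALSE)
  if (J < 1L) stop("`n_occasions` must be >= 1", call. = FALSE)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- matrix(x, I, J)
    else if (is.vector(x) && length(x) == J)
      x <- matrix(rep(as.numeric(x), each = I), I, J)
    x <- as.matrix(x)
    if (!all(dim(x) == c(I, J)))
      stop("`", what, "` must be ", I, " x ", J, call. = FALSE)
    if (anyNA(x) || any(!is.finite(x)))
      stop("`", what, "` must be finite", call. = FALSE)
    dimnames(x) <- list(paste0("y", seq_len(I)), paste0("t", seq_len(J)))
    x
  }
  loadings <- expand(loadings, "loadings")
  intercepts <- expand(intercepts, "intercepts")
  error_var <- expand(error_var, "error_var")
  if (length(state_var) == 1L) state_var <- rep(state_var, J)
  state_var <- as.numeric(state_var)
  if (length(state_var) != J || anyNA(state_var) || any(!is.finite(state_var)))
    stop("`state_var` must be a finite length-", J, " vector", call. = FALSE)
  if (any(state_var < 0)) stop("state variances must be nonnegative", call. = FALSE)
  if (any(error_var < 0)) stop("error variances must be nonnegative", call. = FALSE)
  if (I == 1L) {
    if (any(loadings != 1) || any(intercepts != 0))
      stop("SI-PGM requires unit loadings and zero intercepts", call. = FALSE)
    if (any(state_var != 0))
      stop("state-residual variances are not identified with a single ",
           "indicator; set `state_var = 0` for SI-PGM", call. = FALSE)
  }
  names(state_var) <- paste0("t", seq_len(J))
  structure(
    list(n_indicators = I, n_occasions = J, loadings = loadings,
         intercepts = intercepts, state_var = state_var,
         error_var = error_var),
    class = "measurement_parameters"
  )
}

#' Piecewise growth model
#'
#' Couples a piecewise design, growth factor parameters and measurement
#' parameters into a fully specified SI-PGM (one indicator) or MI-PGM
#' (two or more indicators).
#'
#' @param design A [pgm_design()].
#' @param growth A [growth_parameters()].
#' @param measurement A [measurement_parameters()] whose occasion dimension
#'   matches the design.
#' @return Object of class \code{"pgm_model"}.
#' @examples
#' d <- pgm_design()
#' g <- growth_parameters(c(10, 2, 1), c(1, 0.25, 0.25))
#' m <- measurement_parameters(2, 7, state_var = 0.5, error_var = 0.4)
#' pgm_model(d, g, m)
#' @export
pgm_model <- function(design, growth, measurement) {
  stopifnot(inherits(design, "pgm_design"),
            inherits(growth, "growth_parameters"),
            inherits(measurement, "measurement_parameters"))
  if (measurement$n_occasions != design$n_occasions)
    stop("measurement block has ", measurement$n_occasions,
         " occasions but the design has ", design$n_occasions, call. = FALSE)
  structure(
    list(design = design, growth = growth, measurement = measurement,
         n_indicators = measurement$n_indicators),
    class = "pgm_model"
  )
}

#' @export
print.pgm_model <- function(x, ...) {
  fam <- if (x$n_indicators == 1L) "SI-PGM" else "MI-PGM"
  cat(fam, "with", x$n_indicators, "indicator(s) x",
      x$design$n_occasions, "occasions, knot at t =", x$design$knot, "\n")
  cat("growth means: ", paste(format(x$growth$means, digits = 4),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Observed-variable names of a model layout
#'
#' Column naming convention of wide-format PGM data: \code{"y{i}_t{j}"},
#' occasion-major (indicators vary fastest within an occasion).
#'
#' @param n_indicators Indicators per occasion.
#' @param n_occasions Number of occasions.
#' @return Character vector of length \code{n_indicators * n_occasions}.
#' @keywords internal
variable_names <- function(n_indicators, n_occasions) {
  as.vector(vapply(seq_len(n_occasions), function(j)
    paste0("y", seq_len(n_indicators), "_t", j),
    character(n_indicators)))
}
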