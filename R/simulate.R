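#' Simulate wide-format data from a PGM
#'
#' Draws complete wide-format longitudinal data from a fully specified
#' SI-PGM or MI-PGM. Each subject draws growth factors from a trivariate
#' normal with the model's growth means and covariance, one normal state
#' residual per occasion, and one normal measurement error per
#' indicator-occasion; observations are assembled through the loadings,
#' intercepts and growth basis. Sample moments converge to
#' [implied_moments()] as n grows.
#'
#' @param model A [pgm_model()] or [generating_design()].
#' @param n Number of subjects.
#' @param seed Integer seed; the draw is a pure function of
#'   \code{(model, n, seed)}.
#' @return An n x (I*J) numeric matrix of class \code{"pgm_data"} with
#'   columns \code{"y{i}_t{j}"} (occasion-major, indicator fastest) and
#'   attributes \code{n_indicators}, \code{n_occasions}, \code{seed}.
#' @examples
#' gd <- generating_design(target_os = 0.25)
#' y <- simulate_pgm(gd, n = 100, seed = 1)
#' dim(y)
#' @export
simulate_pgm <- function(model, n, seed) {
  if (inherits(model, "generating_design")) model <- model$model
  stopifnot(inherits(model, "pgm_model"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be positive", call. = FALSE)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single integer `seed` is required", call. = FALSE)
  I <- model$n_indicators
  J <- model$design$n_occasions
  B <- growth_basis(model$design)
  Psi <- model$growth$cov
  # factor scores via symmetric square root (PSD-safe, covariances allowed)
  es <- eigen(Psi, symmetric = TRUE)
  half <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  xi <- matrix(stats::rnorm(n * 3L), n, 3L) %*% half +
    matrix(model$growth$means, n, 3L, byrow = TRUE)        # n x 3
  trait <- xi %*% t(B)                                     # n x J
  zeta <- matrix(stats::rnorm(n * J), n, J) *
    matrix(sqrt(model$measurement$state_var), n, J, byrow = TRUE)
  state <- trait + zeta                                    # latent states
  occ <- rep(seq_len(J), each = I)
  lam <- as.vector(model$measurement$loadings)
  omega <- as.vector(model$measurement$intercepts)
  evar <- as.vector(model$measurement$error_var)
  y <- state[, occ, drop = FALSE] *
    matrix(lam, n, I * J, byrow = TRUE) +
    matrix(omega, n, I * J, byrow = TRUE) +
    matrix(stats::rnorm(n * I * J), n, I * J) *
    matrix(sqrt(evar), n, I * J, byrow = TRUE)
  colnames(y) <- variable_names(I, J)
  structure(y, n_indicators = I, n_occasions = J, seed = as.integer(seed),
            class = c("pgm_data", "matrix", "array"))
}

#' Aggregate indicators into a single composite per occasion
#'
#' Replaces the indicators of each occasion by their arithmetic mean,
#' producing the single-indicator dataset an SI-PGM is fitted to. Under
#' tau-parallel indicators the composite keeps the trait and state variance
#' of a single indicator while dividing the error variance by the number of
#' indicators, so its reliability is the Spearman-Brown step-up of the
#' per-indicator reliability (see [spearman_brown()]).
#'
#' @param data A \code{"pgm_data"} matrix (or any numeric matrix with
#'   \code{"y{i}_t{j}"} column names).
#' @return A \code{"pgm_data"} matrix with one column \code{"y1_t{j}"} per
#'   occasion. Single-indicator input is returned unchanged with a warning.
#' @export
aggregate_indicators <- function(data) {
  info <- parse_layout(colnames(data))
  I <- info$n_indicators; J <- info$n_occasions
  if (I < 2L) {
    warning("input already has a single indicator per occasion; returning ",
            "it unchanged", call. = FALSE)
    return(data)
  }
  occ <- rep(seq_len(J), each = I)
  out <- vapply(seq_len(J), function(j)
    rowMeans(data[, occ == j, drop = FALSE]), numeric(nrow(data)))
  out <- matrix(out, nrow = nrow(data), ncol = J,
                dimnames = list(NULL, variable_names(1L, J)))
  structure(out, n_indicators = 1L, n_occasions = J,
            seed = attr(data, "seed"),
            class = c("pgm_data", "matrix", "array"))
}

# infer (I, J) from "y{i}_t{j}" column names, validating the
# occasion-major/indicator-fastest order
parse_layout <- function(nms) {
  if (is.null(nms))
    stop("data must have \"y{i}_t{j}\" column names", call. = FALSE)
  m <- regmatches(nms, regexec("^y([0-9]+)_t([0-9]+)$", nms))
  bad <- which(lengths(m) != 3L)
  if (length(bad))
    stop("malformed column name(s): ", paste(nms[bad], collapse = ", "),
         " (expected \"y{i}_t{j}\")", call. = FALSE)
  ind <- vapply(m, function(x) as.integer(x[2]), integer(1))
  occ <- vapply(m, function(x) as.integer(x[3]), integer(1))
  I <- max(ind); J <- max(occ)
  expected <- variable_names(I, J)
  if (length(nms) != I * J || !identical(nms, expected))
    stop("columns must be exactly y1_t1 ... y", I, "_t", J,
         ", occasion-major with indicators varying fastest", call. = FALSE)
  list(n_indicators = I, n_occasions = J)
}
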