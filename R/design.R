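#' Piecewise measurement design
#'
#' Defines the time structure of a linear-linear piecewise growth model
#' (PGM): the time codes of the measurement occasions and the fixed knot at
#' which the growth rate changes. The design implies a three-column growth
#' basis (intercept, phase-1 slope, phase-2 slope) via the usual
#' min/max spline coding, which is continuous in time at the knot.
#'
#' @param time_codes Numeric vector of strictly increasing time scores, one
#'   per measurement occasion. The first occasion is conventionally coded 0.
#'   Default \code{0:6} (seven occasions).
#' @param knot Time score of the knot, strictly between the first and last
#'   time codes. Default \code{3} (the fourth occasion of the default grid).
#'
#' @details At least five occasions are required: a two-phase linear PGM is
#'   not identified with fewer. The knot is a known design quantity here, not
#'   an estimated parameter, and each side of the knot must contain at least
#'   two occasions so that both phase slopes are identified.
#'
#' @return An object of class \code{"pgm_design"}: a list with elements
#'   \code{time_codes}, \code{knot} and \code{n_occasions}.
#' @seealso [growth_basis()]
#' @examples
#' d <- pgm_design(time_codes = 0:6, knot = 3)
#' growth_basis(d)
#' @export
pgm_design <- function(time_codes = 0:6, knot = 3) {
  time_codes <- as.numeric(time_codes)
  knot <- as.numeric(knot)
  if (length(knot) != 1L || !is.finite(knot))
    stop("`knot` must be a single finite time score", call. = FALSE)
  if (anyNA(time_codes) || any(!is.finite(time_codes)))
    stop("`time_codes` must be finite", call. = FALSE)
  if (is.unsorted(time_codes, strictly = TRUE))
    stop("`time_codes` must be strictly increasing", call. = FALSE)
  J <- length(time_codes)
  if (J < 5L)
    stop("at least five measurement occasions are needed to identify a ",
         "two-phase piecewise growth model (got ", J, ")", call. = FALSE)
  if (knot <= min(time_codes) || knot >= max(time_codes))
    stop("`knot` must lie strictly inside the observed time range [",
         min(time_codes), ", ", max(time_codes), "]", call. = FALSE)
  if (sum(time_codes < knot) < 2L || sum(time_codes > knot) < 2L)
    stop("the knot must leave at least two occasions on each side for the ",
         "phase slopes to be identified", call. = FALSE)
  structure(
    list(time_codes = time_codes, knot = knot, n_occasions = J),
    class = "pgm_design"
  )
}

#' Growth basis of a piecewise design
#'
#' Builds the J x 3 growth loading matrix of a linear-linear PGM. Row j is
#' \code{c(1, min(t_j, knot), max(t_j - knot, 0))}: the loadings of occasion
#' j on the initial level, the first (pre-knot) change factor, and the
#' second (post-knot) change factor.
#'
#' @param design A [pgm_design()] object.
#' @return Numeric matrix with \code{design$n_occasions} rows and columns
#'   \code{"level"}, \code{"change1"}, \code{"change2"}.
#' @export
growth_basis <- function(design) {
  stopifnot(inherits(design, "pgm_design"))
  t <- design$time_codes
  b <- cbind(level = 1, change1 = pmin(t, design$knot),
             change2 = pmax(t - design$knot, 0))
  rownames(b) <- paste0("t", seq_along(t))
  b
}

#' @export
print.pgm_design <- function(x, ...) {
  cat("Piecewise growth design:", x$n_occasions, "occasions\n")
  cat("  time codes:", paste(x$time_codes, collapse = ", "), "\n")
  cat("  knot at t =", x$knot, "\n")
  invisible(x)
}
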