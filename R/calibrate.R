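#' Calibrate state and error variances to target coefficients
#'
#' Solves the variance decomposition of a tau-parallel MI-PGM for the
#' state-residual and error variances that make occasion specificity and
#' reliability hit given targets exactly at every occasion. With unit
#' loadings the trait-implied variance at occasion t is the quadratic form
#' \eqn{C_t = b_t' \Psi b_t} of the basis row in the growth covariance; the
#' total variance is then \eqn{V_t = C_t / (rel - os)} (the trait share is
#' consistency, which is reliability minus occasion specificity), the state
#' variance \eqn{os \cdot V_t}, and the error variance of every indicator
#' \eqn{(1 - rel) \cdot V_t}.
#'
#' @param growth A [growth_parameters()].
#' @param design A [pgm_design()].
#' @param target_os Target occasion specificity, in \code{[0, 1)}, constant
#'   over occasions.
#' @param target_rel Target per-indicator reliability, in \code{(0, 1]};
#'   must exceed \code{target_os}.
#' @return List with \code{state_var} (length-J vector), \code{error_var}
#'   (length-J vector, per indicator), \code{total_var} and \code{trait_var}
#'   (length-J vectors).
#' @examples
#' g <- growth_parameters(c(10, 2, 1), c(1, 0.25, 0.25))
#' calibrate_variances(g, pgm_design(), target_os = 0.4, target_rel = 0.8)
#' @export
calibrate_variances <- function(growth, design, target_os, target_rel) {
  stopifnot(inherits(growth, "growth_parameters"),
            inherits(design, "pgm_design"))
  if (!(target_os >= 0 && target_os < 1))
    stop("`target_os` must be in [0, 1)", call. = FALSE)
  if (!(target_rel > 0 && target_rel <= 1))
    stop("`target_rel` must be in (0, 1]", call. = FALSE)
  if (target_rel <= target_os)
    stop("infeasible cell: `target_rel` (", target_rel,
         ") must exceed `target_os` (", target_os,
         ") for consistency to be positive", call. = FALSE)
  B <- growth_basis(design)
  trait_var <- rowSums((B %*% growth$cov) * B)   # b_t' Psi b_t per occasion
  if (any(trait_var <= 0))
    stop("degenerate design: trait-implied variance is zero at occasion(s) ",
         paste(which(trait_var <= 0), collapse = ", "), call. = FALSE)
  total_var <- trait_var / (target_rel - target_os)
  list(state_var = target_os * total_var,
       error_var = (1 - target_rel) * total_var,
       total_var = total_var,
       trait_var = trait_var)
}

#' Generating design for calibrated MI-PGM data
#'
#' Bundles the population model of a simulation cell: a piecewise design,
#' growth parameters, the tau-parallel measurement structure whose state and
#' error variances are calibrated so every indicator has the requested
#' occasion specificity and reliability, and the resulting [pgm_model()].
#'
#' @param design A [pgm_design()]. Default: seven occasions coded 0..6 with
#'   the knot at the fourth occasion (t = 3).
#' @param growth A [growth_parameters()]. Default means (10, 2, 1) and
#'   variances (1, 0.25, 0.25) with zero covariances: a piecewise trajectory
#'   whose two phase slopes differ and whose trait variance is positive at
#'   every occasion.
#' @param n_indicators Indicators per occasion; default 2.
#' @param target_os Target occasion specificity; default 0.
#' @param target_rel Target per-indicator reliability; default 0.8.
#' @return Object of class \code{"generating_design"}: list with the inputs,
#'   the calibration, and \code{model}, the assembled population model.
#' @export
generating_design <- function(design = pgm_design(),
                              growth = growth_parameters(c(10, 2, 1),
                                                         c(1, 0.25, 0.25)),
                              n_indicators = 2,
                              target_os = 0,
                              target_rel = 0.8) {
  cal <- calibrate_variances(growth, design, target_os, target_rel)
  meas <- measurement_parameters(
    n_indicators = n_indicators, n_occasions = design$n_occasions,
    state_var = cal$state_var, error_var = cal$error_var)
  structure(
    list(design = design, growth = growth, n_indicators = n_indicators,
         target_os = target_os, target_rel = target_rel,
         calibration = cal,
         model = pgm_model(design, growth, meas)),
    class = "generating_design"
  )
}

#' @export
print.generating_design <- function(x, ...) {
  cat("Calibrated MI-PGM generating design\n")
  cat("  ", x$n_indicators, "indicators x", x$design$n_occasions,
      "occasions, knot at t =", x$design$knot, "\n")
  cat("  target occasion specificity:", x$target_os,
      " target reliability:", x$target_rel, "\n")
  invisible(x)
}
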