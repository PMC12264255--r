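#' Latent state-trait variance coefficients of a PGM
#'
#' Decomposes the model-implied variance of each observed indicator into
#' trait, state and error shares and reports the standard LST coefficients:
#'
#' \itemize{
#'   \item \emph{consistency} — the trait share: the quadratic form of the
#'     occasion's growth-basis row in the growth covariance (all covariance
#'     cross-terms included), scaled by the squared loading, over the total
#'     variance;
#'   \item \emph{occasion specificity} — the state share: the squared
#'     loading times the occasion's state-residual variance over the total
#'     variance;
#'   \item \emph{reliability} — consistency plus occasion specificity, the
#'     proportion of variance from all systematic sources.
#' }
#'
#' For an SI-PGM the state-residual variances are structurally zero, so the
#' occasion specificity is 0 and the only substantive coefficient is the
#' reliability, which then coincides with the consistency.
#'
#' @param object A [pgm_model()], [generating_design()], or [pgm_fit()];
#'   coefficients are always computed from model parameters (population or
#'   estimated), never from raw sample variances.
#' @return A data.frame of class \code{"lst_coefficients"} with columns
#'   \code{indicator}, \code{occasion}, \code{consistency},
#'   \code{occasion_specificity}, \code{reliability},
#'   \code{total_variance}; one row per indicator-occasion.
#' @examples
#' gd <- generating_design(target_os = 0.25, target_rel = 0.8)
#' lst_coefficients(gd)
#' @export
lst_coefficients <- function(object) {
  if (inherits(object, "pgm_fit")) object <- object$model
  if (inherits(object, "generating_design")) object <- object$model
  stopifnot(inherits(object, "pgm_model"))
  I <- object$n_indicators
  J <- object$design$n_occasions
  B <- growth_basis(object$design)
  trait_occ <- rowSums((B %*% object$growth$cov) * B)  # b_t' Psi b_t
  lam2 <- object$measurement$loadings^2                # I x J
  trait <- lam2 * matrix(trait_occ, I, J, byrow = TRUE)
  state <- lam2 * matrix(object$measurement$state_var, I, J, byrow = TRUE)
  total <- trait + state + object$measurement$error_var
  if (any(total <= 0))
    stop("total indicator variance is zero; coefficients undefined",
         call. = FALSE)
  out <- data.frame(
    indicator = rep(seq_len(I), times = J),
    occasion = rep(seq_len(J), each = I),
    consistency = as.vector(trait) / as.vector(total),
    occasion_specificity = as.vector(state) / as.vector(total),
    reliability = as.vector(trait + state) / as.vector(total),
    total_variance = as.vector(total)
  )
  class(out) <- c("lst_coefficients", "data.frame")
  out
}

#' Spearman-Brown step-up of composite reliability
#'
#' Reliability of the unweighted mean (or sum) of k parallel measurements,
#' each with reliability \code{rel}: \code{k * rel / (1 + (k - 1) * rel)}.
#'
#' @param rel Per-measurement reliability, strictly in (0, 1).
#' @param k Number of parallel measurements averaged; positive integer.
#' @return Composite reliability.
#' @examples
#' spearman_brown(0.8, 2)  # 0.889
#' @export
spearman_brown <- function(rel, k) {
  if (any(rel <= 0 | rel >= 1))
    stop("`rel` must be strictly between 0 and 1", call. = FALSE)
  if (any(k < 1) || any(k != round(k)))
    stop("`k` must be a positive integer", call. = FALSE)
  k * rel / (1 + (k - 1) * rel)
}
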