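#' Mean relative bias of a set of estimates
#'
#' The Monte Carlo bias metric: the mean of \code{(estimate - truth) /
#' truth} over replications. When the true value is zero the relative form
#' is undefined, so the mean raw difference is returned instead and the
#' result is flagged as an absolute-difference metric.
#'
#' @param estimates Numeric vector of replication estimates (non-empty,
#'   finite).
#' @param truth Single finite true value.
#' @return Numeric scalar with attributes \code{metric} ("relative" or
#'   "absolute") and \code{mc_se}, the Monte Carlo standard error of the
#'   reported mean.
#' @examples
#' relative_bias(c(0.42, 0.46), truth = 0.889)
#' @export
relative_bias <- function(estimates, truth) {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0L)
    stop("`estimates` must be non-empty", call. = FALSE)
  if (anyNA(estimates) || any(!is.finite(estimates)))
    stop("`estimates` must be finite", call. = FALSE)
  if (length(truth) != 1L || !is.finite(truth))
    stop("`truth` must be a single finite value", call. = FALSE)
  dev <- if (truth != 0) (estimates - truth) / truth else estimates - truth
  se <- if (length(dev) > 1L) stats::sd(dev) / sqrt(length(dev)) else NA_real_
  structure(mean(dev),
            metric = if (truth != 0) "relative" else "absolute",
            mc_se = se)
}
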