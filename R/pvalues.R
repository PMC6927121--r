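## Input validation shared by the estimators and the step-up machinery.

#' Validate a p-value vector
#'
#' Checks that `p` is a non-empty numeric vector of finite values in
#' \eqn{[0, 1]} and returns it stripped of attributes.  All estimators and
#' adjustment functions funnel their input through this check, so malformed
#' input fails early with the offending indices named.
#'
#' @param p numeric vector of p-values.
#' @return the validated numeric vector.
#' @keywords internal
as_pvalues <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) {
    stop("'p' must be a plain numeric vector of p-values", call. = FALSE)
  }
  p <- as.vector(p, mode = "numeric")
  if (length(p) < 1L) {
    stop("'p' must contain at least one p-value", call. = FALSE)
  }
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop(sprintf(
      "p-values must lie in [0, 1]; offending indices: %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  p
}

# clamp a scalar estimate into [lo, hi]
.clamp <- function(x, lo, hi) min(max(x, lo), hi)

# boundary tolerance for assigning p-values to gamma-grid bins: a value
# sitting exactly on k*gamma belongs to the lower interval's closure even
# when k*gamma is not exactly representable in binary
.BIN_EPS <- 1e-12
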