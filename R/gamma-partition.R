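#' Partition a p-value vector on the gamma grid
#'
#' Divides \eqn{(0, 1]} into intervals of length `gamma` and counts p-values
#' per interval.  This is the bookkeeping object behind the Unit Gamma
#' Measurement estimator: the count below `gamma` (`pre_gamma`) holds all
#' true signals plus the null mass of one unit-gamma length, while the
#' intervals above `gamma` hold (ideally) null p-values only, so their counts
#' estimate the null density per unit-gamma length.
#'
#' The number of post-gamma intervals is the largest `n` with
#' \eqn{(n+1)\gamma \le 1} (equivalently \eqn{(n+2)\gamma > 1}).  When
#' \eqn{(n+1)\gamma < 1} the leftover piece \eqn{((n+1)\gamma, 1]} is shorter
#' than `gamma` and is excluded from the interval counts, since a short
#' interval would bias the per-unit-length density.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @param gamma interval length, in \eqn{(0, 0.5)}.  Must exceed the
#'   significance level in force for the estimator to make sense.
#' @return an object of class `"gamma_partition"`: a list with elements
#'   \describe{
#'     \item{gamma, n, m}{the interval length, the number of post-gamma
#'       intervals, and the number of p-values.}
#'     \item{pre_gamma}{count of p-values \eqn{\le \gamma}.}
#'     \item{cumulative_counts}{counts of p-values \eqn{\le k\gamma} for
#'       `k = 1..n+1`.}
#'     \item{interval_counts}{counts in \eqn{(k\gamma, (k+1)\gamma]} for
#'       `k = 1..n`; a p-value exactly on a boundary belongs to the earlier
#'       bin.}
#'     \item{weights}{inverse-count weights
#'       \eqn{\tau_k = (1/D_k) / \sum_j (1/D_j)} over the post-gamma
#'       intervals; `NA` when some interval is empty.}
#'   }
#' @examples
#' gamma_partition(runif(100), gamma = 0.1)
#' @seealso [ugm_m0()] which turns the partition into an m0 estimate.
#' @export
gamma_partition <- function(p, gamma) {
  p <- as_pvalues(p)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0 || gamma >= 0.5) {
    stop("'gamma' must be a single number in (0, 0.5)", call. = FALSE)
  }
  m <- length(p)
  n <- as.integer(floor(1 / gamma + 1e-9)) - 1L
  breaks <- seq_len(n + 1L) * gamma
  cumulative <- vapply(breaks, function(b) sum(p <= b + .BIN_EPS), integer(1L))
  interval <- diff(cumulative)
  weights <- if (all(interval > 0L)) {
    inv <- 1 / interval
    inv / sum(inv)
  } else {
    rep(NA_real_, n)
  }
  structure(
    list(
      gamma = gamma, n = n, m = m,
      pre_gamma = cumulative[[1L]],
      cumulative_counts = cumulative,
      interval_counts = interval,
      weights = weights
    ),
    class = "gamma_partition"
  )
}

#' @export
print.gamma_partition <- function(x, ...) {
  cat(sprintf(
    "Gamma partition of %d p-values (gamma = %g, %d post-gamma intervals)\n",
    x$m, x$gamma, x$n
  ))
  cat(sprintf("  count in (0, %g]: %d\n", x$gamma, x$pre_gamma))
  tab <- data.frame(
    interval = sprintf("(%g, %g]", seq_len(x$n) * x$gamma,
                       (seq_len(x$n) + 1L) * x$gamma),
    count = x$interval_counts,
    weight = round(x$weights, 4)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}
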