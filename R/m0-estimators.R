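#' Estimate the number of true null hypotheses
#'
#' Fits an estimator of \eqn{m_0}, the number of true null hypotheses among
#' `m` tests, from the vector of per-test p-values.  Four estimators are
#' available:
#'
#' \describe{
#'   \item{`"ugm"`}{Unit Gamma Measurement.  The p-value axis is cut into
#'     intervals of length `gamma`.  All intervals above `gamma` should hold
#'     null p-values only, so each count \eqn{D_k} estimates the null mass
#'     per unit-gamma length.  The counts are combined with inverse-count
#'     weights \eqn{\tau_k = (1/D_k)/\sum_j(1/D_j)}, which makes the
#'     combined null density \eqn{\sum_k \tau_k D_k} the harmonic mean of
#'     \eqn{D_1, \dots, D_n}.  Subtracting it from the count below `gamma`
#'     gives \eqn{\hat m_1}, and \eqn{\hat m_0 = m - \hat m_1}.}
#'   \item{`"storey"`}{\eqn{\hat m_0 = (m - r(\lambda)) / (1 - \lambda)}
#'     where \eqn{r(\lambda)} counts p-values \eqn{\le \lambda}.}
#'   \item{`"abh"`}{the stepwise adaptive estimator: with sorted p-values,
#'     compute \eqn{s_k = (m + 1 - k)/(1 - p_{(k)})} and stop at the first
#'     \eqn{k \ge 2} with \eqn{s_k > s_{k-1}};
#'     \eqn{\hat m_0 = \min(m, \lceil s_k \rceil)}.}
#'   \item{`"tst"`}{two-stage estimate: a first-pass linear step-up at level
#'     \eqn{\alpha' = \alpha/(1+\alpha)} yields \eqn{r_1} rejections and
#'     \eqn{\hat m_0 = (m - r_1)/(1 + \alpha)}, the stage-one count deflated
#'     by the same factor by which the two-stage procedure relaxes its
#'     first-pass level.}
#' }
#'
#' Raw estimates are clamped to \eqn{[0, m]} (and \eqn{\hat\pi_0} to
#' \eqn{[0, 1]}); \eqn{\hat m_0} may be non-integer for UGM, Storey and TST.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @param method which estimator to fit.
#' @param gamma UGM interval length in \eqn{(0, 0.5)}; must exceed the
#'   significance level in force.  The default 0.1 keeps the post-gamma
#'   interval counts large enough that the harmonic mean is nearly unbiased
#'   while the window below `gamma` still captures essentially all signal;
#'   see the package vignette for the bias/variance trade-off.
#' @param lambda Storey threshold in \eqn{(0, 1)}; 0.5 is the usual choice.
#' @param alpha significance level used by the two-stage estimator.
#' @param mode UGM only.  `"interval"` (default) uses the disjoint interval
#'   counts \eqn{D_k}; `"literal"` applies the same inverse-count weighting
#'   to the cumulative counts \eqn{Lat_\gamma(k)} instead.  The literal form
#'   is retained for audit: because cumulative counts are non-decreasing
#'   from \eqn{Pre_\gamma}, it drives \eqn{\hat m_1 \le 0} and is clamped,
#'   so the interval reading is the one that carries information.
#' @return an object of class `"m0_fit"`: a list with elements `method`,
#'   `m`, `m0_hat`, `m1_hat` (`= m - m0_hat`), `pi0_hat` (`= m0_hat / m`),
#'   `params` (the tuning parameters used), and for UGM the
#'   [gamma_partition()] in `partition`.
#' @examples
#' set.seed(1)
#' p <- c(runif(900), rbeta(100, 0.5, 20))  # 900 nulls, 100 signals
#' estimate_m0(p, "ugm")
#' estimate_m0(p, "storey")
#' @seealso [ugm_m0()], [storey_m0()], [abh_m0()], [tst_m0()] for direct
#'   access to each estimator, and [adaptive_fdr()] which plugs the estimate
#'   into the adaptive linear step-up procedure.
#' @export
estimate_m0 <- function(p, method = c("ugm", "storey", "abh", "tst"),
                        gamma = 0.1, lambda = 0.5, alpha = 0.05,
                        mode = c("interval", "literal")) {
  method <- match.arg(method)
  switch(method,
    ugm    = ugm_m0(p, gamma = gamma, mode = mode),
    storey = storey_m0(p, lambda = lambda),
    abh    = abh_m0(p),
    tst    = tst_m0(p, alpha = alpha)
  )
}

# assemble an m0_fit object from a raw (unclamped) m0 estimate
.m0_fit <- function(method, m, m0_raw, params, partition = NULL) {
  m0 <- .clamp(m0_raw, 0, m)
  structure(
    list(
      method = method, m = m,
      m0_hat = m0, m1_hat = m - m0,
      pi0_hat = .clamp(m0 / m, 0, 1),
      params = params, partition = partition
    ),
    class = "m0_fit"
  )
}

#' Unit Gamma Measurement estimate of m0
#'
#' @inheritParams estimate_m0
#' @return an object of class `"m0_fit"`; see [estimate_m0()].
#' @examples
#' p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.15, 0.25, 0.3, 0.35, 0.39,
#'        0.45, 0.55, 0.65, 0.7, 0.72, 0.79, 0.85, 0.95)
#' ugm_m0(p, gamma = 0.2)  # m1_hat = 6 - 8/3, m0_hat = 18 - 10/3
#' @export
ugm_m0 <- function(p, gamma = 0.1, mode = c("interval", "literal")) {
  mode <- match.arg(mode)
  part <- gamma_partition(p, gamma)
  counts <- if (mode == "interval") {
    part$interval_counts
  } else {
    part$cumulative_counts[seq_len(part$n)]
  }
  # harmonic mean of the per-interval counts; the limit of the weighted sum
  # sum(tau_k * counts) as any count -> 0 is 0
  hmean <- if (any(counts == 0L)) 0 else part$n / sum(1 / counts)
  m1_raw <- .clamp(part$pre_gamma - hmean, 0, part$m)
  .m0_fit("ugm", part$m, part$m - m1_raw,
          params = list(gamma = gamma, mode = mode), partition = part)
}

#' Storey lambda estimate of m0
#'
#' @inheritParams estimate_m0
#' @return an object of class `"m0_fit"`; see [estimate_m0()].
#' @export
storey_m0 <- function(p, lambda = 0.5) {
  p <- as_pvalues(p)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0 || lambda >= 1) {
    stop("'lambda' must be a single number in (0, 1)", call. = FALSE)
  }
  m <- length(p)
  r <- sum(p <= lambda)
  .m0_fit("storey", m, (m - r) / (1 - lambda),
          params = list(lambda = lambda, r_lambda = r))
}

#' Adaptive Benjamini-Hochberg stepwise estimate of m0
#'
#' @inheritParams estimate_m0
#' @return an object of class `"m0_fit"`; see [estimate_m0()].
#' @export
abh_m0 <- function(p) {
  p <- as_pvalues(p)
  m <- length(p)
  ps <- sort(p)
  # (m + 1 - k) / (1 - p_(k)); p_(k) = 1 gives +Inf, which stops the scan
  s <- (m + 1 - seq_len(m)) / (1 - ps)
  k <- m
  if (m >= 2L) {
    for (i in 2:m) {
      if (s[i] > s[i - 1L]) { k <- i; break }
    }
  }
  .m0_fit("abh", m, min(m, ceiling(s[k])), params = list(k_stop = k))
}

#' Two-stage estimate of m0
#'
#' @inheritParams estimate_m0
#' @return an object of class `"m0_fit"`; see [estimate_m0()].
#' @export
tst_m0 <- function(p, alpha = 0.05) {
  p <- as_pvalues(p)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  }
  m <- length(p)
  alpha1 <- alpha / (1 + alpha)
  r1 <- step_up_reject(p, alpha = alpha1, m_eff = m)$k_hat
  .m0_fit("tst", m, (m - r1) / (1 + alpha),
          params = list(alpha = alpha, stage1_level = alpha1, r1 = r1))
}

#' @export
print.m0_fit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  label <- c(ugm = "Unit Gamma Measurement", storey = "Storey lambda",
             abh = "adaptive Benjamini-Hochberg", tst = "two-stage")[[x$method]]
  cat(sprintf("m0 estimate (%s)\n", label))
  pars <- x$params[!vapply(x$params, is.null, logical(1L))]
  cat(sprintf("  m = %d, %s\n", x$m,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  cat(sprintf("  m0_hat = %s, m1_hat = %s, pi0_hat = %s\n",
              format(x$m0_hat, digits = digits),
              format(x$m1_hat, digits = digits),
              format(x$pi0_hat, digits = digits)))
  invisible(x)
}

#' @export
coef.m0_fit <- function(object, ...) {
  c(m0_hat = object$m0_hat, m1_hat = object$m1_hat,
    pi0_hat = object$pi0_hat)
}

#' @export
summary.m0_fit <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$partition)) {
    cat("\n")
    print(object$partition)
  }
  invisible(object)
}

#' Plot method for m0 fits
#'
#' Draws the p-value histogram on the gamma grid (bin width `gamma` for UGM
#' fits, 0.05 otherwise) with a horizontal line at the fitted uniform null
#' level \eqn{\hat m_0 \times \mathrm{binwidth}}: the bars above the line in
#' the left-most bins are the estimated signal.
#'
#' @param x an object of class `"m0_fit"`.
#' @param p optional p-value vector; required when plotting a fit whose
#'   method does not retain a partition and you want a different bin width.
#' @param ... passed to [graphics::hist()].
#' @return invisibly, `x`.
#' @export
plot.m0_fit <- function(x, p = NULL, ...) {
  width <- if (!is.null(x$partition)) x$partition$gamma else 0.05
  if (is.null(p)) {
    stop("supply the p-value vector via 'p' to plot the histogram",
         call. = FALSE)
  }
  p <- as_pvalues(p)
  brk <- seq(0, 1 + width, by = width)
  brk <- brk[brk <= 1 + .BIN_EPS]
  if (max(brk) < 1) brk <- c(brk, 1)
  graphics::hist(p, breaks = brk, main = sprintf(
    "p-values with fitted null level (%s)", x$method
  ), xlab = "p-value", ...)
  # expected count per width-gamma bin under a uniform null of size m0_hat
  graphics::abline(h = x$m0_hat * width, col = 2, lty = 2)
  invisible(x)
}
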