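#' Linear step-up rejection rule
#'
#' Applies the step-up rule to a p-value vector: with sorted p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, \eqn{\hat k} is the largest `i` with
#' \eqn{p_{(i)} \le i \alpha / m_\mathrm{eff}}, and the \eqn{\hat k}
#' smallest p-values are rejected (none when no index qualifies).  With
#' `m_eff = length(p)` this is the classical Benjamini-Hochberg procedure;
#' substituting an estimate \eqn{\hat m_0 < m} widens the thresholds and
#' gives the adaptive version.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @param alpha target false discovery rate.
#' @param m_eff positive effective number of nulls in the thresholds; may be
#'   non-integer.
#' @return a list of class `"step_up"`: `k_hat` (number of rejections),
#'   `rejected` (logical, original order), `alpha`, `m_eff`, and
#'   `threshold`, the realised rejection cutoff
#'   \eqn{\hat k \alpha / m_\mathrm{eff}} (0 when nothing is rejected).
#' @examples
#' step_up_reject(c(0.001, 0.01, 0.02, 0.9), alpha = 0.05)$k_hat  # 3
#' @export
step_up_reject <- function(p, alpha = 0.05, m_eff = length(p)) {
  p <- as_pvalues(p)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m_eff) || length(m_eff) != 1L || !is.finite(m_eff) ||
      m_eff <= 0) {
    stop("'m_eff' must be a single positive number", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * alpha / m_eff)
  k_hat <- if (length(ok)) max(ok) else 0L
  rejected <- logical(m)
  if (k_hat > 0L) rejected[ord[seq_len(k_hat)]] <- TRUE
  structure(
    list(
      k_hat = as.integer(k_hat), rejected = rejected,
      alpha = alpha, m_eff = m_eff,
      threshold = if (k_hat > 0L) k_hat * alpha / m_eff else 0
    ),
    class = "step_up"
  )
}

#' @export
print.step_up <- function(x, ...) {
  cat(sprintf(
    "Step-up rule: alpha = %g, m_eff = %g -> %d of %d rejected (p <= %g)\n",
    x$alpha, x$m_eff, x$k_hat, length(x$rejected), x$threshold
  ))
  invisible(x)
}

#' Adjusted p-values for the adaptive step-up procedure
#'
#' Computes \eqn{\tilde p_{(i)} = \min_{i \le k \le m}
#' \min(\hat m_0 p_{(k)} / k,\ 1)} — the right-to-left running minimum over
#' sorted p-values — and maps the result back to the original order.  With
#' `m0_hat = length(p)` this is exactly the Benjamini-Hochberg adjustment;
#' smaller `m0_hat` scales every adjusted value down proportionally.
#' Rejecting `{adjusted <= alpha}` reproduces the [step_up_reject()] set
#' with `m_eff = m0_hat`.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @param m0_hat estimated number of true nulls, in \eqn{(0, m]}; used as a
#'   real multiplier without rounding.  Values below 1 are floored to 1
#'   (with a warning), otherwise all adjusted values would collapse to 0.
#' @return numeric vector of adjusted p-values in \eqn{[0, 1]}, original
#'   order.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.04, 0.5), m0_hat = 2)
#' @export
adjust_pvalues <- function(p, m0_hat = length(p)) {
  p <- as_pvalues(p)
  if (!is.numeric(m0_hat) || length(m0_hat) != 1L || !is.finite(m0_hat)) {
    stop("'m0_hat' must be a single finite number", call. = FALSE)
  }
  if (m0_hat < 1) {
    warning("'m0_hat' below 1 floored to 1 in the adjustment")
    m0_hat <- 1
  }
  m <- length(p)
  ord <- order(p)
  raw <- pmin(m0_hat * p[ord] / seq_len(m), 1)
  adj <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Confusion counts for a multiple-testing outcome
#'
#' Cross-tabulates rejection decisions against true null status: `U` nulls
#' retained, `V` nulls rejected (type I errors), `S` non-nulls rejected,
#' `T` non-nulls retained (type II errors), `R = V + S` rejections, and the
#' realised false discovery proportion `V / R` (0 when `R = 0`).
#'
#' @param rejected logical vector of rejection decisions.
#' @param true_null logical vector, `TRUE` where the null hypothesis holds.
#' @return a list of class `"confusion_counts"` with elements `U`, `V`,
#'   `S`, `T`, `R`, `m` and `realized_fdp`.
#' @examples
#' confusion_counts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE))
#' @export
confusion_counts <- function(rejected, true_null) {
  rejected <- as.logical(rejected)
  true_null <- as.logical(true_null)
  if (length(rejected) != length(true_null)) {
    stop("'rejected' and 'true_null' must have equal length", call. = FALSE)
  }
  if (anyNA(rejected) || anyNA(true_null)) {
    stop("'rejected' and 'true_null' must not contain NA", call. = FALSE)
  }
  V <- sum(rejected & true_null)
  S <- sum(rejected & !true_null)
  U <- sum(!rejected & true_null)
  T_ <- sum(!rejected & !true_null)
  R <- V + S
  structure(
    list(U = U, V = V, S = S, T = T_, R = R, m = length(rejected),
         realized_fdp = if (R > 0) V / R else 0),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("m = %d tests: U = %d, V = %d, S = %d, T = %d (R = %d)\n",
              x$m, x$U, x$V, x$S, x$T, x$R))
  cat(sprintf("realized FDP = %g\n", x$realized_fdp))
  invisible(x)
}

#' Adaptive linear step-up FDR procedure
#'
#' The full pipeline: estimate \eqn{\hat m_0} from the p-values with the
#' chosen estimator (see [estimate_m0()]), run the step-up rule with
#' \eqn{m_\mathrm{eff} = \hat m_0}, and attach the matching adjusted
#' p-values.  With an estimator that tracks \eqn{m_0} well this rejects
#' more than the classical Benjamini-Hochberg procedure while keeping the
#' false discovery rate near \eqn{\alpha \, m_0 / \hat m_0 \approx \alpha}.
#'
#' @inheritParams estimate_m0
#' @param alpha target false discovery rate (also passed to the two-stage
#'   estimator when `method = "tst"`).
#' @return an object of class `"adaptive_fdr"`: a list with the p-values
#'   (`p`), the `"m0_fit"` in `fit`, `alpha`, `k_hat`, logical `rejected`
#'   and numeric `adjusted_p` (both in input order).
#' @examples
#' set.seed(1)
#' p <- c(runif(900), rbeta(100, 0.5, 20))
#' fit <- adaptive_fdr(p, method = "ugm", alpha = 0.05)
#' fit
#' table(rejected = fit$rejected)
#' @export
adaptive_fdr <- function(p, method = c("ugm", "storey", "abh", "tst"),
                         alpha = 0.05, gamma = 0.1, lambda = 0.5,
                         mode = c("interval", "literal")) {
  p <- as_pvalues(p)
  fit <- estimate_m0(p, method = method, gamma = gamma, lambda = lambda,
                     alpha = alpha, mode = mode)
  m_eff <- max(fit$m0_hat, 1)  # same floor as the adjustment
  rej <- step_up_reject(p, alpha = alpha, m_eff = m_eff)
  structure(
    list(
      p = p, fit = fit, alpha = alpha,
      k_hat = rej$k_hat, rejected = rej$rejected,
      adjusted_p = adjust_pvalues(p, m0_hat = fit$m0_hat)
    ),
    class = "adaptive_fdr"
  )
}

#' @export
print.adaptive_fdr <- function(x, digits = max(3L, getOption("digits") - 3L),
                               ...) {
  cat("Adaptive linear step-up FDR procedure\n")
  print(x$fit, digits = digits)
  cat(sprintf("  alpha = %g: rejected %d of %d hypotheses\n",
              x$alpha, x$k_hat, x$fit$m))
  invisible(x)
}

#' @export
summary.adaptive_fdr <- function(object, n_show = 10L, ...) {
  print(object, ...)
  ord <- order(object$p)
  tab <- data.frame(
    index = ord,
    p_value = object$p[ord],
    adjusted_p = object$adjusted_p[ord],
    rejected = object$rejected[ord]
  )
  cat(sprintf("\nSmallest %d p-values:\n", min(n_show, nrow(tab))))
  print(utils::head(tab, n_show), row.names = FALSE)
  invisible(object)
}

#' @export
plot.adaptive_fdr <- function(x, ...) {
  plot(x$fit, p = x$p, ...)
  invisible(x)
}
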