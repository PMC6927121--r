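#' Configuration for a two-group expression simulation
#'
#' Describes the synthetic expression design used throughout the benchmark:
#' `m` genes over two groups of `n_per_group` samples.  The first
#' `m0 = round(m * pi0)` genes are true nulls: each draws a gene-specific
#' baseline \eqn{\mu \sim N(0, \mathrm{sd} = \sqrt{2})} shared by both
#' groups, and observations are \eqn{N(\mu, 1)}.  The remaining genes are
#' differentially expressed: their observations carry an
#' observation-level heterogeneity term on top of unit noise, so group-one
#' values are \eqn{N(0, \mathrm{var} = 2)} and group-two values
#' \eqn{N(\delta, \mathrm{var} = 2)} with mean shift `de_shift = 2`.  With
#' 40 samples per group this shift is detected with essentially complete
#' power, so the p-values above any reasonable `gamma` are null-driven —
#' the regime the m0 estimators are designed for.  See the package vignette
#' for why the heterogeneity is placed at observation level.
#'
#' @param m total number of genes.
#' @param pi0 true proportion of null genes, in \eqn{(0, 1]}.
#' @param n_per_group samples per group (at least 2; default 40).
#' @param null_mu_sd standard deviation of the shared null baseline.
#' @param de_shift group-two minus group-one mean for differentially
#'   expressed genes.
#' @param de_sd total standard deviation of a differentially expressed
#'   observation (unit noise plus unit-variance observation-level
#'   heterogeneity by default).
#' @param noise_sd residual standard deviation for null-gene observations.
#' @return a validated list of class `"sim_config"`, with `m0` and `m1`
#'   filled in.
#' @examples
#' sim_config(m = 3000, pi0 = 0.95)
#' @export
sim_config <- function(m, pi0, n_per_group = 40L,
                       null_mu_sd = sqrt(2), de_shift = 2,
                       de_sd = sqrt(2), noise_sd = 1) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != round(m)) {
    stop("'m' must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1) {
    stop("'pi0' must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 2 || n_per_group != round(n_per_group)) {
    stop("'n_per_group' must be a single integer >= 2", call. = FALSE)
  }
  m <- as.integer(m)
  m0 <- as.integer(round(m * pi0))
  structure(
    list(m = m, pi0 = pi0, m0 = m0, m1 = m - m0,
         n_per_group = as.integer(n_per_group),
         null_mu_sd = null_mu_sd, de_shift = de_shift,
         de_sd = de_sd, noise_sd = noise_sd),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation design: m = %d genes (m0 = %d null, m1 = %d shifted by %g), 2 x %d samples\n",
    x$m, x$m0, x$m1, x$de_shift, x$n_per_group
  ))
  invisible(x)
}

#' Simulate a two-group expression profile
#'
#' Draws one expression matrix from the design in a [sim_config()]: null
#' genes share a per-gene baseline across both groups, differentially
#' expressed genes differ by `de_shift` in the mean.  Rows are genes
#' (`gene_1 ... gene_m`, nulls first), columns samples
#' (`S1_1..S1_n, S2_1..S2_n`).
#'
#' @param config a [sim_config()] object.
#' @return a list of class `"sim_profiles"`: `values` (the
#'   `m` by `2 * n_per_group` matrix), `group_labels` (factor, `"S1"` /
#'   `"S2"`), `true_null` (logical per gene) and the `config`.
#' @examples
#' set.seed(1)
#' sim <- simulate_profiles(sim_config(m = 100, pi0 = 0.9, n_per_group = 5))
#' dim(sim$values)
#' @export
simulate_profiles <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config object", call. = FALSE)
  }
  m0 <- config$m0; m1 <- config$m1; n <- config$n_per_group
  mu <- rnorm(m0, 0, config$null_mu_sd)
  null1 <- matrix(rnorm(m0 * n, mean = mu, sd = config$noise_sd), m0, n)
  null2 <- matrix(rnorm(m0 * n, mean = mu, sd = config$noise_sd), m0, n)
  de1 <- matrix(rnorm(m1 * n, mean = 0, sd = config$de_sd), m1, n)
  de2 <- matrix(rnorm(m1 * n, mean = config$de_shift, sd = config$de_sd),
                m1, n)
  values <- cbind(rbind(null1, de1), rbind(null2, de2))
  dimnames(values) <- list(
    paste0("gene_", seq_len(config$m)),
    c(paste0("S1_", seq_len(n)), paste0("S2_", seq_len(n)))
  )
  structure(
    list(
      values = values,
      group_labels = factor(rep(c("S1", "S2"), each = n)),
      true_null = c(rep(TRUE, m0), rep(FALSE, m1)),
      config = config
    ),
    class = "sim_profiles"
  )
}

#' Summary statistics for replicate m0 estimates
#'
#' Collapses the replicate draws of an estimator into the benchmark
#' indicators: mean, sample standard deviation, range (max minus min),
#' quartile range (Q3 minus Q1, linear-interpolation quantiles,
#' [stats::quantile()] type 7), root-mean-square error about the true
#' `m0`, coefficient of variation (`sd / mean`), and the relative error of
#' the mean in percent.
#'
#' @param draws numeric vector of per-replicate m0 estimates (at least 2).
#' @param m0_true the true number of null hypotheses.
#' @param method optional method label carried into the output.
#' @return a one-row data frame with columns `method`, `n_reps`, `mean`,
#'   `sd`, `range`, `quartile_range`, `rmse`, `cv`, `relative_error_pct`.
#' @examples
#' summarize_draws(c(2840, 2850, 2860), m0_true = 2850)
#' @export
summarize_draws <- function(draws, m0_true, method = NA_character_) {
  draws <- as.numeric(draws)
  if (length(draws) < 2L || anyNA(draws)) {
    stop("'draws' must hold at least two non-missing estimates",
         call. = FALSE)
  }
  q <- stats::quantile(draws, c(0.25, 0.75), names = FALSE, type = 7)
  mu <- mean(draws)
  s <- stats::sd(draws)
  data.frame(
    method = method,
    n_reps = length(draws),
    mean = mu,
    sd = s,
    range = max(draws) - min(draws),
    quartile_range = q[2L] - q[1L],
    rmse = sqrt(mean((draws - m0_true)^2)),
    cv = s / mu,
    relative_error_pct = 100 * (mu - m0_true) / m0_true,
    stringsAsFactors = FALSE
  )
}

# deterministic per-replicate seed stream below 2^31, so replicate r of a
# run is reproducible in isolation and all methods share its data
.derive_seed <- function(seed, stream, rep) {
  as.integer((as.double(seed) %% 2147483629 * 48271 +
                stream * 9973 + rep) %% 2147483629)
}

#' Monte-Carlo benchmark of the m0 estimators
#'
#' Repeats the full pipeline `n_reps` times: simulate an expression profile
#' from `config`, compute per-gene two-sample t-test p-values, and apply
#' each requested estimator.  The replicate draws are then collapsed with
#' [summarize_draws()].  All estimators see the same data within a
#' replicate (paired comparison), and the whole run is reproducible from
#' `seed`: replicate `r` re-seeds deterministically from `(seed, r)`.
#'
#' @param config a [sim_config()] object.
#' @param n_reps number of replicates (at least 2).
#' @param methods character vector drawn from
#'   `c("ugm", "storey", "abh", "tst")`.
#' @param seed master integer seed.
#' @param gamma,lambda,alpha estimator tuning parameters, recorded in the
#'   result attributes.
#' @param variant t-test variant, `"pooled"` (default; the simulated groups
#'   share their variance) or `"satterthwaite"`.
#' @param keep_draws keep the per-replicate estimates as attribute
#'   `"draws"` (a `n_reps` by `length(methods)` matrix)?
#' @return a data frame of class `"m0_benchmark"` with one row per method
#'   (columns of [summarize_draws()]), with the design and parameters in
#'   attributes `config`, `params` and `seed`.
#' @examples
#' run_benchmark(sim_config(m = 200, pi0 = 0.9, n_per_group = 10),
#'               n_reps = 5, seed = 1)
#' @export
run_benchmark <- function(config, n_reps,
                          methods = c("ugm", "storey", "abh", "tst"),
                          seed = 1L, gamma = 0.1, lambda = 0.5,
                          alpha = 0.05, variant = "pooled",
                          keep_draws = FALSE) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config object", call. = FALSE)
  }
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 2) {
    stop("'n_reps' must be a single integer >= 2", call. = FALSE)
  }
  known <- c("ugm", "storey", "abh", "tst")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  n <- config$n_per_group
  g1 <- seq_len(n); g2 <- n + seq_len(n)
  draws <- matrix(NA_real_, n_reps, length(methods),
                  dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    set.seed(.derive_seed(seed, 0L, r))
    sim <- simulate_profiles(config)
    p <- .row_test_p(sim$values, g1, g2, variant)
    for (meth in methods) {
      draws[r, meth] <- estimate_m0(p, method = meth, gamma = gamma,
                                    lambda = lambda, alpha = alpha)$m0_hat
    }
  }
  out <- do.call(rbind, lapply(methods, function(meth) {
    summarize_draws(draws[, meth], m0_true = config$m0, method = meth)
  }))
  attr(out, "config") <- config
  attr(out, "params") <- list(gamma = gamma, lambda = lambda, alpha = alpha,
                              variant = variant)
  attr(out, "seed") <- as.integer(seed)
  if (keep_draws) attr(out, "draws") <- draws
  class(out) <- c("m0_benchmark", class(out))
  out
}

#' @export
print.m0_benchmark <- function(x, digits = 4L, ...) {
  cfg <- attr(x, "config")
  pars <- attr(x, "params")
  cat(sprintf(
    "m0 benchmark: m = %d, pi0 = %g (m0 = %d), %d replicates, seed %d\n",
    cfg$m, cfg$pi0, cfg$m0, x$n_reps[1L], attr(x, "seed")
  ))
  cat(sprintf("  gamma = %g, lambda = %g, alpha = %g, %s t-test\n",
              pars$gamma, pars$lambda, pars$alpha, pars$variant))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Benchmark the estimators over a grid of designs
#'
#' Runs [run_benchmark()] for every combination of `m_values` and
#' `pi0_values` and stacks the per-method summaries, adding the design
#' columns and the Monte-Carlo standard error of the replicate mean.
#' Per-configuration seeds are derived deterministically from `seed`, so a
#' fixed seed gives a byte-identical report.
#'
#' @param m_values integer vector of gene counts.
#' @param pi0_values numeric vector of true null proportions.
#' @param n_reps replicates per configuration.
#' @param methods,seed,gamma,lambda,alpha,variant as in [run_benchmark()].
#' @return a data frame with columns `m`, `pi0`, `m0`, the
#'   [summarize_draws()] columns and `mc_se = sd / sqrt(n_reps)`.
#' @examples
#' benchmark_grid(m_values = c(100, 200), pi0_values = 0.9, n_reps = 3,
#'                seed = 1, methods = "ugm")
#' @export
benchmark_grid <- function(m_values = c(1000L, 2000L, 3000L, 5000L, 8000L, 10000L),
                           pi0_values = c(0.8, 0.85, 0.9, 0.95),
                           n_reps = 200L,
                           methods = c("ugm", "storey", "abh", "tst"),
                           seed = 1L, gamma = 0.1, lambda = 0.5,
                           alpha = 0.05, variant = "pooled") {
  grid <- expand.grid(pi0 = pi0_values, m = m_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- sim_config(m = grid$m[i], pi0 = grid$pi0[i])
    res <- run_benchmark(cfg, n_reps = n_reps, methods = methods,
                         seed = .derive_seed(seed, i, 0L), gamma = gamma,
                         lambda = lambda, alpha = alpha, variant = variant)
    cbind(data.frame(m = cfg$m, pi0 = cfg$pi0, m0 = cfg$m0),
          as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  out$mc_se <- out$sd / sqrt(out$n_reps)
  rownames(out) <- NULL
  out
}
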