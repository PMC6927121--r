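# Brute-force oracle for the UGM estimator: element-wise bin assignment and
# the explicit inverse-count weight formula, sharing no code with the
# implementation's cumulative-count path.
brute_ugm_m0 <- function(p, gamma, eps = 1e-12) {
  m <- length(p)
  n <- 1L
  while ((n + 2L) * gamma <= 1 + eps) n <- n + 1L
  pre <- 0L
  D <- integer(n)
  for (x in p) {
    if (x <= gamma + eps) {
      pre <- pre + 1L
    } else {
      for (k in seq_len(n)) {
        if (x > k * gamma + eps && x <= (k + 1L) * gamma + eps) {
          D[k] <- D[k] + 1L
          break
        }
      }
    }
  }
  if (any(D == 0L)) {
    null_per_gamma <- 0
  } else {
    tau <- vapply(seq_len(n), function(i) 1 / (D[i] * sum(1 / D)), 0)
    null_per_gamma <- sum(tau * D)
  }
  m1 <- min(max(pre - null_per_gamma, 0), m)
  m - m1
}

# random p-value sets with a mix of null and signal mass
random_pvals <- function(m, signal_frac = 0.2) {
  n_sig <- rbinom(1L, m, signal_frac)
  p <- c(runif(m - n_sig), rbeta(n_sig, 0.3, 8))
  sample(p)
}
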