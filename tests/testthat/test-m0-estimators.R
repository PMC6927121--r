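toy18 <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.15, 0.25, 0.3, 0.35, 0.39,
           0.45, 0.55, 0.65, 0.7, 0.72, 0.79, 0.85, 0.95)

test_that("UGM worked examples under the interval reading", {
  # perfectly uniform p-values carry no signal
  fit <- ugm_m0((1:20 - 0.5) / 20, gamma = 0.05)
  expect_equal(fit$m0_hat, 20)
  expect_equal(fit$m1_hat, 0)
  # hand computation: harmonic mean of (4,2,4,2) = 8/3, m1 = 6 - 8/3
  fit <- ugm_m0(toy18, gamma = 0.2)
  expect_equal(fit$m1_hat, 10 / 3, tolerance = 1e-9)
  expect_equal(fit$m0_hat, 18 - 10 / 3, tolerance = 1e-9)
  expect_equal(fit$pi0_hat, (18 - 10 / 3) / 18, tolerance = 1e-9)
})

test_that("literal cumulative-count mode collapses m1 to its clamp", {
  # cumulative counts (6,10,14,16) give a harmonic mean ~9.99 > pre = 6,
  # so the literal form drives m1 below zero and the clamp leaves m0 = m
  fit <- ugm_m0(toy18, gamma = 0.2, mode = "literal")
  expect_equal(fit$m1_hat, 0)
  expect_equal(fit$m0_hat, 18)
})

test_that("UGM is exact on uniform grids for every gamma on the grid", {
  p <- (1:40 - 0.5) / 40
  for (gamma in c(0.05, 0.1, 0.2, 0.25)) {
    expect_equal(ugm_m0(p, gamma = gamma)$m0_hat, 40, tolerance = 1e-9)
  }
})

test_that("an empty post-gamma interval makes the estimate conservative", {
  p <- c(0.01, 0.02, 0.25, 0.28, 0.9)   # nothing in (0.1, 0.2]
  fit <- ugm_m0(p, gamma = 0.1)
  expect_equal(fit$m1_hat, 2)           # m1 = pre_gamma when any D(k) = 0
  expect_equal(fit$m0_hat, 3)
})

test_that("UGM matches the brute-force oracle on random small instances", {
  set.seed(2024)
  for (i in 1:1000) {
    p <- random_pvals(sample(5:30, 1))
    gamma <- sample(c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3), 1)
    expect_equal(ugm_m0(p, gamma = gamma)$m0_hat, brute_ugm_m0(p, gamma),
                 tolerance = 1e-9)
  }
})

test_that("Storey estimator counts, rescales and clamps", {
  p <- c(0.01, 0.02, 0.2, 0.4, 0.6, 0.8, 0.9, 0.95, 0.99, 1.0)
  fit <- storey_m0(p, lambda = 0.5)
  expect_equal(fit$params$r_lambda, 4)
  expect_equal(fit$m0_hat, 10)          # raw 12 clamped to m
  expect_equal(fit$pi0_hat, 1)
  expect_equal(storey_m0(runif(50, 0, 0.4), lambda = 0.5)$m0_hat, 0)
})

test_that("ABH stepwise rule stops at the first increase", {
  fit <- abh_m0(c(0.01, 0.02, 0.9))
  # s = (3.030, 2.041, 10.0): first increase at k = 3, ceil(10) clamped to m
  expect_equal(fit$params$k_stop, 3)
  expect_equal(fit$m0_hat, 3)
  expect_equal(abh_m0(rep(1, 7))$m0_hat, 7)   # no evidence at all
  expect_equal(abh_m0(rep(0, 7))$m0_hat, 1)   # all signal
})

test_that("two-stage estimate deflates the stage-one count", {
  p <- c(0.001, 0.002, 0.9, 0.95)
  fit <- tst_m0(p, alpha = 0.05)
  expect_equal(fit$params$stage1_level, 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(fit$params$r1, 2L)
  expect_equal(fit$m0_hat, 2 / 1.05, tolerance = 1e-9)
  expect_equal(tst_m0(rep(1, 6))$m0_hat, 6 / 1.05, tolerance = 1e-9)
})

test_that("all estimators respect the [0, m] contract on random inputs", {
  set.seed(5)
  for (i in 1:60) {
    p <- random_pvals(sample(3:80, 1), signal_frac = runif(1, 0, 0.9))
    m <- length(p)
    for (meth in c("ugm", "storey", "abh", "tst")) {
      fit <- estimate_m0(p, meth)
      expect_gte(fit$m0_hat, 0)
      expect_lte(fit$m0_hat, m)
      expect_equal(fit$m1_hat, m - fit$m0_hat)
      expect_equal(fit$pi0_hat, fit$m0_hat / m)
    }
  }
})

test_that("pure-null p-values give near-full m0 for every estimator", {
  set.seed(77)
  # m large enough that the clamp at m truncates only ~sqrt(m) worth of the
  # Storey estimate's upper tail, well inside the 2% band
  m <- 1000L
  draws <- replicate(500, {
    p <- runif(m)
    c(ugm = ugm_m0(p)$m0_hat, storey = storey_m0(p)$m0_hat,
      abh = abh_m0(p)$m0_hat, tst = tst_m0(p)$m0_hat)
  })
  for (meth in c("ugm", "storey", "abh")) {
    mu <- mean(draws[meth, ])
    se <- sd(draws[meth, ]) / sqrt(ncol(draws))
    expect_true(mu >= m - 3 * se || mu > 0.98 * m,
                label = sprintf("%s pure-null mean %.2f", meth, mu))
  }
  # the two-stage estimate sits a factor (1 + alpha) below the stage-one
  # count by construction, so its pure-null ceiling is m / 1.05
  expect_gt(mean(draws["tst", ]), 0.98 * m / 1.05)
})

test_that("appending clear signal never inflates UGM or Storey m0", {
  set.seed(31)
  for (i in 1:40) {
    p <- runif(sample(8:30, 1))
    k <- sample(1:5, 1)
    p2 <- c(p, rep(1e-9, k))
    # capped at the original m: the extra signal must never be credited to
    # the nulls (the clamp ceiling itself moves from m to m + k)
    expect_lte(min(ugm_m0(p2)$m0_hat, length(p)),
               ugm_m0(p)$m0_hat + 1e-9)
    expect_lte(min(storey_m0(p2)$m0_hat, length(p)),
               storey_m0(p)$m0_hat + 1e-9)
  }
})

test_that("tuning parameters are validated", {
  p <- runif(10)
  expect_error(ugm_m0(p, gamma = 0.7), "\\(0, 0.5\\)")
  expect_error(storey_m0(p, lambda = 1), "\\(0, 1\\)")
  expect_error(storey_m0(p, lambda = 0), "\\(0, 1\\)")
  expect_error(tst_m0(p, alpha = 1.2), "\\(0, 1\\)")
  expect_error(estimate_m0(p, "smoother"))
})
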