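test_that("simulated profiles have the configured shape and null count", {
  set.seed(1)
  sim <- simulate_profiles(sim_config(m = 3000, pi0 = 0.95))
  expect_equal(dim(sim$values), c(3000L, 80L))
  expect_equal(sum(sim$true_null), 2850L)
  expect_equal(levels(sim$group_labels), c("S1", "S2"))
  expect_equal(table(sim$group_labels)[["S1"]], 40L)
  # null genes share their baseline across groups: per-gene group means of
  # a null gene differ only by noise, DE genes by the configured shift
  tt <- row_t_tests(sim$values, sim$group_labels)
  expect_gt(mean(tt$p_value[!sim$true_null] < 0.05), 0.99)
})

test_that("differentially expressed genes are detected with high power", {
  set.seed(2)
  hits <- replicate(20, {
    sim <- simulate_profiles(sim_config(m = 100, pi0 = 0.8))
    p <- row_t_tests(sim$values, sim$group_labels)$p_value
    mean(p[!sim$true_null] < 0.05)
  })
  expect_gt(mean(hits), 0.9)
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(m = 1, pi0 = 0.5), ">= 2")
  expect_error(sim_config(m = 100, pi0 = 0), "\\(0, 1\\]")
  expect_error(sim_config(m = 100, pi0 = 1.1), "\\(0, 1\\]")
  expect_error(sim_config(m = 100, pi0 = 0.5, n_per_group = 1), ">= 2")
  expect_error(simulate_profiles(list(m = 10)), "sim_config")
})

test_that("replicate summaries match hand arithmetic", {
  s <- summarize_draws(c(1, 2, 3, 4), m0_true = 2)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 1.290994, tolerance = 1e-6)
  expect_equal(s$range, 3)
  expect_equal(s$quartile_range, 1.5)   # type-7 quartiles 1.75 and 3.25
  expect_equal(s$rmse, sqrt(1.5), tolerance = 1e-9)
  expect_equal(s$cv, 0.5163978, tolerance = 1e-6)
  expect_equal(s$relative_error_pct, 25)

  s <- summarize_draws(c(2840, 2850, 2860), m0_true = 2850)
  expect_equal(s$mean, 2850)
  expect_equal(s$sd, 10)
  expect_equal(s$range, 20)
  expect_equal(s$rmse, sqrt(200 / 3), tolerance = 1e-9)

  s <- summarize_draws(rep(2850, 5), m0_true = 2850)
  expect_equal(unlist(s[c("sd", "range", "rmse", "cv",
                          "relative_error_pct")]),
               c(sd = 0, range = 0, rmse = 0, cv = 0,
                 relative_error_pct = 0))
  expect_error(summarize_draws(5, 5), "at least two")
})

test_that("rmse decomposes into dispersion plus squared bias", {
  set.seed(3)
  for (i in 1:20) {
    d <- rnorm(sample(5:200, 1), mean = 100, sd = 10)
    s <- summarize_draws(d, m0_true = 95)
    n <- s$n_reps
    expect_equal(s$rmse^2,
                 s$sd^2 * (n - 1) / n + (s$mean - 95)^2, tolerance = 1e-9)
    expect_gte(s$rmse, abs(s$mean - 95) - 1e-12)
    expect_gte(s$range, s$quartile_range)
  }
})

test_that("a fixed seed makes the benchmark byte-identical", {
  cfg <- sim_config(m = 300, pi0 = 0.9, n_per_group = 10)
  b1 <- run_benchmark(cfg, n_reps = 5, seed = 11, keep_draws = TRUE)
  b2 <- run_benchmark(cfg, n_reps = 5, seed = 11, keep_draws = TRUE)
  expect_identical(b1, b2)
  b3 <- run_benchmark(cfg, n_reps = 5, seed = 12, keep_draws = TRUE)
  expect_false(identical(attr(b1, "draws"), attr(b3, "draws")))
  g1 <- benchmark_grid(m_values = 200, pi0_values = c(0.85, 0.95),
                       n_reps = 3, seed = 4, methods = "ugm")
  g2 <- benchmark_grid(m_values = 200, pi0_values = c(0.85, 0.95),
                       n_reps = 3, seed = 4, methods = "ugm")
  expect_identical(g1, g2)
})

test_that("benchmark validates its inputs", {
  cfg <- sim_config(m = 100, pi0 = 0.9, n_per_group = 5)
  expect_error(run_benchmark(cfg, n_reps = 1), ">= 2")
  expect_error(run_benchmark(cfg, n_reps = 5, methods = "qvalue"),
               "unknown method")
})

test_that("two-stage estimates sit well below the true m0", {
  set.seed(6)
  cfg <- sim_config(m = 1000, pi0 = 0.95)
  res <- run_benchmark(cfg, n_reps = 50, methods = "tst", seed = 13)
  expect_lt(res$mean, 0.97 * cfg$m0)
})
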