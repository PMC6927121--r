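# ugm — Unit Gamma Measurement estimation of the number of true nulls

Large-scale screens (microarray or RNA-Seq differential expression, or any
setting with thousands of simultaneous tests) control the false discovery
rate, FDR = E(V/R) with V/R the proportion of false rejections (0 when
R = 0).  The adaptive linear step-up (ALSU) procedure needs an estimate of
m0, the number of true null hypotheses among the m tests: it rejects the
k largest indices with p(i) ≤ i·α/m̂0 and reports adjusted p-values
p̃(i) = min over k ≥ i of min(m̂0·p(k)/k, 1).  The classical plug-ins for
m̂0 are nearly unbiased but can be very unstable from replicate to
replicate, which makes the whole procedure erratic.

This package implements the **Unit Gamma Measurement (UGM)** estimator,
built for stability.  Cut the p-value axis into intervals of length γ
(γ above the significance level), with n the largest integer such that
(n+1)γ ≤ 1 < (n+2)γ.  If the signal lies below γ, every interval above γ
holds null p-values only, so each count D_k estimates the null mass per
unit-γ length.  UGM combines them with inverse-count weights
τ_k = (1/D_k)/Σ_j(1/D_j) — making Σ τ_k D_k the harmonic mean of the
counts — and sets

    m̂1 = Pre_γ − hmean(D_1, …, D_n),   m̂0 = m − m̂1,

where Pre_γ counts p ≤ γ; both clamped to [0, m].  Also provided: the
Storey-λ, adaptive Benjamini–Hochberg (stepwise) and two-stage (TST)
comparator estimators, the ALSU rejection/adjustment machinery, vectorised
per-gene two-sample t-tests (pooled and Welch–Satterthwaite), and a
Monte-Carlo benchmark that measures each estimator's mean, SD, range,
quartile range, RMSE and CV over replicated two-group expression
simulations.

## Worked example

```r
library(ugm)
set.seed(1)
sim <- simulate_profiles(sim_config(m = 1000, pi0 = 0.9))   # 900 nulls
p   <- row_t_tests(sim$values, sim$group_labels)$p_value

estimate_m0(p, "ugm")
#> m0 estimate (Unit Gamma Measurement)
#>   m = 1000, gamma = 0.1, mode = interval
#>   m0_hat = 911.1, m1_hat = 88.85, pi0_hat = 0.9111

fit <- adaptive_fdr(p, method = "ugm", alpha = 0.05)
confusion_counts(fit$rejected, sim$true_null)
#> m = 1000 tests: U = 894, V = 6, S = 100, T = 0 (R = 106)
#> realized FDP = 0.0566038
```

The estimator reads 911.1 of the 1000 genes as null (truth: 900); the
adaptive procedure then rejects 106 genes at α = 0.05, among them all 100
truly shifted genes and 6 nulls — a realised false discovery proportion of
0.057, in line with the 0.05 target up to Monte-Carlo noise.

The benchmark compares estimators over replicates of the same design:

```r
run_benchmark(sim_config(m = 1000, pi0 = 0.9), n_reps = 20, seed = 1)
#>  method n_reps  mean     sd   range quartile_range   rmse       cv relative_error_pct
#>     ugm     20 899.8 13.399  44.053         16.514 13.062 0.014891           -0.02243
#>  storey     20 899.8 28.246 112.000         27.000 27.532 0.031392           -0.02222
#>     abh     20 901.6  1.603   6.000          1.250  2.236 0.001778            0.17778
#>     tst     20 852.7  2.234   7.619          3.095 47.336 0.002620           -5.25397
```

UGM and Storey-λ are both essentially unbiased here (relative error
−0.02%), but UGM's replicate SD is less than half of Storey's; the
two-stage estimate sits ≈ 5% low by construction (it deflates its
stage-one count by 1 + α).  See the vignette
(`vignettes/unit-gamma-m0.Rmd`) for the model, the γ bias/variance
trade-off, and the simulation design.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "ugm-cli.R", package = "ugm"))')" \
    estimate --pvalues pvals.txt --method all --gamma 0.1
```

Subcommands: `estimate`, `adjust`, `test` (expression matrix → p-values),
`simulate`, `benchmark`; all take `--out FILE`, `--sep`, `--seed` where
relevant and exit non-zero on validation errors.

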