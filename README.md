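# srbvs

Spike-and-slab Bayesian variable selection for time-to-event outcomes that
are observed through **error-prone self-reports**.

## The problem

In large prospective cohorts, silent diseases (type 2 diabetes is the
motivating example) are often ascertained by asking participants at
scheduled visits whether they have been diagnosed. These binary
self-reports are cheap but imperfect: a report after the true onset time
`X` is positive only with sensitivity φ₁, and a report before onset is
negative only with specificity φ₀. Treating the first positive report as
the event time biases analyses, and the bias propagates into variable
selection: with imperfect specificity, methods that assume error-free
outcomes lose much of their power to find truly associated covariates.

`srbvs` is for biostatisticians analysing interval-censored,
misclassified outcomes against high-dimensional covariates (SNP panels,
metabolomics), and for methodologists who want a reproducible simulation
bench for this setting.

## The model

With pooled ordered visit times `0 = τ₀ < τ₁ < … < τ_J < τ_{J+1} = ∞`,
baseline interval probabilities `θ_j = Pr(τ_{j−1} < X ≤ τ_j)` and a
proportional-hazards covariate model `S(x|z) = S₀(x)^{exp(z'β)}`, the
log-likelihood of the observed report sequences is

    l(θ, β) = Σ_i log Σ_{j=1}^{J+1} D_ij (S_{j−1}^{h_i} − S_j^{h_i}),
    h_i = exp(z_i'β),   S_j = Σ_{k>j} θ_k,

where `D_ij` is the probability of subject i's report sequence given
`X ∈ (τ_{j−1}, τ_j]`: visits before the interval contribute specificity
factors, visits at/after contribute sensitivity factors.

For `P ≫ n`, coefficients carry a spike-and-slab prior
`β_p | γ_p ~ γ_p N(0, b²) + (1−γ_p) δ₀`,
`γ_p | ω ~ Bernoulli(ω)`, `ω ~ Beta(w₁, w₂)`. A
Metropolis–Hastings-within-Gibbs sampler updates (γ, β, ω), profiling θ
out of the likelihood at every proposal, and covariates are ranked by
posterior inclusion probability. See the methods vignette
(`vignettes/srbvs-methods.Rmd`) for the complete account.

## Worked example

Simulate a cohort of 100 subjects, 100 Hardy–Weinberg SNPs, five true
effects (β = 1) and noisy self-reports (φ₁ = 1, φ₀ = 0.9) at visits in
years 2, 4, 6, 8; then run the error-aware sampler and look at the
ranking:

```r
library(srbvs)

design <- simulation_design(n = 100, P = 100, n_true = 5, beta_true = 1,
                            cir = 0.3, accuracy = test_accuracy(1, 0.9))
ds <- simulate_dataset(design, seed = 42)
ds$true_idx
#> [1] 22 30 44 64 73

chain <- run_chain(ds$panels, ds$Z, test_accuracy(1, 0.9),
                   bvs_hyperparameters(n_iter = 12000, burn_in = 2400),
                   seed = 7)
head(inclusion_probabilities(chain), 6)
#>   covariate index probability rank
#> 1     snp22    22   1.0000000    1
#> 2     snp30    30   1.0000000    2
#> 3     snp44    44   1.0000000    3
#> 4     snp73    73   0.9847917    4
#> 5     snp85    85   0.3217708    5
#> 6     snp64    64   0.3170833    6
```

Four of the five true SNPs (22, 30, 44, 73) are selected with posterior
inclusion probability near one; the fifth (64) ranks sixth, just behind a
null SNP — the top-5 metric for this replicate is 0.8. The same panels
analysed as if the reports were perfect must first be truncated at the
first positive (`apply_ntfp()`), which is what the `bvs_perfect` strategy
of the study driver does.

A low-dimensional check of a single covariate with WHI-like accuracy
(φ₁ = 0.61, φ₀ = 0.995) via maximum likelihood:

```r
acc <- test_accuracy(0.61, 0.995)
set.seed(1)
Z <- matrix(rnorm(2000), 2000, 1)
X <- simulate_event_times(Z, 1L, 1.0, baseline_hazard_from_cir(0.3, 8))
fit <- fit_ml(simulate_self_reports(X, c(2, 4, 6, 8), acc), Z, acc)
fit
#> Misclassification-aware interval-censored PH fit
#> log-likelihood: -2656.2362
#>   estimate      se     z   p_value
#> 1     1.06 0.05255 20.18 1.564e-90
```

The Wald interval 1.06 ± 1.96·0.053 covers the generating β = 1.

The replication-study driver compares analysis strategies on many
simulated datasets and reports the probability that a truly associated
covariate ranks in the top five (`run_replication_study()`); the
`exec/srbvs` script exposes `simulate`, `fit`, `bvs` and `study`
subcommands for shell use.

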