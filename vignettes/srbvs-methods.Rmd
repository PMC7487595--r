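---
title: "Variable selection with error-prone self-reported outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable selection with error-prone self-reported outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In large prospective cohorts, the onset of a silent disease such as type 2
diabetes is typically registered through periodic binary self-reports
rather than a gold-standard diagnostic. Self-reports are cheap but
error-prone: a report after the true onset is positive only with
sensitivity $\varphi_1$, and a report before onset is negative only with
specificity $\varphi_0$. The true event time $X$ is therefore never
observed; what is observed is a sequence of noisy binary readings at
scheduled visit times. Treating the first positive self-report as an exact
or interval-censored event time biases both estimation and — the focus of
this package — variable selection in high-dimensional covariate panels
(SNPs, metabolites).

`srbvs` implements a likelihood that models the report-error mechanism
directly, and embeds it in a spike-and-slab Bayesian variable selection
(BVS) sampler so that covariates can be ranked by posterior inclusion
probability while accounting for outcome misclassification.

## The likelihood

Pool the distinct visit times of all $N$ subjects and order them,
$0 = \tau_0 < \tau_1 < \dots < \tau_J < \tau_{J+1} = \infty$. These define
$J+1$ disjoint intervals $I_j$; let
$\theta_j = \Pr(\tau_{j-1} < X \le \tau_j)$ be the baseline interval
probabilities, $\sum_j \theta_j = 1$. Covariates act through a
proportional-hazards model, $S(x \mid z) = S_0(x)^{\exp(z'\beta)}$.

For subject $i$, let $D_{ij}$ be the probability of their observed report
sequence *given* $X \in I_j$: a visit strictly before $I_j$ contributes a
specificity factor ($\varphi_0$ for a negative, $1-\varphi_0$ for a
positive), and a visit at or after contributes a sensitivity factor
($\varphi_1$ for a positive, $1-\varphi_1$ for a negative). A visit falling
exactly at the event time counts as post-event, matching the half-open
intervals. The log-likelihood is

$$
l(\theta, \beta) \;=\; \sum_{i=1}^{N} \log
  \sum_{j=1}^{J+1} D_{ij}\,\bigl(S_{j-1}^{h_i} - S_j^{h_i}\bigr),
\qquad h_i = e^{z_i'\beta},\quad S_j = \sum_{k > j}\theta_k ,
$$

with $S_0 = 1$ and $S_{J+1} = 0$. Summation by parts gives the
algebraically identical "differenced" dialect
$\sum_j C_{ij}\, (\sum_{k \ge j}\theta_k)^{h_i}$ with
$C_{ij} = D_{ij} - D_{i,j-1}$; both are implemented and their agreement is
a standing property test. With a perfect test ($\varphi_1=\varphi_0=1$)
each $D$ row is the indicator of the censoring interval bracketed by the
last negative and first positive report, and the likelihood reduces to the
textbook grouped proportional-hazards interval-censoring likelihood.

A report sequence that is impossible under the assumed accuracy (a
negative after a positive with a perfect test) makes a subject's
contribution zero; the likelihood then evaluates to $-\infty$ and the
offending subject is flagged.

## Profiling the baseline interval probabilities

$\theta$ is a nuisance parameter of dimension $J$. At every coefficient
value the package maximizes $l$ over the open simplex ("profiling") via a
multinomial-logit reparameterization with the last interval as reference,
using a damped Newton ascent with analytic gradient and Hessian. Numerical
choices, fixed once:

* convergence when the log-likelihood improvement drops below `1e-8`
  (at most 200 iterations), with one restart from the uniform simplex
  point on failure;
* $\theta$ floored at $\varepsilon = 10^{-10}$ before powers and logs
  (survival tail sums are clamped to $[\varepsilon, 1]$), and the returned
  $\theta$ is floored and renormalized; the cached profile value is
  evaluated at exactly that floored point so cached and recomputed
  log-likelihoods agree bitwise;
* a trust-region cap on the Newton step and Levenberg-style ridging when
  the Hessian is not negative definite;
* warm starts: inside the sampler every profile call starts from the
  current state's $\theta$, which typically converges in 2–4 Newton steps
  and cuts runtime by roughly an order of magnitude. The profile result is
  deterministic given its inputs and warm start.

Low-dimensional maximum-likelihood fits (`fit_ml`, enforced $P \le 20$)
maximize jointly over $(\beta, \eta)$ with BFGS and analytic gradients;
standard errors come from the inverse of a central-difference Hessian at
the maximum, and per-coefficient Wald statistics follow. The $\beta$ block
of the inverse full-information matrix is invariant to the smooth
reparameterization of the nuisance $\theta$, so Wald inference can be done
on the logit scale.

## The spike-and-slab sampler

Coefficients carry the mixture prior
$\beta_p \mid \gamma_p \sim \gamma_p N(0, b^2) + (1-\gamma_p)\,\delta_0$
with inclusion indicators $\gamma_p \mid \omega \sim$ Bernoulli($\omega$)
and $\omega \sim$ Beta($w_1, w_2$); $\theta$ has a flat Dirichlet prior
but is *profiled*, not sampled (see below). Defaults $b = 1$, $w_1 = 5$,
$w_2 = 100$ (prior inclusion mass $\approx 4.8\%$), refine probability
$p_{\text{main}} = 0.30$, 100{,}000 iterations with 20{,}000 burn-in.

One iteration performs, in order:

1. **Flip move.** A covariate $p$ is chosen uniformly;
   $\gamma_p^* = 1-\gamma_p$. A covariate being switched on draws
   $\beta_p^* \sim N(0, b^2)$; one switched off is set exactly to zero.
   $\theta$ is re-profiled at $\beta^*$ and the proposal is accepted with
   probability $\min(e^\Delta, 1)$,
   $\Delta = l(\theta^*, \beta^*) - l(\theta, \beta) +
   (2\gamma_p^*-1)\log\frac{\omega}{1-\omega}$. The slab prior of the
   entering (or leaving) coefficient cancels exactly against its proposal
   density, which the test suite verifies against a brute-force
   log-target-ratio oracle rather than assuming.
2. **Refine moves.** Each currently included covariate is, independently
   with probability $p_{\text{main}}$, updated by a random walk
   $\beta_p^* \sim N(\beta_p, b^2)$ with its own re-profiling and
   accept/reject;
   $\Delta = l(\theta^*, \beta^*) - l(\theta, \beta) +
   \{\beta_p^2 - \beta_p^{*2}\}/(2b^2)$. Per-covariate (rather than
   blocked) acceptance is used because each $\Delta$ references a single
   coefficient.
3. **Conjugate update.** $\omega \sim$
   Beta($w_1 + K_\gamma,\, w_2 + P - K_\gamma$), $K_\gamma$ the number of
   included covariates.

Post-burn-in inclusion indicators are tallied into per-covariate posterior
inclusion probabilities; covariates are ranked by descending probability
with ties broken by ascending index (stable, so reruns agree).

**Profiling, not sampling, $\theta$.** The algorithm maximizes over
$\theta$ at every proposal, so the invariant target is an approximate
*profiled* posterior rather than the full joint posterior. This is a
deliberate design of the method itself; no correction is attempted, and
users should read inclusion probabilities as a ranking statistic rather
than calibrated posterior mass.

**Prior equilibrium.** When the likelihood carries no information about
$\gamma$ (e.g. all-zero covariates), the chain provably samples $\gamma$
from its Beta-Bernoulli prior, and the test suite checks the mean
inclusion probability against $w_1/(w_1+w_2)$. With real but pure-noise
covariates the equilibrium sits *below* the prior mass: entering the model
through a $N(0,b^2)$ slab draw that the data do not support carries an
Occam penalty. Tests assert the prior mass as an upper bound in that
regime.

**Determinism.** A chain is fully reproducible from its seed. The
iteration loop is implemented in compiled code that consumes R's RNG
stream in a fixed draw order, and an R-level reference loop composed of
the exported single-move functions reproduces it draw for draw; the suite
checks bit-identical agreement. Replicates of a study derive their seeds
by a documented splitting rule, so any replicate can be reproduced in
isolation and results do not depend on worker count.

## The synthetic-data generator

The generator emulates a two-arm simulation design for evaluating variable
selection with error-prone outcomes:

* $n = 100$ subjects, $P = 100$ covariates; five covariates drawn
  uniformly without replacement carry $\beta = 1$ (hazard ratio
  $e^{\beta} \approx 2.7$), the rest zero.
* SNP designs: per-column minor allele frequency drawn from a two-bin
  mixture (74% of columns Uniform(0.05, 0.35), 26% Uniform(0.35, 0.5)),
  genotypes under Hardy–Weinberg proportions coded additively 0/1/2, then
  standardized. Continuous ("metabolomics-like") designs use standardized
  Gaussians with optional exchangeable correlation.
* Event times are exponential with baseline hazard
  $\lambda_0 = -\log(1-\mathrm{CIR})/T$, calibrated so the
  covariate-reference group reaches cumulative incidence CIR (10% or 30%)
  by the study end $T = 8$ years; covariates act proportionally on the
  hazard.
* Four pre-scheduled visits shared by all subjects, placed at 2, 4, 6, 8
  years (equal spacing; the placement within the 8-year window is the
  package's choice).
* At each visit a Bernoulli self-report: positive with probability
  $\varphi_1$ if the visit is at or after $X$, else $1-\varphi_0$,
  independent across visits given $X$.
* Two designs: NMISS keeps all scheduled reports; NTFP discards
  everything after the first positive (at most one positive remains and
  it terminates the panel).

What the generator does **not** emulate: the original studies resampled a
fixed 100×100 submatrix of real GWAS genotypes (with linkage
disequilibrium) or real metabolomics correlation; the generator
substitutes independent Hardy–Weinberg columns (or exchangeable Gaussian
correlation with configurable $\rho$ but no claim of fidelity). Passing
tests therefore demonstrate the method's behavior under idealized,
independent designs; real-data covariate correlation can shift
variable-selection accuracy by a few points in either direction, and the
misspecified perfect-test comparator is the strategy most sensitive to it
(under independent designs it scores a few points higher than under a
correlated design, which also widens its gap to the error-aware NTFP
analysis). A user-supplied covariate CSV can close this gap through the
I/O layer.

## The replication study driver

`run_replication_study()` simulates datasets under a design, analyses each
with a configurable set of strategies, and scores the fraction of true
covariates ranked in the top $k$ (default 5) by inclusion probability:

* `bvs_e_nmiss` — all scheduled reports, analysis at the generating
  $(\varphi_1, \varphi_0)$;
* `bvs_e_ntfp` — reports truncated at the first positive, generating
  accuracies;
* `bvs_perfect` — truncated reports analysed as if self-reports were
  perfect ($\varphi_1=\varphi_0=1$); truncation is required because a
  negative after a positive has probability zero under a perfect test.

The top-$k$ metric and the count of null covariates in the top $k$ satisfy
the partition identity
$k = |{\rm truths\ in\ top\ }k| + |{\rm nulls\ in\ top\ }k|$ exactly.
Expected qualitative behavior, which the acceptance tests check at fixed
margins: with imperfect specificity and no truncation, the error-aware
analysis beats the perfect-test analysis by a wide margin (the perfect
model mistakes false positives for early events); after NTFP truncation
the two are comparable; and all strategies improve as the event rate
rises from CIR 10% to 30%.

External per-replicate rankings (e.g. from a random survival forest run
outside this package) can be ingested from CSV and scored with the same
metric; the driver does not implement tree ensembles itself.

## Problem sizes used by the tests and the acceptance script

The reference simulation design (1,000 replicates, 100,000-iteration
chains) costs days of CPU. The package's own test suite and acceptance
script run the identical design at reduced scale, chosen once as a
compute/precision trade-off and fixed: chains of 12,000 iterations with
2,400 burn-in; 100 replicates for the diagnostic setting (CIR 0.1,
$\varphi_1 = 1, \varphi_0 = 0.9$) whose cells are compared against the
reference values, 60 for the perfect-report baseline, and 40 for the
CIR 0.3 settings that feed direction-of-effect checks; the standalone
acceptance script reports the same cells at 60 replicates for the CIR 0.1
settings and 30 for the CIR 0.3 settings to stay well inside a
quarter-hour of CPU. At
these sizes the per-cell Monte-Carlo standard error of the top-5 metric is
roughly 0.02–0.04. Pilot comparisons at 8,000, 16,000 and 30,000
iterations showed no detectable chain-length effect on the metric at these
chain lengths; replicate-to-replicate variation dominates.

Other fixed test scales: the maximum-likelihood recovery experiment uses
$n = 2000$, one covariate, 100 replicates; conjugate-update moment checks
use $10^5$ draws; simulator calibration checks use $10^5$ subjects.

## Known limitations

* $\varphi_1, \varphi_0$ are treated as known constants; no uncertainty in
  the accuracy parameters is propagated.
* Time-varying covariates, missed-visit processes, informative visit
  schedules and competing risks are out of scope.
* The profiled posterior is an approximation (see above); formal MCMC
  run-length diagnostics are limited to the optional trace export.
* The visit grid is shared across subjects in the generator; the
  likelihood itself supports arbitrary per-subject visit subsets of the
  pooled grid.
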