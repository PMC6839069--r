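---
title: "A random-effects model for the clonal relatedness of tumor pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A random-effects model for the clonal relatedness of tumor pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalmix)
library(dplyr)
```

## The scientific problem

When a patient presents with two distinct tumors — for example cancers
in both breasts — the pair may be two independent primary cancers, or
one tumor may be a metastasis of the other (the tumors are *clonally
related*). The distinction changes prognosis and treatment, but it is
not observable directly. What is observable, after panel sequencing of
both tumors, is the set of somatic mutations in each: a mutation present
in both tumors (a *match*, or shared mutation) is evidence for clonal
relatedness, and a mutation private to one tumor is mild evidence
against it. Crucially, how much a match proves depends on how common
the mutation is: two independent breast cancers can easily both acquire
a hotspot mutation that occurs in ~14% of breast cancers, whereas a
coincident match at a locus mutated in fewer than 1 in 1000 tumors is
very unlikely unless the tumors share an origin.

`clonalmix` implements a random-effects model that analyzes **all cases
of a study jointly**: it estimates the population proportion of clonal
cases, `pi`, together with the distribution of the *clonality signal*,
and returns a posterior probability of clonality for every case.

## The model

For case $j$, let $G_j$ be the set of loci mutated in at least one
tumor of the pair, partitioned into shared loci $A_j$ and private loci
$B_j$. Each locus $i$ has a known occurrence probability $p_i \in
(0,1)$. The latent clonality indicator is $C_j$, and the clonality
signal $\xi_j \in [0,1)$ is the anticipated fraction of observed
mutations that are matches — it reflects how much of the tumors'
evolution was shared ($\xi_j = 0$ when $C_j = 0$).

Conditional on $(\xi_j, C_j = 1)$, each observed locus is shared with
probability
$$\frac{\xi_j + (1-\xi_j)\,p_i}{\xi_j + (1-\xi_j)(2-p_i)}$$
and private with the complementary probability
$2(1-\xi_j)(1-p_i) / \{\xi_j + (1-\xi_j)(2-p_i)\}$; under independence
($C_j=0$) these reduce to $p_i/(2-p_i)$ and $2(1-p_i)/(2-p_i)$ — the
same formulas at $\xi_j = 0$. For fixed $\xi_j$ the likelihood ratio of
a match (clonal vs independent) is strictly decreasing in $p_i$: rarer
matches are stronger evidence. These per-locus terms multiply over
$G_j$; a case with no observed mutations contributes a factor of one.

Population structure: $C_j \sim \text{Bernoulli}(\pi)$ and, for clonal
cases, $-\log(1-\xi_j)$ is lognormal with parameters $\mu$ and
$\sigma$ — equivalently $u_j = \log(-\log(1-\xi_j)) \sim N(\mu,
\sigma)$. We read $\mu$ and $\sigma$ as the mean and standard
deviation of the underlying normal (of $u$); this is the reading under
which the reference shape $\mu = 0.7$, $\sigma = 0.3$ concentrates
$\xi$ near $1-\exp(-e^{0.7}) \approx 0.87$, i.e. describes clonal
cases whose mutations are mostly matched, which is how that scenario
is meant to behave. The signal density is never interpreted with
natural-scale moments.

The observed-data likelihood marginalizes both latent variables:
$$L(\pi,\mu,\sigma) \;=\; \prod_{j=1}^{n} \Big\{ \pi
\int_0^1 P(Y_j \mid \xi, C_j{=}1)\, g(\xi)\, d\xi \;+\;
(1-\pi)\, P(Y_j \mid C_j{=}0) \Big\}.$$

## Two estimators

**One-step constrained maximization** (`fit_onestep()`) maximizes
$\log L$ directly with a box-constrained quasi-Newton algorithm
(`optim(method = "L-BFGS-B")`) over $\pi \in [0,1]$, $\mu \in
[-10,10]$, $\sigma \in [0.05,10]$. Because $\pi$ is a free coordinate
of the optimizer, the estimate can land exactly on 0 or 1. A boundary
estimate is pathological for interpretation: it forces the posterior
clonality probability of *every* case to 0 or 1, even for a case with
a rare match.

**EM** (`fit_em()`) treats $(C_j, \xi_j)$ as missing data. The E-step
computes, per case, the posterior weight
$w_j = \pi M_j / \{\pi M_j + (1-\pi) I_j\}$ and the posterior first
and second moments of $u_j$ given $C_j = 1$; the M-step has closed
forms: $\hat\pi$ is the mean of the $w_j$, and $\hat\mu,
\hat\sigma^2$ are the $w$-weighted mean and variance of the posterior
$u$ moments. Because $\hat\pi$ is an average of probabilities it
reaches 0 or 1 only if every single posterior does — this is the
mechanism by which EM avoids spurious boundary estimates, and we never
clip $\pi$ so as not to mask it. `posterior_clonality()` returns the
per-case $w_j$ at any parameter values.

Both estimators target the same likelihood; on well-identified data
they agree closely (the package tests assert agreement within 0.02 on
simulated data from the saturated-signal scenario). Where they differ
in practice is near degenerate regions of the surface, discussed below.

## Numerical choices

* **Quadrature.** The signal integral has no closed form. We use
  adaptive Gauss–Hermite quadrature on the $u$ scale, where the signal
  is exactly normal and the integrand is smooth: for each case the
  $K = 64$ nodes (the default) are centred at the mode of that case's integrand
  (located by a vectorized golden-section search) and scaled by its
  curvature, the standard construction for mixed-model marginal
  likelihoods. Placement matters here because $k$ shared loci tilt the
  integrand by roughly $e^{k u}$ in the small-signal regime, which
  pushes its mass far from the prior mean when $\sigma$ is large;
  prior-centred nodes lose several digits exactly in those cases. The
  suite checks agreement with adaptive numerical integration
  (`stats::integrate`, no fixed grid) to $10^{-6}$ over randomized
  cases and parameters, and that refining $K = 64 \to 256$ changes no
  fixture case log-likelihood by more than $10^{-8}$. The exported
  `signal_grid()` (prior-located nodes, weights normalized to one)
  serves expectations under the signal law itself.
* **Log-space accumulation.** All per-locus terms are accumulated as
  logs with `log1p`/`expm1` forms, and mixtures use log-sum-exp, so a
  case with a hundred loci at $p = 10^{-6}$ does not underflow.
* **Convergence.** EM stops when the observed-data log-likelihood
  changes by less than `tol` ($10^{-6}$) between iterations, up to
  `max_iter` = 1000; the per-iteration
  log-likelihood trace is retained and is nondecreasing (a property
  the tests assert with $10^{-10}$ slack).
* **Bounds and floors.** $\sigma$ is floored at `sigma_min` = 0.05 in
  the M-step and bounded in the one-step box; this prevents an exact
  point-mass signal distribution when few cases carry posterior
  weight. $p_i = 0$ or $1$ are rejected at validation, not clamped:
  they make the per-locus terms degenerate and almost always indicate
  a data error.
* **Initialization.** Default start $(\pi_0, \mu_0, \sigma_0) = (0.5,
  -1, 1)$, the intermediate signal shape. Mixture likelihoods can be
  multimodal, so `fit_clonality()` defaults to a five-point multistart
  on $\pi_0 \in \{0.1, \dots, 0.9\}$ with best-log-likelihood
  selection; it is cheap at this scale.
* **Degenerate inputs.** A dataset whose cases all have zero observed
  loci has a likelihood flat in all parameters; the fitters return the
  starting values unchanged, flag convergence, and warn. An M-step
  with all $w_j = 0$ sets $\pi = 0$ and keeps the current $\mu,
  \sigma$ (logged, not an error). Boundary fits report posteriors at
  the snapped value of $\pi$ so the forced constants are exact.

## The worked example and a known degeneracy

The packaged dataset (`contralateral_breast_cases()`) transcribes the
49-case contralateral breast cancer study: per-tumor mutation counts,
match counts, and match probabilities (0.137 for the three PIK3CA
H1047R matches; rare matches are reported only as "< 1/1000" and we use
the bound $10^{-3}$, the conservative choice because it *weakens* the
rare-match evidence). Private-locus probabilities are not published;
we default them to $10^{-3}$, and the likelihood is insensitive to
this because private terms depend on $p$ only through $1-p$ factors.
Matched mutations are counted inside the published per-tumor totals,
so a case contributes `left + right - 2 * matches` private loci. All
three probability choices are exposed as arguments.

```{r example, eval = FALSE}
tbl <- contralateral_breast_cases()
fit <- fit_em(tbl, multistart = TRUE)
tidy(fit)     # pi ~ 0.0586: close to 3/49, the three rare-match cases
```

On the full data both estimators give $\hat\pi \approx 0.059$, and the
posterior weights separate exactly as the evidence suggests: the three
rare-match cases receive high $w_j$, the three hotspot-match cases low
$w_j$.

Removing the two most clearly clonal cases (36 and 48) exposes a real
weakness of the *model* — not of either algorithm. The exact
likelihood surface of the reduced dataset develops a narrow interior
ridge at $\sigma$ near its floor and $\mu \approx -3.7$: a clonal
component degenerated to a near-point mass at $\xi \approx 0.03$,
which mimics the independent component everywhere except on the one
remaining rare match. Along this ridge the likelihood exceeds both the
$\pi = 0$ plateau and the moderate-signal region by a few thousandths
of a log-likelihood unit, and the configuration is insensitive to the
exact value of the $\sigma$ floor. This is the classic mixture
degeneracy (as with variance-collapsing components in normal
mixtures). Consequences with our accurate quadrature: the one-step
maximizer finds the ridge (an interior $\hat\pi \approx 0.15$ with a
degenerate signal) rather than the boundary, and EM drifts slowly
along the ridge without meeting the convergence tolerances within
`max_iter` (passing $\hat\pi \approx 0.05$ early, ending near
0.08–0.10 depending on the start). Coarser integration schemes cannot
resolve the ridge and instead return either the boundary $\hat\pi = 0$
(one-step) or a stop in the slow $\hat\pi \approx 0.05$ basin (EM).
We report what the exact surface supports and flag non-convergence
honestly rather than tuning the stopping rule to a preferred answer;
users should treat near-degenerate fits ($\sigma$ at its floor, or EM
not converged) as a sign that the data cannot identify the signal
distribution, and consider fixing $\sigma$ or adding cases.

## The simulator and what passing tests mean

`simulate_cases()` draws from exactly the generative model the
likelihood assumes: Bernoulli clonality, lognormal signal, and
per-locus shared/private indicators with the model's conditional
probabilities. Three reference signal shapes are built in
(`scenario_params()`): sparse matching ($\mu=-2, \sigma=1.5$),
intermediate ($-1, 1$), and saturated ($0.7, 0.3$).

The mutation-profile distribution is not dictated by the model, so it
is a design choice, fixed once: loci per case $\sim 1 +
\text{Poisson}(6)$ (matching the observed per-case totals of roughly
1–16 in the breast study), and $p$ drawn as a 90/10 mixture of rare
(log-uniform on $[10^{-4}, 10^{-2}]$) and hotspot-like (uniform on
$[0.05, 0.15]$, bracketing 0.137) values — a panel with mostly rare
variants and a minority of hotspots. `loci_model()` exposes every
knob. Because sparse-information settings are sensitive to this
choice, cell-level results under the sparse scenario are reproduced
qualitatively (boundary-count ordering between estimators), while the
informative scenarios are reproduced numerically.

`run_study()` fits every replicate with both estimators and reports
per-cell mean, sd, range, boundary counts, and the EM summary
restricted to replicates where one-step hit a boundary. The test suite
runs the study at desk scale — 200 replicates for the $n = 100$ cells
and 100 replicates for the sparse $n = 25$ cell, against 500 in a
full-scale run — and a 20-seed parameter-recovery check at $n = 500$;
`replicates` restores any scale.

What these passing tests do **not** show: performance on real data.
The generator draws loci independently with known $p_i$; real panels
have correlated mutations (pathway co-occurrence and mutual
exclusivity), subtype-dependent occurrence probabilities, and $p_i$
that must themselves be estimated from external catalogs — all outside
the model. The simulation results validate the estimators *under the
model*, not the model itself.

## Limitations

* Occurrence probabilities are treated as known; estimating them (and
  propagating their uncertainty) is out of scope.
* Loci are modeled as independent within a case.
* No standard errors or confidence intervals are produced; study-level
  spread comes from Monte-Carlo replication.
* Near-boundary datasets can be weakly identified (the ridge above);
  diagnostics (`converged`, `boundary`, `sigma` at floor) should be
  inspected before interpreting $\hat\pi$.
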