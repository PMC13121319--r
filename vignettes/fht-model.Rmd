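---
title: "Dependent censoring from coupled compound Poisson hitting times: model, estimation, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dependent censoring from coupled compound Poisson hitting times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpfht)
```

## The model

Two nonnegative, nondecreasing pure-jump processes share one Poisson clock:
inter-arrival times $E_1, E_2, \dots$ are i.i.d. exponential with intensity
$\lambda > 0$, and at the $n$-th tick the first margin jumps by $X_n$ and the
second by $Z_n$, with $(X_n)$ and $(Z_n)$ i.i.d. sequences independent of the
clock and of each other. The event time $T$ is the first clock time at which
the cumulative $X$-jumps reach a threshold $x > 0$; the censoring time $C$ is
the first time the cumulative $Z$-jumps reach $z > 0$. Because both margins
are inspected at the same random times, $T = C$ happens with positive
probability: the joint law of $(T, C)$ has an absolutely continuous part off
the diagonal and a singular part on it. This is the natural description of
follow-up studies where two monotone markers are measured at the same
irregular visits and a decision is triggered when either crosses a critical
level.

Only the censored outcome is observed, under one of two schemes:

* **Model I**: $(Y, \Delta) = (\min(T, C),\ 1\{T \le C\})$;
* **Model II**: $(Y, \Delta) = (\min(T, C),\ \Delta)$ with $\Delta = 0$ for
  $T > C$, $1$ for $T < C$, and $2$ for the tie $T = C$.

Everything about the model is channelled through the *coefficient sequences*
$$c_{n,X} = P(X_1 + \dots + X_n < x), \qquad c_{n,Z} = P(Z_1 + \dots + Z_n < z),$$
with $c_{0} = 1$ and a strict inequality (the crossing rule is
$\ge$ the threshold). Each outcome branch density is a Poisson mixture: for
example the Model I uncensored branch is
$$f(t, 1) = \sum_{n \ge 0} (c_{n,X} - c_{n+1,X})\, c_{n,Z}\,
\lambda e^{-\lambda t} \frac{(\lambda t)^n}{n!},$$
the tie probability is $P(T = C) = \sum_n (c_{n,X} - c_{n+1,X})(c_{n,Z} -
c_{n+1,Z})$ (free of $\lambda$), and the hazard of $Y$ is
$\lambda(1 - g(t))$ with $g$ a ratio of two coefficient-weighted series.
`coeff_sequence()` computes the sequences with closed forms only: binomial
and Poisson convolution identities for the lattice families, the gamma
convolution for exponential/gamma jumps, and an exact truncated convolution
for user-supplied finite lattices. No numeric convolution of arbitrary
densities is attempted; the named families cover every configuration used by
the experiments, and an unvalidated generic code path would be a liability.

## Identifiability and the jump-law taxonomy

Whether the observed outcome law pins down $(\lambda, \alpha, \beta)$ depends
on the jump laws through three classes (`classify_family()`): **F1** (jumps
a.s. bounded away from 0, so the sequences hit an exact zero), **F2**
(absolutely continuous with mass near 0; the ratio $c_{n+1}/c_n \to 0$), and
**F3** (discrete with an atom at 0; the ratio tends to $P(\text{jump}=0)$
with an $O(1/n)$ discrepancy). If either margin is F1 or F2 the hazard
plateau identifies $\lambda$ and Model I suffices (conditions H1/H2.i); if
both margins are F3 the plateau only identifies $\lambda(1 - P[X_1=0]P[Z_1=0])$
and the tie-aware Model II is required (H2.ii). `check_assumption()` performs
this routing, and `ratio_limit_diagnostic()` estimates the tail ratio by
regressing on $1/n$ and $1/n^2$ — it *reports* the trend, never asserts class
membership, because the constant in the $O(1/n)$ bound is purely existential.
Two cautionary constructions are kept as executable demonstrations:
`mixture_pair_gap()` (two different $(\lambda, \text{coefficients})$ pairs
with one and the same mixture density) and `matched_binomial_parameter()`
(two binomial jump laws of different sizes that agree on the single relevant
coefficient).

## Truncation of the series

The likelihood uses the partial sums up to an order $N$, frozen before
optimization so the objective is smooth in $\theta$. When either margin is
F1 the series terminates and the evaluation is exact
(`fht_model()` auto-detects this; the Bernoulli/degenerate configuration
terminates at $N = 17$). Otherwise a uniform bound on the log-density
truncation error over $[0, \tau] \times \{0,1,2\}$ is available
(`remainder_bound()`): for any $\lambda_m \ge \lambda$ it is
$\min_j \{ j!/(\lambda_m\tau)^j\, b_{j,N}\, \text{TAIL} \}$, where $b_{j,N}$
compares the supremum of the post-$N$ branch coefficients to their value at
$j$, and TAIL is the exact tail sum of $(\lambda_m\tau)^n/n!$ or, cruder,
$e^{\lambda_m\tau}$. Both variants are reported; the supremum over $n > N$ is
taken on a finite window with a verified-decrease stopping rule. For the
two-exponential configuration at $N = 25$, $\lambda_m = 2$, $\tau = 20$, the
bound is finite but large — with $\lambda_m \tau = 40 > N$ the tail factor is
enormous, and small printed magnitudes sometimes quoted for comparable
setups could not be reproduced by direct evaluation of the formula. The
package therefore reports the bound as computed and treats $N$ pragmatically:
`choose_truncation()` returns the exact order when one exists, scans the
bound otherwise, and falls back to
$\lceil \lambda_m\tau + 10\sqrt{\lambda_m\tau}\rceil$, past which the Poisson
weights themselves are negligible on $[0, \tau]$.

Two distinct orders are involved, and conflating them was the source of a
bug worth documenting. The *likelihood* order stays frozen (that is the
estimator being studied). The *descriptive* evaluators — hazard, marginal
and observed-time survival, and the off-diagonal joint density — extend the
order with the evaluation time (the Poisson weight is centered at
$\lambda t$, so they use $N_{\text{eval}} \approx$ the $1-10^{-13}$ Poisson
quantile). They also work from log-coefficients (`pgamma(..., log.p=TRUE)`
and friends) because for exponential jumps $c_n$ underflows the double range
past $n \approx 200$. Without both measures the hazard tail and the $u > v$
branch of the joint density (whose outer index counts the *later* margin's
jumps) are silently wrong.

A related caution on the hazard plateau: for two exponential margins the
dominant index of the hazard ratio grows like
$(\alpha x \cdot \beta z \cdot \lambda t)^{1/3}$, so
$\lambda - h_Y(t) \sim t^{-2/3}$ — the limit is $\lambda$ but the approach is
slow (still $\approx 0.1$ at $t = 400$ in the reference configuration). Tests
assert the decay law, not an unattainably tight gap at moderate $t$.

## Simulation

`simulate_latent()` draws, per subject, one shared stream of exponential
inter-arrivals feeding both margins (independent clocks are deliberately not
offered — the common clock *is* the dependence structure). Ties are decided
by equality of the jump counts at crossing, never by comparing
floating-point times: the diagonal atom is a structural event. A per-subject
cap on ticks (default $10^6$) guards against jump laws with almost all mass
at 0. The generator doubles as the test-data source; its default
configurations (`study_case()`) are:

| case | $\lambda$ | $X_1$ | $Z_1$ | $(x, z)$ | condition | scheme | $N$ |
|---|---|---|---|---|---|---|---|
| a | 1.42 | Bernoulli(0.36) | $\equiv 1$ | (7, 17) | H1 | I | 17 (exact) |
| b | 1.42 | Exp(0.71) | Exp(2.04) | (14, 7) | H2.i | I | 25 |
| c | 1.42 | Bernoulli(0.36) | Poisson(1.23) | (7, 19) | H2.ii | II | 28 |

What the generator emulates is exactly the model's own data-generating
process; what it does not emulate is anything a real study adds on top —
covariates, heterogeneous thresholds, rounding of recorded times,
non-exponential visit gaps. Passing tests therefore validate the
implementation against its own probabilistic claims, not the adequacy of the
model for any particular dataset.

## Estimation and asymptotics

`fit_mle()` maximizes the mean log-likelihood
$\frac1n \sum_i \log f(Y_i, \Delta_i;\theta)$ over a compact box (defaults:
$\lambda$ and rate-type parameters in $[0.01, 50]$, probabilities in
$[0.001, 0.999]$; the box is configurable since the interior-truth assumption
is the user's to guarantee). The search is bounded quasi-Newton (`L-BFGS-B`)
on transformed coordinates — log for intensity/rates, logit for
probabilities — restarted from random points in the central half of the
transformed box (5 by default), keeping the best interior optimum. The
density accumulates in log space by log-sum-exp with zero coefficients
skipped, since $(\lambda t)^n/n!$ overflows in linear space for
$\lambda t \gtrsim 30$.

`info_matrices()` returns $A_n$ (averaged Hessian of the per-observation
log-densities) and $B_n$ (averaged outer products of scores) by central
finite differences, with steps scaled to parameter magnitude
($10^{-5}$-relative for scores, $\varepsilon^{1/4}$-relative for the
Hessian). Analytic derivatives for every family would multiply code with
little benefit; the Erlang special case, where the derivative is available
by hand, is used as a unit-test oracle instead. `sandwich_cov()` forms the
robust $A_n^{-1} B_n A_n^{-1}$ and the model-based $-A_n^{-1}$; in this
well-specified setting $A = -B$ at the truth, and the relative gap
$\|A_n + B_n\|/\|B_n\|$ at the optimum is monitored as a specification
check (≤ 0.1 on large samples in the tests).

## The simulation experiments

`coverage_experiment()` fits $M$ independent replicates and reports the
fraction of the pivots
$n(\hat\theta_k - \theta^0)^\top A (\hat\theta_k - \theta^0)$ below
$\chi^2_{1+d_1+d_2}$ quantiles, with $A$ either $B_n(\hat\theta_k)$ or
$D^{-1}$, $D$ the empirical covariance of the $\sqrt n$-scaled estimates.
$D$ is centered at the empirical mean — the standard estimator; truth
centering is available as an option and differs by $O(\text{bias}^2)$.
Replicate seeds are `base_seed + k`; failed fits and non-positive-definite
matrices are excluded with reported counts. `bias_mse_curves()` computes the
pointwise mean squared error and mean absolute error of the estimated
marginal CDFs over replicates.

Problem sizes used by the shipped tests are deliberate choices: coverage at
$M = 100$ for $n = 50$ (configurations a and b) and $n = 800$
(configuration a, whose replicates also feed the Mardia normality omnibus);
recovery checks at $n = 5000$; Monte-Carlo/analytic agreement at $10^5$
paths. These reproduce the first and last columns of the reference coverage
tables rather than every intermediate sample size.

One empirical finding deserves emphasis. For configuration b at $n = 50$
our $B_n$-based pivot is close to calibrated (acceptance rate ≈ 0.89 at the
90% level): the measured covariance of $\sqrt n(\hat\theta - \theta^0)$
exceeds the asymptotic $-A(\theta^0)^{-1}$ by only ~25–30%, which caps how
much under-coverage the pivot can show. Reports of much stronger
finite-sample under-coverage for this pivot depend on the numerical route
used for the scores and the optimizer; the package reports what it computes.
The $D^{-1}$ pivot row and the entire configuration-a table are reproduced
within binomial noise.

## Degenerate inputs, tie-breaks, tolerances

* Strictness on lattice boundaries: $P(S_n < x)$ is the CDF at the largest
  lattice point strictly below $x$; for user lattices a relative tolerance
  of $10^{-9}$ decides "at the threshold".
* $t = 0$ is admitted in the densities through the $n = 0$ term only.
* `joint_density_ac()` refuses $u = v$ rather than returning 0: the
  singular component lives there.
* Coefficient sequences are cached by value of (family, parameters,
  threshold, order), since the optimizer re-evaluates them at every step.
* The tie probability attaches a tail bound
  $\min(c_{N+1,X}, c_{N+1,Z})$ and flags results when it exceeds a
  tolerance (default $10^{-6}$).

## Limitations

No covariates or regression structure; no random thresholds; no
time-inhomogeneous intensities; monotone processes only. The `binomial`
size and `discrete_lattice` atoms are structural (fixed, not estimated).
Verifying the F2 convolution-monotonicity property for arbitrary
user-supplied densities is out of scope — classification relies on the
named families' known properties.
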