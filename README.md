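# cpfht

Dependent and censored first hitting times of coupled compound Poisson
processes.

## The problem

In many follow-up studies two monotone markers are measured for each subject
at the *same* irregular visit times, and the record stops when either marker
crosses a critical level — think of a liver-injury enzyme rising toward its
peak while a coagulation factor falls toward a transplantation threshold,
both sampled at the same hospital visits. The event time and the censoring
time are then *dependent*, and they can be *exactly equal* with positive
probability (both crossings detected at the same visit). Standard
survival tools, and most copula-based dependent-censoring methods, assume a
jointly absolutely continuous law and cannot express this atom on the
diagonal.

`cpfht` implements a first hitting-time model that builds the dependence
structurally. A single Poisson clock with intensity $\lambda$ drives both
margins: at the $n$-th tick the first latent process jumps by $X_n$ and the
second by $Z_n$ (i.i.d. nonnegative jumps, parametric families). The event
time $T$ and censoring time $C$ are the first clock times at which the
cumulative jumps reach thresholds $x$ and $z$. The observable is
$(Y, \Delta)$ with $Y = \min(T, C)$ and either $\Delta = 1\{T \le C\}$
(Model I) or $\Delta \in \{0, 1, 2\}$ distinguishing the tie (Model II).

All model functions are Poisson mixtures of the coefficient sequences
$c_{n,X} = P(X_1 + \dots + X_n < x)$ and $c_{n,Z} = P(Z_1 + \dots + Z_n < z)$;
for example

$$f(t, 1) = \sum_{n\ge0} (c_{n,X} - c_{n+1,X})\,c_{n,Z}\,
\lambda e^{-\lambda t}\tfrac{(\lambda t)^n}{n!},
\qquad
P(T{=}C) = \sum_{n\ge0} (c_{n,X} - c_{n+1,X})(c_{n,Z} - c_{n+1,Z}).$$

The package provides exact simulation of the latent process and outcomes,
closed-form/truncated-series densities with an explicit truncation-error
bound, identifiability diagnostics (which jump-law classes require the
tie-aware Model II), maximum-likelihood estimation with sandwich covariance
$A_n^{-1} B_n A_n^{-1}$, and the coverage/bias simulation experiments. See
the vignette (`vignettes/fht-model.Rmd`) for the methods account.

## Worked example

Two exponential jump families (both class F2, so Model I identifies all
three parameters):

```r
library(cpfht)
cs <- study_case("b")     # lambda = 1.42, X ~ Exp(0.71), Z ~ Exp(2.04),
print(cs$model)           # thresholds (14, 7), series order N = 25
#> hitting-time model (Model I), thresholds x = 14, z = 7, N = 25
#> X margin: jump family: exponential(rate=0.71)  [P(jump = 0) = 0, class F2]
#> Z margin: jump family: exponential(rate=2.04)  [P(jump = 0) = 0, class F2]
#> identifiability: H2.i

s <- simulate_sample(cs$theta, cs$model, n = 1000, seed = 42)
table(s$delta)            # 0 = censored (T > C), 1 = event (T <= C)
#>   0   1
#> 150 850
prob_equal(cs$theta, cs$model)   # structural tie probability
#> [1] 0.0555193

fit <- fit_mle(s, cs$model, starts = 3, seed = 7)
print(fit)
#> hitting-time model fit (Model I, n = 1000, N = 25)
#>            estimate       se
#> lambda      1.46660 0.064559
#> alpha.rate  0.74947 0.035918
#> beta.rate   2.16670 0.094039
#> mean log-likelihood -2.901374, converged: TRUE
```

Each estimate is within two standard errors of the generating values
(1.42, 0.71, 2.04). The standard errors come from the sandwich covariance,
`sqrt(diag(A_n^{-1} B_n A_n^{-1}) / n)`.

Identifiability diagnostics route a configuration to the observation scheme
it needs:

```r
check_assumption(cs$model$x_family, cs$model$z_family, 14, 7)
#> assumption H2.i (X: F2, Z: F2) -> Model I
#> Model I sufficient
```

A configuration with discrete jumps and atoms at zero on both margins
(e.g. Bernoulli and Poisson jumps, `study_case("c")`) returns `H2.ii`:
there Model I cannot identify the intensity and Model II is required.

A thin command-line wrapper over these functions is installed at
`inst/cli/cpfht.R` (`simulate`, `fit`, `coverage`, `curves`, `diagnose`
against a YAML config; every run writes a manifest from which its artifacts
can be regenerated byte-identically).

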