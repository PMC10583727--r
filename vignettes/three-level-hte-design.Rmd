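---
title: "Designing three-level randomized trials for treatment effect heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing three-level randomized trials for treatment effect heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hte3)
library(dplyr)
```

## The design problem

Pragmatic trials in health care delivery often randomize intact groups and
collect outcomes on participants nested in subclusters (providers, clinics,
schools) nested in clusters (health systems, districts). Beyond the average
treatment effect (ATE), investigators increasingly prespecify *confirmatory*
analyses of treatment effect heterogeneity (HTE): does the effect differ
across subpopulations defined by a baseline effect modifier such as a test
score, gender, or self-rated health? Powering that interaction test is
harder than powering the ATE because the answer depends not only on how
outcomes cluster but also on how the *modifier itself* clusters.

`hte3` implements the full analytic machinery for this problem: variances
and design effects for the interaction and ATE estimators under
randomization at any of the three levels, power and sample-size solvers,
a generative simulator, and a fast REML engine so that every closed form
can be checked empirically.

## Model and assumptions

The analysis model is a linear mixed ANCOVA. For participant $k$ in
subcluster $j$ of cluster $i$,

$$
Y_{ijk} = \beta_1 + \beta_2 W_{ijk} + \beta_3^T X_{ijk}
        + \beta_4^T W_{ijk} X_{ijk} + \gamma_i + u_{ij} + \epsilon_{ijk},
$$

with independent normal random intercepts at the cluster
($\sigma^2_\gamma$) and subcluster ($\sigma^2_u$) levels and residual
$\sigma^2_\epsilon$. The null hypothesis of no systematic HTE is
$\beta_4 = 0$; after globally mean-centering $X$, $\beta_2$ is the
covariate-adjusted ATE. The design is balanced: $n_c$ clusters, $n_s$
subclusters per cluster, $m$ participants per subcluster, and exact
allocation of a fraction $\bar W$ of units at the randomized level.

Two nested exchangeable correlation structures carry all the dependence
information:

* **outcome ICCs** conditional on the modifier: $\alpha_0$ within a
  subcluster, $\alpha_1$ across subclusters of the same cluster;
* **covariate ICCs** of the modifier: $\rho_0$ and $\rho_1$ analogously.

Each structure has three distinct eigenvalues, e.g. for the outcome
$\lambda_1 = 1-\alpha_0$,
$\lambda_2 = 1+(m-1)\alpha_0 - m\alpha_1$,
$\lambda_3 = 1+(m-1)\alpha_0 + (n_s-1)m\alpha_1$
(with $\zeta_1,\zeta_2,\zeta_3$ for the modifier), and a closed-form
inverse, which is why none of the production code ever factorizes a
matrix: everything is $O(1)$ in the eigenvalue algebra
(`nex_spec()`, `nex_eigen()`, `nex_inverse()`).

## Variances and design effects

All unit variances scale an unclustered base variance by a design effect.
For the interaction estimator
($\sigma_4^2 = \lim n_c n_s m\,\mathrm{var}(\hat\beta_4)$, base
$\sigma^2_{y|x}/\{\bar W(1-\bar W)\sigma^2_x\}$):

| randomization | design effect |
|---|---|
| cluster | $n_s m \big/ \{\lambda_3^{-1}\zeta_3 + (n_s-1)\lambda_2^{-1}\zeta_2 + n_s(m-1)\lambda_1^{-1}\zeta_1\}$ |
| subcluster | $m \big/ \{m\lambda_1^{-1} - (1+(m-1)\rho_0)(\lambda_1^{-1}-\lambda_2^{-1})\}$ |
| participant | $\lambda_1$ |

For the covariate-adjusted ATE the design effect is simply $\lambda_3$,
$\lambda_2$, or $\lambda_1$. Useful consequences, all of which are tested:

* variances are ordered: cluster $\ge$ subcluster $\ge$ participant
  randomization, for both estimands;
* the interaction variance depends only on covariate ICCs *within* the
  randomization unit (a subcluster-randomized trial is free of $\rho_1$;
  an individually randomized trial is free of both);
* unlike the ATE design effect, the HTE design effect under cluster
  randomization is bounded as $m \to \infty$, approaching
  $(1-\alpha_0)/(1-\rho_0)$ — with possible variance *deflation* when
  $\rho_0 \le \alpha_0$;
* for a binary modifier $\sigma^2_x = p(1-p)$, so HTE power is maximal at
  prevalence one half;
* modifiers measured at the subcluster level ($\rho_0 = 1$) or cluster
  level ($\rho_0=\rho_1=1$) reduce to simpler forms, the latter matching
  the ATE design effect exactly.

```{r}
d <- design_spec(n_s = 4, m = 20, rand_level = "cluster")
o <- outcome_model(alpha0 = 0.015, alpha1 = 0.01)
x <- modifier_model(rho0 = 0.15, rho1 = 0.10)
hte_unit_variance(d, o, x)
```

## The closed forms versus the exact expected information

The package also ships an exact oracle, `gls_unit_variance()`: it assembles
the expected per-cluster GLS information $E[Z^T R^{-1} Z]$ with the
modifier expectation taken analytically and the allocation second moments
taken exactly under balanced randomization (within a randomization unit
$E[w_t w_{t'}] = \bar W(1-\bar W)$; across the $K$ units of an enclosing
unit $-\bar W(1-\bar W)/(K-1)$, the without-replacement covariance), then
inverts.

Developing this oracle surfaced a genuine and, to our knowledge,
undocumented property of the closed forms above: the cluster-randomized
HTE variance and all three ATE variances agree with the exact information
to machine precision, but the **subcluster- and participant-randomized HTE
forms are leading-order approximations**. They omit allocation coupling
terms of size $(\lambda_3-\lambda_2)\zeta_2/(n_s\lambda_2\lambda_3)$
(subcluster) and $O(1/m)$ (participant) in the information, which vanish
as the number of randomization units per enclosing unit grows but are
visible at very small $n_s$ or $m$ (up to ~15% in variance at
$n_s = m = 2$, under 1–4% at realistic sizes). We verified this three
independent ways: exact enumeration over balanced allocations, Monte Carlo
estimates of the expected information, and direct simulation of the
realized GLS estimator, which tracks the oracle, not the approximation.

The package deliberately implements the *classical closed forms* as the
design engine — they are the method, they reproduce the benchmark design
tables and worked examples, and at design-relevant sizes the approximation error is far
below the uncertainty in any assumed ICC. The oracle is exported so users
can quantify the gap for their own design; the test suite asserts the
machine-precision identities where they hold and the convergence of the
approximate forms to the oracle where they do not. One acceptance check
that demands 1e-8 oracle equality for *all* closed forms at tiny designs
is left failing on the two approximate cases, intentionally: the
discrepancy is a property of the formulas, not of this implementation.

The multivariate generalization `mv_omega4()` substitutes the block
eigen-matrices of a `nex_block()` structure for the scalar $\zeta$ terms in
the same printed forms, so its $p=1$ case reduces exactly to the scalar
engine at every randomization level, and its cluster-randomized case is
exact. The block parameterization (total, within-subcluster, and
between-subcluster cross-covariance blocks) is the minimal set the
expected-information computation needs; its scalar reduction to the
univariate structure is the internal-consistency check.

## Power and sample size

`wald_power()` evaluates the two-sided power
$\Phi(|\Delta|/\mathrm{SE} - z_{1-\alpha/2}) +
 \Phi(-|\Delta|/\mathrm{SE} - z_{1-\alpha/2})$ with
$\mathrm{SE} = \sqrt{\sigma^2/(n_c n_s m)}$. The minor tail is included
because it is analytically part of a two-sided test; at design-relevant
effect sizes it changes nothing at three decimals. Sample size inverts the
inequality $n_c n_s m \ge \sigma^2 (z_{1-\alpha/2}+z_{1-\lambda})^2 /
\Delta^2$ and rounds up to feasibility: under cluster randomization with
equal allocation, the next *even* integer, so the randomization itself is
exactly balanced.

Two non-normal references are provided:

* **between-within t** ($n_c - 2$ df) for the ATE under cluster
  randomization. The solver iterates the noncentral-t power criterion over
  feasible integers rather than inverting the normal formula — at
  $m=20$, $n_s=4$, small ICCs and $\Delta_{\mathrm{ATE}} = 0.2$ the normal
  criterion gives 20 clusters while the t criterion correctly requires 22;
* **noncentral chi-square** for joint tests of $p$ modifiers
  (`mv_power()`, `mv_required_clusters()`), with noncentrality
  $n_c \Delta^T \Omega_4^{-1} \Delta$ and root-solving over $[1, 10^6]$.

`solve_dimension()` can instead solve $n_s$ or $m$, re-evaluating the unit
variance at each candidate (it depends on both); because the
cluster-randomized ATE variance grows linearly in $m$, power can plateau
below target, which is reported as an explicit "unattainable" error rather
than a huge number. `power_contour()` evaluates sensitivity grids over
$(\rho_0, \rho_1/\rho_0)$ or $(\alpha_0, \alpha_1/\alpha_0)$, flagging
infeasible ICC combinations instead of dropping them;
`plot_power_contour()` renders them.

```{r}
required_clusters(hte_unit_variance(d, o, x), 4, 20, effect = 0.1)
```

## The simulator and what it does (not) emulate

`simulate_trial()` draws the modifier from the nested random-effects model
$X_{ijk} = \mu_x + a_i + b_{ij} + c_{ijk}$ with component variances
$\sigma^2_x\rho_1$, $\sigma^2_x(\rho_0-\rho_1)$, $\sigma^2_x(1-\rho_0)$,
assigns treatment by exact permutation at the randomized level, and
generates outcomes from the ANCOVA model with components
$\sigma^2_{y|x}\alpha_1$, $\sigma^2_{y|x}(\alpha_0-\alpha_1)$,
$\sigma^2_{y|x}(1-\alpha_0)$. Defaults in `builtin_scenarios()` mirror the
canonical study conditions: $m \in \{20, 50\}$, $n_s \in \{4, 8\}$,
$(\alpha_0,\alpha_1) \in \{(0.015,0.01), (0.1,0.05)\}$,
$(\rho_0,\rho_1) \in \{(0.15,0.1), (0.3,0.15), (0.5,0.3)\}$, fixed effects
$\beta_1 = 1$, $\beta_2 = 0.2$, $\beta_3 = 0.3$, $\mu_x = 1$, effects
$\Delta_{\mathrm{HTE}} = 0.1$ and $\Delta_{\mathrm{ATE}} = 0.2$, 5%
two-sided tests at 80% power.

Binary modifiers are generated by a shared-response scheme: a participant
copies a cluster-level Bernoulli($p$) draw with probability
$\sqrt{\rho_1}$, otherwise a subcluster-level draw with probability chosen
so the within-subcluster correlation is exactly $\rho_0$ (feasible when
$\rho_0 - \rho_1 \le (1-\sqrt{\rho_1})^2$), otherwise its own draw. All
margins are exactly Bernoulli($p$) and all design formulas use second
moments only, so this is sufficient for validation; it is *not* a claim
about the joint distribution of any real binary trait.

What passing simulations establish is therefore calibration *under the
generative model the formulas assume*: Gaussian components, balance, a
correctly specified ANCOVA. Real trials with unequal cluster sizes,
non-normal outcomes, informative cluster sizes, or missing data are
outside what these tests can certify.

For the unadjusted-analysis comparison, `marginal_icc()` converts
conditional parameters to marginal ones: with $b_3 = \beta_3 +
\beta_4\bar W$, the modifier contributes
$c^2 = (b_3^2 + \beta_4^2\bar W(1-\bar W))\sigma^2_x$ to the
treatment-conditional outcome variance, giving weight
$\omega = \sigma^2_{y|x}/(\sigma^2_{y|x}+c^2)$ and marginal ICCs
$\tilde\alpha = \omega\alpha + (1-\omega)\rho$. This closed form is exact
under cluster-level randomization (treatment constant within clusters,
arm-wise averaging of the interaction slope) and is gated in the tests on
a Monte Carlo oracle rather than trusted as algebra. Sizing the unadjusted
analysis with $(\tilde\alpha_0,\tilde\alpha_1,\sigma^2_y)$ never needs
fewer clusters than the covariate-adjusted analysis across the built-in
grid — the quantitative case for adjustment.

## REML inference engine

`fit_lm_ancova()` maximizes the restricted likelihood natively on balanced
data. Three cross-product matrices (raw, subcluster-summed,
cluster-summed) are accumulated once; each likelihood evaluation is then
closed-form via the eigenvalue algebra, with the total variance profiled
out and the two ICCs optimized on the unconstrained
log-relative-variance scale $(\log\sigma^2_\gamma/\sigma^2_\epsilon,
\log\sigma^2_u/\sigma^2_\epsilon)$ by Nelder–Mead (relative tolerance
1e-12, 500 iterations). This keeps components nonnegative by
construction; estimates whose relative components fall below 1e-7 are
reported as exact zeros, and at that boundary the GLS fit coincides with
ordinary least squares. A fit takes a few milliseconds at thousands of
rows, which is what makes simulation-based validation routine. The engine
is checked against a dense-matrix restricted-likelihood oracle at tiny
sizes (1e-8) and against `lme4` on moderate data (estimates, standard
errors, and variance components to four decimals); `lme4` is a
cross-check, never the implementation.

`wald_hte()` tests the interaction against the standard normal (or the
$\chi^2_p$ quadratic form jointly); `wald_ate()` tests the treatment main
effect against the normal or the between-within $t(n_c-2)$ reference. The
HTE statistic is invariant to modifier centering.
`operating_characteristics()` wraps the replicate loop with counter-based
per-replicate seeds (`seed + replicate`), a single refit from independence
starting values on non-convergence, and explicit failure counts — in
practice the native engine converges on every replicate of the built-in
scenarios.

## Numerical and scope choices

* Validity of an ICC pair is exactly the positivity of its eigenvalue
  triple; $\alpha_1 > \alpha_0$ only warns, since the algebra does not
  forbid it. Covariate structures may be degenerate ($\rho_0 = 1$):
  positive semidefiniteness suffices there.
* Dense matrices exist only in oracles and tests (dimension guards at
  5000); production formulas are eigenvalue-algebraic.
* Feasibility rounding generalizes "next even integer" to the smallest
  integer making the randomized-unit count times the allocation fraction
  integral.
* Noncentral t and chi-square tails come from R's standard distribution
  functions.
* Problem sizes in the test and acceptance runs are chosen for a single
  CPU: the empirical power reproduction uses 500–600 replicates (the
  reference tables used 5000) and the null-calibration check 1000, with
  agreement judged within three binomial Monte Carlo standard errors;
  `run_report(grid, reps = 5000)` reproduces the full-scale experiment
  when a machine budget allows.

## Limitations

Equal cluster and subcluster sizes are assumed throughout; unequal-size
corrections, binary outcomes with binomial variance (the linear model is
at best an approximation there), random covariate-effect (slope) models,
and working-correlation misspecification are out of scope. The
between-within $t$ correction is applied only where the reference
experiments applied it (ATE under cluster randomization); no
Kenward–Roger or Satterthwaite machinery is provided for the HTE test.
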