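# hte3

Design and validation machinery for **three-level randomized trials**
(participants nested in subclusters nested in clusters) that are powered for
**confirmatory treatment-effect-heterogeneity (HTE) analysis** — the Wald
test of a treatment-by-covariate interaction in a linear mixed ANCOVA — as
well as for the covariate-adjusted average treatment effect (ATE).

It is written for trial statisticians planning pragmatic cluster or
subcluster randomized trials: given outcome intraclass correlations
(ICCs) conditional on an effect modifier, the ICCs *of the modifier
itself*, variances, an effect size, and a randomization level, it returns
the interaction-estimator variance, the design effect, the power, and the
required number of clusters — and can verify any of those numbers by
simulating trials and refitting them with a fast built-in REML engine.

## The model and the key quantities

For participant *k* in subcluster *j* of cluster *i*:

    Y_ijk = b1 + b2 W_ijk + b3 X_ijk + b4 W_ijk X_ijk + g_i + u_ij + e_ijk

with nested random intercepts. Outcomes have conditional ICCs `alpha0`
(within subcluster) and `alpha1` (between subclusters); the modifier has
ICCs `rho0`, `rho1`. Both correlation structures are *nested exchangeable*
with three eigenvalues, e.g. `lambda1 = 1 - alpha0`,
`lambda2 = 1 + (m-1) alpha0 - m alpha1`,
`lambda3 = 1 + (m-1) alpha0 + (n_s-1) m alpha1`.

The variance of the interaction estimator, standardized by total sample
size, is the unclustered ANCOVA variance
`sigma2_y / (W(1-W) sigma2_x)` times a design effect: under cluster
randomization

    theta = n_s m / ( zeta3/lambda3 + (n_s-1) zeta2/lambda2 + n_s (m-1) zeta1/lambda1 ),

with simpler forms for subcluster-level randomization (free of `rho1`) and
participant-level randomization (`theta = 1 - alpha0`). The ATE design
effect is a single eigenvalue (`lambda3`, `lambda2`, or `lambda1`). Sample
size solves `n_c n_s m >= sigma^2 (z_{1-a/2} + z_{power})^2 / effect^2`,
rounded up to an even number of clusters under equal cluster
randomization; the ATE under cluster randomization uses an iterated
noncentral-t criterion with `n_c - 2` degrees of freedom.

## Worked example

Power a cluster-randomized literacy trial (`n_s = 4` schools per zone,
`m = 25` children per school) to detect effect modification by baseline
score, with outcome ICCs 0.104 / 0.008, covariate ICCs 0.2 / 0.1, and a
standardized interaction effect of 0.12:

```r
library(hte3)

d <- design_spec(n_s = 4, m = 25, rand_level = "cluster")
o <- outcome_model(alpha0 = 0.104, alpha1 = 0.008)
x <- modifier_model(rho0 = 0.2, rho1 = 0.1)

(v <- hte_unit_variance(d, o, x))
#> Unit variance (HTE, cluster randomization): 4.34948  [design effect 1.08737]

required_clusters(v, n_s = 4, m = 25, effect = 0.12)
#> Required n_c: 24 (raw 23.707, achieved power 0.805, normal reference)
```

So residual clustering inflates the interaction variance by ~9%, and 24
randomized zones (rounded up to an even number for 1:1 allocation) give
80% power. The same calls with `ate_unit_variance()` size the ATE; a
binary modifier uses `modifier_model(kind = "binary", prevalence = p)`,
whose variance `p(1-p)` makes power best at prevalence 0.5.

To check a design by simulation instead of formula:

```r
oc <- operating_characteristics(
  design_spec(42, 4, 20, "cluster"),
  outcome_model(alpha0 = 0.015, alpha1 = 0.01),
  modifier_model(mu_x = 1, rho0 = 0.15, rho1 = 0.10),
  beta = c(1, 0.2, 0.3, 0.1), test = "hte", reps = 500, seed = 731
)
oc$power
#> [1] 0.802   # analytic prediction at n_c = 42: 0.806
```

`builtin_scenarios()` ships the canonical 24-scenario HTE and ATE grids
plus both worked examples; `run_report()` turns any subset into a table of
solved sizes, predicted power, and (optionally) empirical size/power;
`power_contour()` + `plot_power_contour()` draw ICC sensitivity maps.

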