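---
title: "Multiple-imputation score tests for interval-censored data with an intermediate event"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-imputation score tests for interval-censored data with an intermediate event}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icie)
```

## The problem

In trials where subjects can experience an *intermediate clinical event*
(IE) -- a switch to second-line therapy, a transplant -- before the event of
interest, the hazard may change at the IE, and subjects who experience the
IE are a length-biased selection: they must have survived until their
waiting time $W$.  When follow-up happens at scheduled visits, the event
time $T$ is additionally *interval-censored*: it is only known to lie in
$(L, R]$ between the last attended visit before the event and the first one
after it ($R = \infty$ for a right-censored subject).  Naive two-sample
comparisons ignore one or both features: the log-rank test ignores the
hazard change at the IE, and the IE-stratified log-rank test compares the
post-IE strata as if entry into them were unbiased.

`icie` implements non-iterative multiple-imputation (MI) tests for this
setting.  Per subject we observe the group $x \in \{1, 0\}$ (A/B), the
interval $(L, R]$, the event indicator $\delta$, the IE indicator
$Z = I(W \le T)$, and -- exactly -- the waiting time $W$ when $Z = 1$.

## Model and hypotheses

Let $T_0$ and $T_1$ denote the event time conditional on $Z = 0$ and
$Z = 1$, with survival functions $Q_0$, $Q_1$; the IE waiting time $W$ has
survival $G$ and is independent of $T$.  The two groups are compared under
stratum-wise proportional hazards

$$Q_{kA}(t) = Q_{kB}(t)^{\beta_k}, \qquad k = 0, 1,$$

with joint null $H_0: \beta_0 = \beta_1 = 0$ (equality of both the pre- and
post-IE survival distributions).  Importantly the hypothesis does not
involve $G$: a difference in IE *rates* between groups is not a difference
in survival.

### Score statistics

With counting-process notation $z_j(t) = I(W_j \le t)$ (identically 0 when
$Z_j = 0$) and risk indicator $R_j(t) = I(T_j \ge t)$, the post-IE score is

$$\hat S_1 = \sum_{i:\, z_i(t_i) = 1} \left( x_i - p_i \right), \qquad
  p_i = \frac{n_i}{N_i},$$

where $N_i = \sum_j R_j(t_i) z_j(t_i)$ counts the post-IE risk set at event
time $t_i$ and $n_i$ its group-A part, with null variance
$V(\hat S_1) = \sum_i p_i (1 - p_i)$; $\hat S_0$ is the analogue over
pre-IE events with shares $\pi_i = m_i / M_i$ from the pre-IE risk set
$R_j(t)(1 - z_j(t))$.  Each event contributes to exactly one of
$\hat S_0 / \hat S_1$ according to $z$ at its own event time; with $z
\equiv 0$, $\hat S_0$ is exactly the log-rank numerator.  The joint test
refers $\chi^2_2 = \hat S_1^2 / V(\hat S_1) + \hat S_0^2 / V(\hat S_0)$ to
a chi-square with 2 df; the hypothesis is separable, so
$\hat S_k^2 / V(\hat S_k)$ tests $\beta_k = 0$ alone on 1 df
(`chi2_tests()`).

These statistics need exact (or right-censored) times, which
interval-censored data do not provide -- hence imputation.

## The imputation procedures

Both methods first assemble, per IE stratum $k$, the set of candidate mass
points (`build_candidate_sets()`):

* $k = 0$: $\{0\}$, all $L_i, R_i$ of subjects without the IE, all $W_i$ of
  subjects with it (for the pre-IE distribution an IE subject is simply
  right-censored at $W$), and $\infty$;
* $k = 1$: $\{0\}$, all $L_i, R_i, W_i$ of subjects with the IE (the
  truncation point $W$ may itself carry mass), and $\infty$.

One completed data set then sets, for every subject,

* $\delta = 0,\ Z = 0$: censored at $L_i$;
* $Z = 1$ (pre-IE part): censored at $W_i$;
* $\delta = 0,\ Z = 1$ (post-IE part): censored at $L_i$, left-truncated at
  $W_i$;
* $\delta = 1$: an imputed exact time drawn from the stratum's candidate
  points restricted to $(L_i, R_i]$.

The **uniform-weight** method draws uniformly over
$\{s_j : L_i < s_j \le R_i\}$.  The **weighted** method draws
proportionally to the Turnbull NPMLE mass restricted to the same set
(`conditional_mass()`).  Each of the $M$ completed data sets is scored with
`nam_zelen_score()`, and the $M$ pairs are pooled (`pool_rubin()`):
$\bar S_k$ is the mean score, and with within-variance
$\bar V_k = M^{-1} \sum_r \hat V^{(r)}_k$ and between-variance
$B_k = (M-1)^{-1} \sum_r (S^{(r)}_k - \bar S_k)^2$, two combined forms are
reported:

$$V_1 = \bar V + (1 + 1/M)\, B \quad \text{(additive)}, \qquad
  V_2 = \bar V - B \quad \text{(subtractive)}.$$

The additive form is the classical Rubin combination and mildly
*over*-estimates (conservative test); the subtractive form, designed for
settings with low follow-up loss, mildly *under*-estimates.  The identity
$V_1 - V_2 = (2 + 1/M) B$ is exact and asserted in the test suite.
$M = 10$ by default: the statistics are smooth functionals, and the
between-variance stabilises quickly.

### The NPMLE under left truncation

`turnbull_npmle()` maximises
$\prod_i P(T \in (L_i, R_i]) / P(T > W_i)$ over distributions supported on
the innermost (Turnbull) intervals formed by all observation and truncation
endpoints, via the self-consistency (EM) fixed point with "ghost" mass for
the truncated-out region.  Numerical choices:

* convergence when the largest absolute mass change drops below $10^{-6}$
  (cap 5000 steps, non-convergence flagged, never silent);
* the plain EM step is accelerated with a SQUAREM-style extrapolation; an
  extrapolated iterate is accepted only if it does not decrease the
  likelihood, so the recorded likelihood trace stays monotone and the fixed
  point is the same;
* exact observations are handled by giving the atom $\{t\}$ its own
  (eps-shifted) innermost interval;
* when a point representative of a support interval is needed (imputation),
  mass sits at the interval's right endpoint, consistent with imputing from
  endpoint candidate sets;
* a subject interval carrying zero NPMLE mass falls back to the uniform
  candidate draw (counted and reported in the result); an empty candidate
  subset (an exact observation) imputes $R_i$ itself.

The NPMLE under left truncation is known to be inconsistent at early times;
no correction is applied here -- the estimate is an imputation weight, not
a reported estimator, and the uniform-weight method is the robustness
check: across all simulated scenarios the two methods' size and power are
nearly identical.

### Which data enter the NPMLE weight

The weight for stratum $k = 0$ is estimated from the intervals of subjects
without the IE together with the IE subjects right-censored at $W$; for
$k = 1$ from the IE subjects' intervals with truncation sets $(W, \infty)$.
Estimation is done *within each treatment group*.  This was a genuinely
open design point: a single pooled estimate is also defensible, but
imputation weights are meant to reflect each sample's own distribution, and
pooling demonstrably shrinks the between-group contrast of the pooled
scores (the combined variance then overestimates the true sampling
variance of $\bar S_k$, making the weighted test conservative under the
null and blunting its power).  `impute_weighted()` still accepts explicit
single estimates if pooled weights are wanted.

### Tie and boundary conventions

* $z_j(t)$ is closed at $W$: an event exactly at an IE time counts as
  post-IE, and a subject entering the post-IE risk set exactly at an event
  time is at risk (the indicator $I(W_j \le t)$ taken literally; relevant
  because imputed times and other subjects' $W$ values share the candidate
  grid).
* Risk sets are closed at $t$: $R_j(t) = I(T_j \ge t)$; tied events share
  the same risk-set shares.
* Events with an empty risk denominator contribute nothing; a zero-variance
  component is dropped from the composite statistic with the df reduced and
  a warning (with no IE subjects at all the 2-df test degenerates to the
  1-df pre-IE test).
* A non-positive subtractive variance $V_2$ is replaced by $V_1$ for that
  component and flagged -- this avoids spuriously infinite statistics while
  keeping the additive/subtractive comparison meaningful.

## The data generator

`generate_cohort()` implements the simulation mechanism used for all
calibration claims, per group $g$:

* $W \sim \text{Exp}(\mu_g)$ with $\mu_g = \theta_g \lambda_{0g} / (1 -
  \theta_g)$, so $\theta_g = P(Z = 1) = \mu_g / (\mu_g + \lambda_{0g})$;
* $T_0 \sim \text{Exp}(\lambda_{0g})$; if $W > T_0$ then $T = T_0$,
  $Z = 0$; otherwise $T = T_1$ drawn from the Exp$(1/m_{1g})$ distribution
  left-truncated at $W$ (inversion of the conditional survival);
* $\delta \sim \text{Bernoulli}(1 - c_p)$, independent of $T$;
* visits at $E + k\psi$ with $E \sim U(0, \psi)$, or $E \sim U(W, W +
  \psi)$ for IE subjects (post-IE follow-up starts at the IE, so $W \le
  L$); $\psi = 0.5$; the first visit is always attended, later ones are
  missed independently with probability 0.1 before $t = 1$ and 0.2 after
  ("first year" read as $t < 1$, natural on a time scale with unit mean
  pre-IE survival); visits continue until an attended one exceeds $T$ (no
  cap).  $L$/$R$ are the attended visits bracketing $T$; $R = \infty$ when
  $\delta = 0$.  When no attended visit precedes $T$, $L$ is the start of
  follow-up (0, or $W$ post-IE).

What the generator does *not* emulate about real data: non-exponential
baseline hazards, dependent or administrative censoring, interval-censored
IE times, covariate-driven visit compliance.  Passing tests therefore
demonstrate calibration of the machinery under the stated mechanism, not
robustness to those violations.

## Simulation harness, sizes used, and reproducibility

`run_scenario()` replicates a scenario, applying the MI tests to the
interval data and the log-rank / stratified log-rank comparators to the
*true* times (the comparators get the easier data on purpose: they are
mis-specified, not information-starved), and reports rejection fractions at
$\alpha = 0.05$ (strict `p < 0.05`) with per-cell Monte-Carlo standard
errors.  A root seed spawns one child seed per replication, so rows are
reproducible and single replications can be replayed; within a
replication, imputation draws consume the stream sequentially (all $M$
draws per subject at once), so results for given $M$ are reproducible but
changing $M$ changes the stream.  Replication failures are counted, never
silently dropped; a row with more than 1% failures is flagged invalid.

The package's own calibration checks use 1000 replications per scenario --
the same replication count as the reported tables they are compared to,
giving binomial standard errors of about 0.007 at the null and at most
0.016 near power 0.5 -- with $n$ = 50--200 subjects per group as the
scenario dictates.  Property checks (oracle equality, invariants,
distributional checks) use small fixtures or $10^4$--$10^5$ draws where a
3-standard-error band is asserted.

## Known limitations

* Two groups, binary IE observed exactly; interval-censored $W$ is out of
  scope.
* P-values use the chi-square reference for the pooled statistics; no
  finite-$M$ (F-type) reference is applied, matching the procedure the
  package implements.
* The subtractive variance can be anti-conservative in small samples; the
  additive form is the default recommendation.
* Exponential latencies in the generator; the tests themselves are
  nonparametric.
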