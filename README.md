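# icie

Two-sample tests for **i**nterval-**c**ensored survival data with an
**i**ntermediate clinical **e**vent.

## The problem

In many trials a subject can experience an intermediate clinical event (IE)
— a switch to second-line therapy, a transplant — before the event of
interest, and the hazard may change at the IE.  Subjects who experience the
IE are a length-biased selection: they must have survived until their
waiting time `W`.  On top of that, event times observed at scheduled visits
are interval-censored: `T` is only known to lie in `(L, R]`.  In this
setting the log-rank test (which ignores the IE) and the IE-stratified
log-rank test (which ignores the length bias of the post-IE stratum) can be
badly miscalibrated — empirical sizes above 0.2 and 0.7 respectively in the
package's simulation tables — while tests that use the IE information
properly keep the nominal level and gain power.

`icie` is for biostatisticians analysing such trials and for
methodologists studying these operating characteristics.

## The method

Per subject we observe the group `x ∈ {1, 0}` (A/B), the interval
`(L, R]`, the event indicator `δ`, the IE indicator `Z = I(W ≤ T)`, and the
exact waiting time `W` when `Z = 1`.  The two groups are compared under
stratum-wise proportional hazards

    Q_kA(t) = Q_kB(t)^{β_k},   k = 0 (pre-IE), 1 (post-IE),

with joint null `H0: β0 = β1 = 0`.  With `z_j(t) = I(W_j ≤ t)` and risk
indicator `R_j(t) = I(T_j ≥ t)`, the post-IE score statistic is

    S1 = Σ_{events with z=1} (x_i − p_i),   p_i = n_i / N_i,
    V(S1) = Σ p_i (1 − p_i),

with `N_i` (and its group-A part `n_i`) counting the post-IE risk set at
the event time; `S0` is the analogue over pre-IE events from the risk set
`R_j(t)(1 − z_j(t))`.  The composite statistic
`S1²/V(S1) + S0²/V(S0)` is referred to χ² with 2 df; the hypothesis is
separable, so each `S_k²/V(S_k)` tests `β_k = 0` alone on 1 df.

Because these scores need exact times, interval-censored events are
**multiply imputed** from the stratum-specific candidate mass points inside
each subject's interval — either with uniform weights, or weighted by the
Turnbull NPMLE computed under left truncation within each treatment
group — and the M = 10 replicate scores are pooled with Rubin-style
combinations: additive `V1 = W̄ + (1 + 1/M)B` and subtractive
`V2 = W̄ − B` variance forms.

See the methods vignette (`vignettes/mi-score-tests.Rmd`) for the full
procedure, the data-generating mechanism and the numerical conventions.

## Worked example

A scenario in which only the post-IE mean survival differs between groups
(2 vs 1 time units), with 30% random censoring and 100 subjects per group:

```r
library(icie)
cfg <- scenario_config(theta_A = 0.5, theta_B = 0.5, m1_A = 2, m1_B = 1,
                       c_p = 0.3, n_per_group = 100)
set.seed(11)
coh <- generate_cohort(cfg)
head(coh, 4)
#>   id group     L     R delta Z      W T_true
#> 1  1     A 1.347 2.347     1 1 0.8021  1.670
#> 2  2     A 0.377 0.877     1 0     NA  0.547
#> 3  3     A 0.351 0.851     1 1 0.0212  0.401
#> 4  4     A 0.000 0.486     1 0     NA  0.276

set.seed(1)
mi_test(coh, method = "weighted", M = 10)
#> Multiple-imputation Nam-Zelen test (weighted weights, M = 10)
#>   pooled scores: S0 = 2.6613, S1 = -9.5335
#>   additive    variance: V(S0) = 20.4179, V(S1) = 15.1076, chi2(2 df) = 6.363, p = 0.04153
#>   subtractive variance: V(S0) = 18.1608, V(S1) = 14.5056, chi2(2 df) = 6.656, p = 0.03587
```

The pooled post-IE score `S1 = −9.5` says group B (coded `x = 0`)
accumulated about 9.5 more post-IE events than expected under the null —
the group with the shorter post-IE survival.  The composite test rejects at
the 5% level (p = 0.042 additive, 0.036 subtractive), and the separable
1-df tests localise the difference to the post-IE stratum
(`β1`: p = 0.014; `β0`: p = 0.56).  The comparators on the *true* —
not interval-censored — times miss or mislead:

```r
x <- as.integer(coh$group == "A")
logrank_test(coh$T_true, coh$delta, x)$p          # 0.187
stratified_logrank(coh$T_true, coh$delta, x, coh$Z)$p  # 0.013
```

Simulation rows (empirical size/power over replications) come from
`run_scenario()`, and whole tables from `run_tables()` driven by a YAML
configuration (see `inst/extdata/tables_example.yaml`).  A thin CLI wraps
these: `Rscript inst/cli/icie.R {simulate|test|tables} --help`.

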