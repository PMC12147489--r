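# lcprofile

Latent class profile models (LCPM) with time-dependent covariates, for
multivariate categorical longitudinal data — the kind of panel produced
when patients answer a battery of symptom questions at repeated clinic
visits and the analyst wants to discover both *symptom states* at each
visit and *whole trajectories* of those states across the study.

## The model

For subject *i*, items *m* = 1..M with r<sub>m</sub> categories at
occasions *t* = 1..T, the LCPM posits a latent class C<sub>t</sub> ∈ 1..K
at every occasion and a latent profile U ∈ 1..S indexing class
trajectories:

P(Y<sub>i</sub> | x<sub>i</sub>, z<sub>i</sub>) = Σ<sub>u</sub>
Σ<sub>c<sub>1</sub></sub>…Σ<sub>c<sub>T</sub></sub> γ<sub>u</sub>(x<sub>i</sub>)
∏<sub>t</sub> [ η<sup>(t)</sup><sub>c<sub>t</sub>|u</sub>(z<sub>it</sub>)
∏<sub>m</sub> ρ<sub>m y<sub>imt</sub> | c<sub>t</sub></sub> ]

with multinomial-logit structural parts: profile prevalence
γ<sub>u</sub>(x) = softmax(x′β<sub>u</sub>) driven by baseline covariates,
and — the distinctive feature — class membership given the profile,
η<sup>(t)</sup><sub>c|u</sub>(z) = softmax(z′α<sup>(t)</sup><sub>c|u</sub>),
driven by *time-dependent* covariates. Estimation is maximum likelihood by
an EM algorithm whose E-step runs a forward–backward recursion over the
class sequence (O(T·S·K²) instead of S·K<sup>T</sup>) and whose M-step
combines closed-form updates for ρ (missing-at-random corrected) with
damped Newton–Raphson steps for [β, α]. Standard errors come from the
observed information matrix; model selection uses BIC grids, a parametric
bootstrap G² test of absolute fit, and a likelihood-ratio test of
time-invariant measurement.

## Worked example

```r
library(lcprofile)

# benchmark generating model: K = 2 classes, S = 2 profiles, T = 3,
# four binary items, x_i ~ N(1,1), z_it ~ N(1,1)
sc    <- lcpm_scenario("strong", N = 500)
panel <- generate_panel(sc, seed = 11)

fit <- fit_lcpm(panel$data, sc$spec, lcpm_control(n_starts = 3, seed = 1))
fit
#> LCPM fit
#>   K = 2 classes, S = 2 profiles, T = 3, N = 500
#>   log-likelihood: -2551.9992  (start 2 of 3, converged, 44 iterations)
#>   free parameters: 22   BIC: 5240.72

# align labels to the generating truth, then Wald inference
al  <- align_labels(fit$params, sc$true_params)
inf <- observed_information(al$params, data = panel$data)
wald_intervals(inf)[c(1, 17:20), c("parameter", "estimate", "se", "lower", "upper")]
#>        parameter   estimate         se      lower      upper
#> 1       rho_11|1  0.9197076 0.01002877  0.9000515  0.9393636
#> 17      beta_0|2 -0.8478338 0.17682711 -1.1944086 -0.5012591
#> 18      beta_1|2  1.0842134 0.13527083  0.8190874  1.3493393
#> 19 alpha_02|1(1)  0.9339887 0.27250276  0.3998931  1.4680843
#> 20 alpha_12|1(1)  1.1421599 0.30807647  0.5383411  1.7459787
```

The item-response rows are on the probability scale (true ρ<sub>11|1</sub>
= 0.9), the coefficient rows on the logit scale (true β<sub>|2</sub> =
(−1, 1), true α<sup>(1)</sup><sub>2|1</sub> = (1, log 9 − 1) ≈ (1, 1.197));
every true value sits inside its 95% interval. `select_lcpm()` tabulates
BIC over a (K, S) grid, `bootstrap_gof()` returns the parametric-bootstrap
p-value of the G² deviance, and `run_recovery_study()` /
`run_accuracy_study()` rerun the full simulation studies.

A command-line interface wrapping these functions (subcommands `fit`,
`select`, `boot`, `lrt`, `simulate`, `recover`, `accuracy`) is installed at
`system.file("cli", "lcpm.R", package = "lcprofile")`.

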