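# sealIH

Detecting and characterizing **latent individual heterogeneity in
reproductive rates** from multistate encounter histories, built around the
long-term Erebus Bay Weddell seal (*Leptonychotes weddellii*) study system.

Long-lived vertebrates vary enormously in realized reproductive output.
The hard question is whether that variation reflects persistent latent
differences among individuals (frailty / "fixed heterogeneity") or merely
the stochasticity of yearly breed/skip transitions among identical
individuals ("dynamic heterogeneity"), once state, age, and year effects
are accounted for — and, if latent differences exist, whether harsh
environmental periods amplify their expression. `sealIH` is for population
ecologists and biostatisticians who want to ask those questions of
encounter-history data, or to study the behavior of the method itself with
fully synthetic populations.

## The model

An encounter history runs from a female's first reproduction (state `F`)
to her last sighting — her *minimal lifetime window* — with every later
year either `E` (pup) or `S` (skip). Each within-window transition is a
Bernoulli outcome with

```
logit ψ[kE]_{i,t} = μ + δ_k + γ₁ A_{i,t} + γ₂ A²_{i,t} + η_t + α_i + β_i X_t
```

where `k` is the previous year's state (`δ_F + δ_E + δ_S = 0`), `A` is
standardized age in the outcome year, `η_t ~ N(0, σ_η)` are year effects,
`X_t` flags the perturbed iceberg years (2001–2005), and `α_i ~ N(0, σ_α)`,
`β_i ~ N(0, σ_β)` are latent individual effects. Three nested hypotheses
are compared: **H1** (no individual effects), **H2** (`α_i` only — fixed
heterogeneity), **H3** (`α_i` and `β_i` — environment-dependent
expression). Fitting is Bayesian, via a compiled adaptive
Metropolis-within-Gibbs sampler (cross-checked against JAGS in the test
suite). Model comparison uses **posterior predictive checks** on
trajectory statistics — the SD and maximum, across females with windows of
≥ 5 years, of total reproductive output (RepOutput), `E,E` pair counts
(ConsecRep), and longest breeding run (PersistRep) — rather than
information criteria, and the biological meaning of the estimated
heterogeneity is rendered as projected pup production for hypothetical
frail / average / robust females.

## Worked example

Generate a synthetic population at reference parameters (fixed
heterogeneity truth), fit H2, check it, and project:

```r
library(sealIH)

synth <- sample_population(generator_config(n_individuals = 300), seed = 1)
synth$population
#> <seal_population> 300 females, 2084 individual-year records
#>   study years 1982-2011; iceberg years 2001-2005
#>   age standardization: mean 12.07, sd 4.47

fit <- fit_ih(synth, "H2", burnin = 800, samples = 2000, seed = 1)
derive_state_rates(fit)
#> # A tibble: 3 × 4
#>   from_state  mean lci2.5 uci97.5
#> 1 F          0.454  0.355   0.558
#> 2 E          0.683  0.616   0.744
#> 3 S          0.753  0.685   0.812

back_transform_sd(fit, "alpha")
#> # A tibble: 1 × 4
#>   which  mean lci2.5 uci97.5
#> 1 alpha 0.139  0.100   0.181
```

The skip-to-breed rate (0.75) exceeds the breed-to-breed rate (0.68): with
individual quality in the model, breeding this year *costs* next year's
breeding probability. The probability-scale heterogeneity SD (0.139,
CI excluding zero) recovers the generating value 0.15. The posterior
predictive check of the matched model is calibrated (mid-range p-values):

```r
run_ppc(fit, n_rep = 500, seed = 1)
#>   statistic   summary observed p_value
#> 1 rep_output  sd          2.84   0.39
#> 2 rep_output  max        17      0.43
#> 3 consec_rep  sd          2.53   0.198
#> ...
```

(fitting H1 to the same data instead drives `p_value` for `sd rep_output`
below 0.05 — the model cannot reproduce the observed spread). Finally,
projected 11-year pup production for hypothetical females at ∓2σ_α:

```r
ty <- project_typology(reference_params("H2"), k = 2, n_sim = 5000, seed = 1)
ty
#>   type    offset_logit  mean    sd
#> 1 frail          -1.44  4.41  1.37
#> 2 average         0     7.22  1.39
#> 3 robust          1.44  9.46  1.07
attr(ty, "ratio")
#> [1] 2.15
```

A robust female is expected to produce about twice as many pups as a frail
one over the same 11 years in the same environments.

`run_pipeline()` chains all stages (simulate → fit H1/H2/H3 → PPC →
projection → report) from a config list or YAML file and writes every
stage's artifacts plus a replayable metadata record to a run directory.
`autoplot()` methods draw the PPC histograms, projection distributions,
and the posterior age trend; `plot_alpha_beta()` draws the H3
individual-effect scatter.

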