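# ipmss — integrated population modelling for source–sink diagnosis

`ipmss` asks a deceptively simple question about a focal subpopulation that
looks stable in the counts: is it a genuine **source** (net recruitment, net
emigration), or a **cryptic sink** — mortality exceeding recruitment, with
the books balanced by immigration from elsewhere? The motivating system is a
long-lived migratory goose population wintering at one large focal site (W)
connected to an aggregated pool of other sites (E), but the machinery is
generic for any two-site, two-age-class system with marked individuals and
census counts.

Counts alone cannot answer the question, so the package fits a Bayesian
**integrated population model (IPM)**: a multistate capture–mark–recapture
likelihood (survival φ, movement ψ between W and E, site-specific detection
p, from animals marked as juveniles at W) is combined with a state-space
model of the age-structured census at W,

    N_juv,t+1 ~ Pois(β_t · N_ad,t)
    N_ad,t+1  = Bin(N_juv,t, φ_juv ψ_WW) + Bin(N_ad,t + N_imm,t, φ_ad ψ_WW)
    N_imm,t+1 ~ Pois(ω_t · (N_juv,t + N_ad,t + N_imm,t))

with counts observed as `J_t ~ Pois(N_juv,t)`, `A_t ~ Pois(N_ad,t + N_imm,t)`
(a Gaussian law with estimated σ²_J, σ²_A is available). All rates carry
logit/log-scale random year effects. Because both likelihoods share φ and ψ,
the immigration rate ω — invisible to the marked sample — is identified as
the shortfall between the census and what the CMR rates can sustain.

Post hoc, every posterior draw parameterizes the two-stage projection matrix

    [ 0                      β                    ]
    [ φ_juv(1−ψ_juv,WE)+ω    φ_ad(1−ψ_ad,WE)+ω    ]

whose dominant eigenvalue λ is compared across three scenarios (full, no
immigration ω=0, no migration ψ_WE=ω=0); λ_no_migration < 1 with immigrant
inflow exceeding emigrant outflow is the sink signature. Posterior
correlations among demographic time series (PCRI = N_{t+1}/N_t against
immigration, emigration, survival, recruitment) probe compensation and
density dependence, with identifiability claimed when P(r>0) > 0.975 or
< 0.025.

The MCMC kernel (C++/Rcpp) is a blocked Metropolis-within-Gibbs with
forward-filtering backward-sampling of the latent capture states,
interweaved centered/non-centered hyperparameter updates, and tailored joint
moves for the weakly identified adult/immigrant split. A synthetic-data
generator reproduces the statistical structure of a multi-decade marking and
census programme so that every stage is testable end to end.

## Worked example

```r
library(ipmss)

# a 15-occasion synthetic study: rates drawn around the reported posterior
# means, ~30 juveniles marked per year, Poisson census noise
sim <- simulate_ipm_data(n_years = 14, releases_per_year = 30, seed = 11)
fit <- fit_ipm(sim$histories, sim$census, mcmc_config("desk"), seed = 11)
print(fit)
#> Integrated population model fit
#>   15 census years (1983-1997), 420 capture histories
#>   3 chains x 4000 iterations (burn-in 1000, thin 2): 4500 draws
#>   max R-hat 1.436 (NOT converged)
#>   posterior hyper-means (natural scale):
#>  phi_juv_W   phi_ad_W   phi_ad_E psi_juv_WE  psi_ad_WE  psi_ad_EW        p_W
#>      0.645      0.837      0.687      0.143      0.091      0.132      0.826
#>        p_E       beta      omega
#>      0.662      0.171      0.119
```

The hyper-means land near the generating values (adult survival 0.81,
adult emigration 0.09, recruitment 0.16); the R-hat warning reflects a few
slow latent counts at this deliberately short desk preset — lengthen the
run for final inference. The scenario analysis and verdict:

```r
scenario_lambdas(fit, "full")
#> lambda (full scenario): mean 1.011, 95% CRI 1.001-1.022  [4500 draws]
scenario_lambdas(fit, "no_migration")
#> lambda (no_migration scenario): mean 0.968, 95% CRI 0.935-0.996  [4500 draws]
classify_source_sink(fit)
#> Source-sink verdict: SINK
#>   P(lambda_no_migration < 1) = 0.988 (threshold 0.975)
#>   lambda_no_migration: mean 0.968, 95% CRI 0.935-0.996
#>   mean annual immigrant inflow 638.2 vs emigrant outflow 465.7 (females)
```

With migration the population grows (λ ≈ 1.01); sealed off, it declines
(λ ≈ 0.97, 98.8% posterior mass below 1) while taking in more immigrants
than it exports — a sink kept afloat by its neighbours. The compensation
structure shows up in the posterior correlations:

```r
posterior_correlation(fit, "pcri", "immigration")
#> r(pcri ~ immigration): mean 0.436, mode 0.495, 95% CRI 0.208-0.616, P(r>0) = 1.000 [positive]
```

A command-line pipeline wraps the same functions
(`simulate → fit → project → correlate → report`):

```sh
Rscript inst/cli/ipmss.R report out_dir=run1 n_years=14 releases_per_year=30 seed=11
```

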