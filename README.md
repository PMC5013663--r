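# edgeweb

Quantitative host–parasitoid food webs and apparent competition across
habitat edges.

Host species that share parasitoids are indirectly linked: a rise in one
host's abundance can raise attack rates on the others through the shared
enemy pool (*apparent competition*). `edgeweb` is for community ecologists
who want to test whether that mechanism structures an entire
host–parasitoid assemblage — including across an edge between two habitats
such as plantation and native forest — strongly enough that future
parasitism rates and abundance changes can be *predicted* from food-web
data.

## What it computes

**Dependence index.** From a regional quantitative web of attack counts
`a` (hosts indexed by habitat, so taxon *i* in plantation and in native
forest are distinct nodes), the dependence of host *iA* on host *jB* is

    d[iA,jB] = Σ_k ( a[iA,k] / Σ_l a[iA,l] ) · ( a[jB,k] / Σ_m a[mB',k] )

with `k, l` over parasitoid species and `m` over all hosts in the pooled
habitats: the share of *iA*'s parasitoid pressure that recruits from
*jB*. Rows of parasitized hosts sum to one.

**Expected parasitism rate.** For each focal host at a validation site,
given its attack total at time *t* and every partner's abundance change,

    E_raw[iA] = Σ_jB d[iA,jB] · (attacks[iA,t] / n[jB,t]) · n[jB,t+1]  /  n[iA,t+1]
    E[iA]     = min(E_raw[iA], 1)

which is compared against the observed rate `O = attacks(t+1)/n(t+1)`,
the initial rate `I = attacks(t)/n(t)`, and the abundance change
`dN = n(t+1) − n(t)`, with within- vs cross-habitat decomposition,
intraspecific-exclusion and binary-web variants.

**Validation statistics.** Poisson GLMM BACI test of the experimental
herbivore reduction; binomial GLMM of observed on expected rates with
two-stage AIC selection (random structure, then fixed structure; within 2
AIC points the simpler model wins); Nakagawa–Schielzeth marginal and
conditional R², percent change in variance, Pearson overdispersion
checks; linear models of abundance change; ANOVA with Tukey letters on
`log d` by habitat-pair class.

**Synthetic data.** A generator reproducing the study design (8 training
sites × 7 rounds; 8 blocks × 2 sites × 2 habitats × 2 timesteps with a
plantation-side herbivore reduction at half the sites) with a coupling
parameter `lambda` that sets how much apparent competition the data truly
contain — `1` for full coupling, `0` for none, negative for apparent
mutualism — plus a deterministic expectation mode for machine-precision
round-trip tests.

## Worked example

```r
library(edgeweb)

scen    <- generate_scenario(scenario_config(seed = 42))
metaweb <- build_web(scen$training, dataset = "training")
metaweb
#> <quantweb> 45 hosts x 20 parasitoids (quantitative, habitat-indexed)
#>   total attacks: 377; parasitized hosts: 33

dep    <- dependence_matrix(metaweb)
panels <- site_panels(scen$validation, scen$design)
tab    <- assemble_prediction_table(dep, panels, quiet = TRUE)

baci <- baci_abundance_test(panels)
baci$interaction
#> estimate -0.76, z = -9.1, p = 7.3e-20

fit <- fit_prediction_model(tab, predictors = c("E", "habitat", "treatment"))
fit$selected
#> <fit_report> E [binomial]
#>   AIC 88.75, 2 parameters
#>          term estimate    se statistic        p
#> 1 (Intercept)    -3.24 0.371     -8.74 2.35e-18
#> 2           E     4.28 1.022      4.19 2.77e-05
fit$selected$r2
#>    marginal conditional
#>   0.229       0.229
```

Reading the output: the synthetic community (45 habitat-indexed hosts, 20
parasitoids, 377 regional parasitism events) was generated with full
apparent-competition coupling. The BACI interaction is strongly negative —
the simulated spray reduced treated-plantation caterpillar counts well
beyond the natural decline at control sites. Model selection keeps the
expected parasitism rate as the only fixed effect, with a positive slope
(4.28 on the logit scale, p ≈ 3e-05): hosts predicted to suffer more
apparent competition were indeed parasitized more at the later timestep,
and the expected rate alone explains ~23% of the variation (marginal R²).
With `lambda = 0` the same pipeline returns a null slope at the nominal
false-positive rate.

An end-to-end run that writes all artifacts (metaweb, dependence table,
prediction table, model reports, manifest with digests):

```r
run_pipeline(pipeline_config(out_dir = "run1",
                             simulate = scenario_config(seed = 42)))
```

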