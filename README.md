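# adcea

Markov cohort cost-effectiveness modelling of diagnostic strategies for
Alzheimer's disease (AD), built for health economists evaluating early
diagnosis: a standard cognitive work-up, standard MRI, and MRI enhanced
with a hypothetical amyloid-binding contrast agent capable of detecting
asymptomatic early-stage disease.

Two settings are packaged:

* a **memory-clinic analysis** — 70-year-old patients consulting for mild
  cognitive impairment, tested once, followed for 3 years;
* **screen-and-treat analyses** — systematic screening of the over-60
  population (population-wide or ApoE4 carriers only, with doubled
  incidence), rescreened every 5 years over 15 years, assuming a drug
  effective in early AD.

## The model in brief

A cohort evolves over states (disease stage × care setting × clinical
status) in 6-month cycles; the cycle matrix is the principal square root
of an annual transition matrix composed of stage progression, incident AD,
age-specific and stage-excess mortality, and institutionalization. A
decision tree classifies the cohort at testing events (per-stage
sensitivities, specificity, direct diagnosis at severe stage) and assigns
treatment. Discounted (5%/year) societal costs and QALYs accumulate per
cycle; strategies are ranked by dominance and incremental
cost-effectiveness ratios (ICER = ΔC/ΔE versus the next non-dominated
strategy), with the preferred strategy selected against a
willingness-to-pay λ = 76 171 €/QALY — equivalently, maximal net monetary
benefit `E·λ − C`. The sensitivity suite provides univariate sweeps,
10 000-trial Monte-Carlo probabilistic sensitivity analysis with
triangular priors, cost-effectiveness acceptability curves, and partial
rank correlation coefficients (PRCC) with t-based significance.

Every parameter printed in the source literature is used verbatim; every
unpublished value (the supplementary transition matrix, stage utilities,
care costs, age tables) is a documented stand-in flagged `STAND_IN` in the
provenance map. See `vignettes/methods.Rmd` for what the stand-ins can and
cannot reproduce.

## Worked example

```r
library(adcea)

p <- default_base_case("PRIMARY")     # validated parameter set
s <- scenario_spec("PRIMARY")         # 70-year-olds, 3-year horizon
res <- run_scenario(p, s)             # all three strategies
build_icer_table(res$outcomes)
#>   strategy     cost     qaly    ce      status    icer
#> 1 standard 41738.27 1.829610 22813 ON_FRONTIER
#> 2      mri 42085.01 1.833213 22957 ON_FRONTIER  96 215
#> 3  mri_clp 42532.77 1.834333 23187 ON_FRONTIER 399 898
preferred_strategy(build_icer_table(res$outcomes), wtp = 76171)
#> [1] "standard"
```

Each row gives a strategy's discounted cost (€) and QALYs per person over
the horizon, the average cost-effectiveness ratio (`ce`, €/QALY), the
dominance status, and the ICER versus the preceding frontier strategy.
Here the contrast-enhanced strategy buys its extra 0.0011 QALY at about
400 000 €/QALY — far above the 76 171 €/QALY threshold — so it is not
preferred under the packaged stand-in parameters.

Probabilistic sensitivity analysis and PRCC:

```r
psa <- run_psa(p, s, n = 10000, seed = 1)
head(ceac(psa, wtp_grid = seq(0, 2e5, 2.5e4)))
pr <- prcc(psa$draws, psa$icer)       # e.g. contrast cost +0.67,
pr[order(-abs(pr$prcc)), ]            # test sensitivity -0.83
```

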