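# fructuric

Individual dietary fructose intake estimation and hyperuricemia risk
modelling in R.

## The problem

Whether dietary fructose raises serum uric acid enough to matter for
hyperuricemia (uric acid > 8.4 mg/dL in men, > 7.5 mg/dL in women) is a
question best asked in population survey data — but public one-day dietary
recall files report foods and grams, not fructose.  `fructuric` is for
nutritional epidemiologists who need to (a) estimate each subject's
fructose intake from recall records, (b) build an analysis-ready cohort
with categorical exposure coding, and (c) fit the descriptive and risk
models that such analyses report — with every stage testable against
synthetic data carrying known, planted effects.

## The method in brief

**Intake estimation.** Each recall record is decomposed through a
food-to-commodity composition table; per-commodity fructose content is
resolved directly from a nutrient reference or, when missing, imputed from
a related family commodity *j* as

    f_i = (carb_i / 100) × (fructose_j / carb_j)

Added sugars (beet/cane sugar and molasses, corn sweeteners, honey, maple
syrup, sorghum syrup) are identified by sweetener class.  Corn-sweetener
mass *m* yields unbound fructose `m × Σ s_k φ_k` over components
HFCS-55/HFCS-42/corn syrup with disappearance shares `s_k` and fructose
fractions `φ = (0.55, 0.42, 0)`.  Bound fructose is half the added-sucrose
mass.  Per subject: *all added* = added unbound + added bound, *total* =
all added + natural unbound, with percent energy at 4 kcal/g.  The
non-estimable naturally occurring bound fructose is bounded from
population means: `max(0, total_sugars − added − lactose) × ratio × ½`.

**Risk modelling.** Hyperuricemia is classified by strict sex-specific
cut-offs (CDC > 8.4/> 7.5 mg/dL, legacy > 7/> 6 for sensitivity).
Exposures enter as quartiles (alcohol as 0 / ≤15 / ≤30 / >30 g/d levels);
logistic regression reports odds ratios with Wald 95% limits against the
lowest-intake reference, crude and adjusted for 13 explanatory variables;
uric-acid means are compared by GLM with Dunnett many-to-one contrasts;
goodness of fit is Hosmer–Lemeshow.

## Worked example

```r
library(fructuric)

cfg <- run_config(scenario = scenario_config(n_subjects = 2000, seed = 7))
res <- run_pipeline(cfg)
res
#> Pipeline result: 1829 subjects in analysis cohort
#>   hyperuricemia prevalence: 2.52% (cdc scheme)
#>   exposures modelled: added_unbound_fructose_q, all_added_fructose_q,
#>     total_fructose_q, alcohol_level, fiber_q
```

2,000 subjects were simulated; 171 were excluded (age, disease flags,
unreliable recalls), leaving 1,829 whose prevalence sits near the 2.5%
generator target.  The crude alcohol risk model:

```r
res$risk_results$alcohol_level$unadjusted
#> unadjusted model for exposure 'alcohol_level' (reference level 1)
#>   level   n cases     or ci_low ci_high         p unstable
#> 1     2 174     3 0.8603 0.2583   2.865 8.064e-01    FALSE
#> 2     3 136    11 4.3153 2.0907   8.907 7.663e-05    FALSE
#> 3     4 168     5 1.5042 0.5714   3.960 4.084e-01    FALSE
#> exposure LRT p = 0.00423 ; goodness-of-fit p = 1
```

Each row contrasts an alcohol level against non-drinkers (level 1): at
this sample size the planted effects (true ORs 0.8, 1.7, 1.8) are
recovered only noisily — n = 2,000 with ~46 cases gives wide intervals —
which is exactly why the test suite checks CI *coverage* over 200
replicates at n = 5,000 rather than point estimates.  The cut-off
sensitivity analysis shows the dominance of the lower scheme:

```r
res$sensitivity$prevalence
#>   scheme  rate
#> 1 cdc     2.52
#> 2 legacy 17.2
```

Desk-scale quantities:

```r
natural_bound_underestimate(135.91, 99.86, 14.49, 0.2653)
#> 2.86   # g/day upper bound on missed natural bound fructose
power_two_group(0.025, 2, 0.05, 2346)
#> 0.991  # two-proportion power at 2.5% reference prevalence, OR 2
```

A thin CLI over the same functions ships in `inst/cli/fructuric.R`
(subcommands `simulate`, `estimate`, `prepare`, `analyze`, `report`,
`all`).

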