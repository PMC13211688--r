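# radecol

Statistical workflow for organ-level radioecology of wild mammals sampled as
small cohorts: decay correction and mass-basis bookkeeping, censoring-aware
summaries, relative-to-muscle tissue distribution with permutation inference,
robust Bayesian radionuclide-vs-stable-analogue correlation, and
soil-to-whole-organism concentration ratios.

## Who this is for

Ecotoxicologists and radioecologists working with tissue panels from a
handful of carcasses of protected species — cohorts of 5–10 animals, seven
tissues (muscle, heart, spleen, lungs, liver, kidney, femoral bone), gamma
spectrometry for radionuclides (e.g. ^137^Cs, ^40^K, ^210^Pb) and ICPMS for
stable elements, with some values censored below the decision threshold. At
those sample sizes, classical asymptotics are unreliable; the package leans
on exact permutation enumeration and Bayesian estimation instead.

## The core methods

* **Decay correction**: `A = A0 * 2^(-Δt / T½)` with Δt on a fixed
  365.25-day year; `decay_correct()` applies it to tissue activities and
  soil references alike.
* **Mass basis**: wet-mass value = dry-mass value × `f`, with
  `f = 1 − moisture` per tissue (`moisture_to_factor()`, `to_wet_basis()`).
* **Permutation tests** (`paired_signflip_test()`, `perm_corr_test()`,
  `perm_meandiff_test()`): two-sided, exhaustively enumerated when feasible
  (exact rational p-values), Monte Carlo with the add-one correction
  `(k+1)/(B+1)` otherwise.
* **Robust correlation** (`robust_correlation()`): bivariate Student-t
  likelihood with priors `ρ ~ U(−1,1)`, `ν−1 ~ Exp(mean 29)`,
  `μ ~ N(x̄, 2.5·SD)`, `σ ~ HalfNormal(2.5·SD)`, sampled by component-wise
  adaptive random-walk Metropolis (4 chains × 2000 draws, 1000 tuning steps
  by default) with split-R̂, effective-sample-size and 95% highest-density
  interval summaries. The t likelihood down-weights the single outlier
  animal such cohorts usually contain, without excluding it.
* **Concentration ratios** (`cr_table()`):
  `CR = c_wo (wet mass) / c_soil (dry mass)`, built per animal from a proxy
  tissue (muscle for ^137^Cs; bone × 0.16 for Pb routes), soil references
  decay-corrected to each animal's sampling date.
* **Synthetic cohorts** (`generate_cohort()`): seeded lognormal tissue
  panels with inter-tissue correlation, heavy-tailed analogue pairs,
  an outlier animal and censoring — so the whole chain is testable without
  field data.

## Worked example

```r
library(radecol)
cohort <- generate_cohort(sim_params(seed = 42))

subset(tissue_summary(cohort, "Cs137"), select = -c(unit, basis))
#>   analyte tissue n_detected n_censored    am    sd    gm median    min  max
#> 1   Cs137 muscle          7          0 12.11 14.84  6.37  6.754 1.2946 43.4
#> 2   Cs137  heart          7          0 20.76 28.60 10.25  6.804 2.7070 80.4
#> ...

relative_to_muscle(cohort, "Cs137")
#> Distribution of Cs137 relative to muscle (mean %):
#> muscle  heart spleen  lungs  liver kidney   bone
#>  100.0  278.2   47.4   75.5  125.3  124.5   38.5

cs <- subset(cohort$measurements, analyte == "Cs137" & tissue == "muscle")
st <- subset(cohort$measurements, analyte == "Cs" & tissue == "muscle")
robust_correlation(log(cs$value), log(st$value),
                   mcmc_settings(n_chains = 4, n_draws = 2000,
                                 n_tune = 1000, seed = 7))
#>   n rho_mean hdi_low hdi_high rhat_max ess_min n_effective_draws
#> 1 7    0.563  -0.019    0.963        1    2929              8000

cr_table(cohort, c("Cs137", "Pb"), transfer_config(), default_soil_table())
#>   analyte proxy_tissue n      am     sd      gm     min    max soil_value_used
#> 1   Cs137       muscle 7 0.02492 0.0309 0.01303 0.00253 0.0902             122
#> 2      Pb         bone 7 0.00571 0.0048 0.00414 0.00087 0.0151           65000
```

Reading the output: the summary table is the conventional AM ± SD / GM /
median / range layout per tissue on a dry-mass basis. The relative
distribution is the mean over animals of each tissue's percentage of that
animal's own muscle value. The robust correlation row says that with seven
animals the muscle ^137^Cs–Cs association is estimated at ρ ≈ 0.56 but the
95% HDI (−0.02, 0.96) is wide — exactly the honest uncertainty statement
such a cohort supports — with both convergence diagnostics
(R̂ ≤ 1.01, ESS ≫ 400) satisfied. The CR rows are dimensionless
soil-to-whole-organism transfer ratios; the `soil_value_used` for ^137^Cs
(≈122 Bq/kg) is the mean of the two literature soil entries after decay
correction to the animals' sampling dates.

`run_pipeline(run_config(...))` chains every stage (summaries, relative +
sign-flip tests, Spearman matrices, robust correlations, CRs, threshold
screening) into a directory of seed-stamped CSVs with a log and a JSON
manifest; two runs with the same configuration are byte-identical.

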