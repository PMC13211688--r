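---
title: "Methods: tissue distribution, robust analogue correlation and transfer parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue distribution, robust analogue correlation and transfer parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radecol)
```

## The scientific problem

Organ-level radioecology of protected carnivores works with very small
cohorts — a handful of carcasses collected opportunistically over several
years — in which each animal contributes paired measurements across seven
tissues (muscle, heart, spleen, lungs, liver, kidney, femoral bone).
Radionuclides such as ^137^Cs (half-life 30.0 y) and ^210^Pb (22.2 y) are
measured by gamma-ray spectrometry together with a panel of stable elements,
some of which fall below the decision threshold and are only known as "less
than" values. The questions such a dataset can answer are correspondingly
modest but specific:

* how an analyte distributes across tissues relative to muscle;
* whether a radionuclide tracks its stable chemical analogue (Cs for
  ^137^Cs, K for ^40^K, Pb for ^210^Pb) well enough that stable-element
  surveys could stand in for radionuclide data;
* what soil-to-whole-organism concentration ratios (CR~wo-soil~) the cohort
  implies, for use in radiological assessment frameworks.

radecol implements this chain end to end, with a seeded synthetic cohort
generator so that every stage is testable without animal data.

## Physical bookkeeping

Decay correction uses $A = A_0 \cdot 2^{-\Delta t / T_{1/2}}$ with
$\Delta t$ in years on a fixed 365.25-day year. The calendar-exact
alternative differs by under 0.1% over the relevant time spans and
complicates reproducibility, so the fixed year is used throughout, for
tissue activities and soil references alike. Negative $\Delta t$
back-corrects with the same formula, which makes the round trip an exact
inverse — a property the tests check to machine precision.

Mass-basis conversion is linear bookkeeping: a dry-mass concentration times
the tissue's dry-matter fraction $f = 1 - \text{moisture}$ gives the
wet-mass value. Measured moistures give muscle $f = 0.25$, heart 0.24,
lungs 0.23 and liver 0.30. No measured moisture is available for spleen or
kidney; the packaged defaults (0.23 and 0.25) are configuration
placeholders chosen near the soft-tissue range, clearly flagged in the
documentation, and should be replaced when study-specific values exist.
Bone uses a conventional dry-to-wet mass ratio of 0.8 rather than a
measured moisture. Censored values pass through conversions exactly like
detections, flag intact: basis conversion is unit bookkeeping, not
inference.

## Censoring policy and summaries

Below-threshold measurements are stored as the reporting threshold with
`censored = TRUE`. All descriptive statistics (arithmetic mean, sample SD,
geometric mean, median, range) use detected values only and report the
censored count alongside. Complete-case exclusion was chosen over LOD/2
substitution as the primary policy because substitution invents a number
where only a bound is known; `relative_to_muscle()` exposes
`censoring = "half_lod"` as an explicit alternative for sensitivity
analysis. The geometric mean is `exp(mean(log(x)))` over detections and is
undefined (an error, not a silent `NA`) for nonpositive values. The median
of an even count is the midpoint of the two central order statistics.

## Relative-to-muscle distribution

Tissue profiles are expressed per animal: each tissue's value as a
percentage of that same animal's muscle value, then averaged across
animals. The alternative — the ratio of tissue means — was rejected
because the paired sign-flip test of relative radionuclide versus relative
stable-analogue distribution needs per-animal paired values, and because a
ratio of means is dominated by whichever animal happens to be most
contaminated. Both conventions can be computed from the returned per-animal
matrix; the mean of per-animal ratios is primary.

## Permutation inference

With 5–10 animals, exact enumeration of a permutation null is cheaper and
cleaner than asymptotics, so each test enumerates the complete null set
whenever feasible — all $2^n$ sign patterns for the paired sign-flip test
($2^n \le 2^{20}$), all $n!$ orderings for the correlation test
($n! \le 10^6$), all $\binom{n}{n_a}$ label assignments for the
difference-in-means test — and reports `method = "exhaustive"` with an
exact rational p-value. The identity arrangement is part of the null set,
and ties between a permuted and the observed statistic count toward the
numerator (conservative). When enumeration is infeasible or the caller
forces it, Monte-Carlo sampling with $B$ permutations (default 10,000)
uses the add-one correction $p = (k+1)/(B+1)$, which cannot return zero.
Exhaustive p-values carry no such correction — exact enumeration stays
exact.

## The robust analogue correlation model

The association between a radionuclide and its stable analogue is
estimated with a bivariate Student-t likelihood,

$$ (x_i, y_i) \sim t_\nu\!\left(\mu, \; \Sigma = \mathrm{diag}(\sigma)
\begin{pmatrix} 1 & \rho \\ \rho & 1 \end{pmatrix}
\mathrm{diag}(\sigma)\right), $$

with weakly informative priors determined by the sample moments:
$\rho \sim \mathrm{Uniform}(-1, 1)$, $\nu - 1 \sim$ Exponential with mean
29, $\mu_j \sim N(\bar{x}_j,\, 2.5\,s_j)$ and $\sigma_j \sim$
HalfNormal$(2.5\,s_j)$. The t likelihood estimates its own tail weight, so
a single discordant animal widens the tails instead of dragging $\rho$ —
the cohorts this package targets typically contain one biologically
plausible outlier that must be retained, and no outlier-rejection option is
offered. Sample moments entering the priors use detected values only,
consistent with the censoring policy; pairs with a missing member are
dropped listwise.

### Sampler

The posterior is explored by component-wise adaptive random-walk Metropolis
on transformed parameters (raw $\mu$, $\log \sigma$, $\mathrm{atanh}\,\rho$,
$\log(\nu - 1)$), with the log-Jacobian added so the chain targets the
stated priors on the natural scale. A gradient-based sampler would also
work, but with six parameters and a cheap likelihood the random-walk
sampler meets the convergence bar without a derivative engine; adequacy is
defined by the diagnostics, not the sampler brand. Proposal scales adapt in
batches of 50 iterations toward the component-wise optimum acceptance rate
of 0.44, and adaptation stops when tuning ends, so the recorded chain is a
valid Markov chain. Each recorded draw is preceded by five full component
sweeps, a cheap way to decorrelate consecutive draws; with the default
4 chains × 2000 draws (1000 tuning steps) this yields split-$\hat R$
comfortably below 1.01 and effective sample sizes in the thousands on
cohort-scale data. Chain $c$ is seeded `seed + c`, with per-chain jittered
starting values around the sample moments.

### Diagnostics and summaries

* **Split-$\hat R$**: each chain is halved and the Gelman–Rubin
  between/within variance ratio is computed over the half-sequences;
  values below 1.01 are taken as converged. Degenerate inputs (e.g.
  copied chains) are reported exactly as computed, with no clamping at 1.
* **ESS**: per chain, Geyer's initial-positive-sequence estimate from the
  autocorrelation function, summed across chains. Constant chains carry no
  information and return `NA`.
* **HDI**: the shortest contiguous interval over the sorted draws
  containing $\lceil 0.95\,n \rceil$ draws — the highest-density interval,
  not the equal-tailed interval, which matters for the skewed $\rho$
  posteriors these small cohorts produce.

The reported `rhat_max` and `ess_min` are the worst cases over all six
parameters, so a single poorly mixing scale parameter cannot hide behind a
well-mixed correlation.

## Transfer parameters

Whole-organism concentrations are built from a proxy tissue per analyte
(muscle for ^137^Cs, Ca, Cd and Cu; bone for Mn; liver for Zn), converted
to wet mass with the tissue factor. Pb routed through bone — both ^210^Pb
and stable Pb — instead multiplies the dry bone value by 0.16, a published
bone-to-whole-organism factor that already embeds the 0.8 bone mass ratio.

$$ \mathrm{CR_{wo\text{-}soil}} = \frac{c_\mathrm{wo}\ \text{(wet mass)}}
{c_\mathrm{soil}\ \text{(dry mass)}} $$

CRs are computed per animal first and summarised afterwards (AM ± SD, GM,
range); summarising first would make the reported ranges impossible. For
radionuclides the soil reference is the arithmetic mean of the available
literature entries, each decay-corrected from its own reference date to the
individual animal's sampling date *before* averaging, since entries may
stem from surveys of different vintage. The two packaged soil ^137^Cs
entries (109 and 141 Bq/kg) are literature values whose reference dates are
not published; the packaged defaults assume mid-survey dates (2013-07-01,
2016-07-01). Because both entries decay at the same rate, shifting either
assumed date by a year changes the corrected mean by only ~2.3%, well
inside the cohort's between-animal spread; users with better provenance
should set the dates explicitly. All other soil values in the packaged
table are synthetic placeholders (labelled as such) — real soil
concentrations are site-specific inputs. `cr_table()` refuses mismatched
numerator/denominator units rather than converting silently.

## The synthetic cohort generator

`generate_cohort()` emulates the features of real tissue-distribution data
that the analysis chain relies on:

* **Log-normal marginals** with analyte- and tissue-specific medians.
  Default medians are set to realistic values for a temperate-forest
  carnivore cohort (muscle ^137^Cs median 6.49 Bq/kg dm, etc.); default
  log-scale SDs are chosen for test power rather than biological fidelity,
  since per-tissue variance components are rarely published.
* **Inter-tissue correlation** via an equicorrelated (default 0.7) or
  user-supplied positive-definite correlation matrix on the log scale.
* **Heavy-tailed analogue pairs**: a radionuclide and its stable analogue
  are coupled within each tissue at correlation `analogue_rho` (default
  0.8) and divided by one shared per-animal $\sqrt{\chi^2_\nu / \nu}$
  mixing variable (default $\nu = 5$). Sharing the mixing variable across
  tissues and pair members makes every margin Student-t while leaving both
  the pair correlation and the inter-tissue correlation exactly at their
  nominal values — Pearson correlation is invariant under a common scale
  mixture.
* **One outlier animal** (default index 4, multiplier 5) whose values are
  inflated but retained, mirroring the one-hot-animal pattern these
  cohorts show.
* **Censoring**: values below a per-analyte threshold are replaced by the
  threshold and flagged.

Draws come from named substreams derived from the master seed, one per
analyte block, so adding an analyte never perturbs the draws of another.
What the generator does *not* emulate: spatial structure in exposure,
age/sex effects, diet-driven regional differences, or measurement
uncertainty correlated across analytes. Passing tests on synthetic cohorts
therefore demonstrates correctness of the statistical machinery under the
stated model, not biological realism of any particular dataset.

## Numerical choices and degenerate inputs

* Permutation tie counting uses a relative tolerance of $10^{-12}$ when
  comparing permuted to observed statistics, so floating-point noise cannot
  flip an exact tie.
* `log_posterior()` returns $-\infty$ for invalid parameters instead of
  raising, which is what a Metropolis accept/reject step needs.
* Zero-variance data are refused before sampling; a constant vector has no
  correlation to estimate.
* Spearman entries with fewer than three complete pairs are `NA`, never 0 —
  absence of evidence is not a zero correlation.
* The BCI regresses mass on length (mass is the response in the
  residual-index method); the OLS fit requires three reference points and
  nonzero length variance, and animals missing either biometric get a
  missing BCI rather than an imputed one.

## Problem sizes used in the test suite

The suite exercises the generator at $n = 10{,}000$ animals for empirical
correlation and censoring-rate checks, the bivariate-t sampler at
$n = 50{,}000$ draws for moment checks, the permutation tests over 50
random fixtures ($n \le 12$) against exhaustive enumeration plus 200
null replicates per test for type-I calibration, and the MCMC at the
default 4 × 2000 settings for one recovery run plus 50 lighter
(2 × 1000) replicates for HDI coverage. These sizes give Monte-Carlo noise
comfortably below each check's tolerance while keeping a full run of the
suite in the low minutes.

## Known limitations

* The robust correlation model is strictly bivariate; no multivariate
  extension, model comparison, or posterior predictive checking is
  provided.
* No multiple-testing correction is applied across tissues, matching the
  exploratory, per-tissue reporting convention of the field.
* Threshold screening compares ranges against literature constants; it is
  a screening layout, not a dose or risk model.
* The packaged BCI can only be computed against a user-supplied (or the
  cohort's own) reference population; published reference regressions for
  wild populations are generally not available as data.
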