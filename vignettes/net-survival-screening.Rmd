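---
title: "Net survival for screening-eligible cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net survival for screening-eligible cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the estimators and corrections it implements, the assumptions they rest
on, every tunable parameter with its default and the reason for it, what
the synthetic-data generator does and does not emulate, and the
numerical conventions that a reader reproducing or auditing results will
want to know. Nothing empirical is claimed here that the package's test
suite does not itself compute.

## 1. Net survival and the weighted estimator

Net survival is the survival a cohort would experience if the cancer
were the only cause of death. With individual death and at-risk
processes $N_i(t)$, $Y_i(t)$, expected (population) survival
$S_{Pi}(t)$ and expected hazard $\lambda_{Pi}(t)$ taken from a life
table matched to the patient's stratum, the inverse-weighted cumulative
excess hazard accumulates an observed part at each death time and a
continuous population part,

$$
d\hat\Lambda_O(t) = \frac{\sum_i w_i(t)\, dN_i(t)}{\sum_i w_i(t) Y_i(t)},
\qquad
d\hat\Lambda_P(t) = \frac{\sum_i w_i(t) Y_i(t) \lambda_{Pi}(t)\,dt}
                         {\sum_i w_i(t) Y_i(t)},
\qquad w_i(t) = 1/S_{Pi}(t).
$$

`pohar_perme()` reports net survival as the product-integral

$$
\widehat{NS}(t) = \prod_{s \le t}\bigl(1 - d\hat\Lambda_O(s)\bigr)
                  \times \exp\bigl(+\hat\Lambda_P(t)\bigr),
$$

and stores the cumulative excess hazard as $-\log \widehat{NS}(t)$, so
the identity $NS = \exp(-\Lambda_E)$ holds exactly. The product form of
the discrete part (rather than $\exp(-\sum d\hat\Lambda_O)$) was chosen
deliberately: under a zero-mortality life table all weights are 1, the
population part vanishes, and the estimator collapses *exactly* — to
machine precision, which the test suite asserts at $10^{-12}$ — to the
Kaplan–Meier product-limit estimator. The additive form would differ
from Kaplan–Meier at second order in each increment. The two forms are
asymptotically equivalent; the product form is the one with the exact
classical reduction.

Consequences worth knowing:

* Net survival may exceed 1 (a group with fewer deaths than its
  background mortality predicts has negative excess hazard), and
  confidence limits may exceed 100%; that reads as "not significantly
  different from background mortality".
* Variance is the weighted counting-process estimator
  $\sum_i w_i^2\, dN_i / (\sum_i w_i Y_i)^2$, accumulated over death
  times. Confidence limits are formed as
  $\Lambda_E \pm z\,\mathrm{SE}$ and exponentiated — symmetric on the
  hazard scale, where the estimator is closest to normal.
* Ties: deaths at a time point are processed before censorings at the
  same time (the standard counting-process convention).
* Events recorded on the day of diagnosis are kept at half a day of
  follow-up rather than dropped.

### Numerical integration

The population term is integrated exactly between consecutive
breakpoints: every follow-up time, every whole-year boundary (where the
annual hazard changes) and any requested grid point is a breakpoint,
and extra points cap the step at `max_step` (default 1/12 year). On
each interval the numerator $\int \sum_i w_i Y_i \lambda_{Pi}\,ds$ has
the closed form $\sum_i [S_{Pi}(a)^{-1}e^{\lambda_i (b-a)} -
S_{Pi}(a)^{-1}]$; the slowly varying denominator is evaluated at the
interval midpoint, leaving an error of third order in the step. The
accumulation loop is in C++ (the usual practice for counting-process
estimators), which keeps a 10,000-patient estimate under a second.

## 2. Life tables

`life_table()` stores annual death probabilities $q$ by single year of
age, calendar year, and optionally ethnicity group × deprivation group.
Net survival is only as unbiased as the life table is specific: if
ethnic-minority or deprived groups have different background mortality
and a general-population table is used, the difference is misattributed
to the cancer.

**Calendar interpolation.** Stratified tables are typically anchored to
a census year (2001). `interpolate_life_tables()` carries them across
years by proportional scaling *on the hazard scale*:
$h_s(\mathrm{age}, y) = h_s(\mathrm{age}, 2001)\,
h_{nat}(\mathrm{age}, y)/h_{nat}(\mathrm{age}, 2001)$, then
$q = 1 - e^{-h}$. Hazards, not probabilities, because hazards compose
multiplicatively under $\exp(-\int\lambda)$ and proportional scaling is
the standard demographic assumption. The base year is returned exactly
(bit-identical), and years *before* the base year use the same ratio
construction — an explicit choice, since backward extension could also
have been done by freezing the base year.

**Path convention.** A patient's expected hazard on $[k-1, k)$ years
since diagnosis is the table value at attained age
$\mathrm{age}_{dx} + k - 1$ and calendar year
$\mathrm{year}_{dx} + k - 1$: age and calendar year advance together at
whole-year offsets from diagnosis. Registry schemas carry completed age
and dates but not birth dates, so the exact birthday convention is
unknowable; advancing both clocks at diagnosis anniversaries keeps each
patient's hazard path piecewise constant on unit intervals, which the
estimator and the simulator then share. Ages beyond the table use the
terminal band; years outside it are clamped to the nearest tabulated
year.

## 3. Lead-time correction

**Model.** The preclinical screen-detectable phase (sojourn time) is
exponential with mean `mst` (default 4 years, the standard estimate for
women 50–70). By memorylessness the lead time $L$ of a screen-detected
tumour is also exponential with mean `mst`. Given an observed survival
time $t$, two closed-form expectations for the lead time are provided
(`leadtime_config(variant=)`):

* `conditional_truncated` (default):
  $E[L \mid L \le t] = \mathrm{mst} - t e^{-t/\mathrm{mst}} /
  (1 - e^{-t/\mathrm{mst}})$ — the mean lead time among women whose
  lead time cannot have exceeded the time they were observed to
  survive;
* `expected_min`: $E[\min(L, t)] = \mathrm{mst}(1 - e^{-t/\mathrm{mst}})$.

Both are 0 at $t = 0$, strictly increasing in $t$ and `mst`, bounded by
`mst`, and validated in the suite against a $10^7$-draw Monte-Carlo
oracle (stratified uniforms through the exponential quantile function,
so the oracle's own error is negligible next to the 3-decimal
comparison). The conditional form is the default because the
correction's target is the lead time actually experienced, which is
necessarily at most the observed survival.

**Imputation.** For each of `m = 10` datasets, a lead time
$s_{ij} \sim \mathrm{Exp}(\mathrm{mean} = E_{s,i})$ is drawn
independently per screen-detected woman and dataset, subtracted from
her observed time, and floored at `epsilon` (one day) rather than
re-drawn — re-drawing would couple the datasets. Non-screen-detected
women are untouched.

**Time origin of corrected data** (a choice this package makes
explicitly): each corrected dataset is re-indexed at the *predicted
symptomatic diagnosis* — the diagnosis date and age at diagnosis are
advanced by the drawn lead time along with the shortened survival time.
The justification is quantitative: the corrected clock starts roughly
$L$ years after screen detection, and if the expected-mortality path is
left anchored at the screen-detection age, the background hazard is
evaluated systematically too young (about 2.8 years at the defaults,
where the hazard grows ~9% per year of age). In generator experiments
subtracting the *true* lead times, that misalignment alone biased
5-year net survival about 1.3 points low; re-indexing removes it.

**Over-diagnosis.** A screen-detected tumour is excluded when its
expected lead time exceeds the woman's observed survival in either
operational sense: the predicted symptomatic diagnosis date falls after
the accrual window closes, or the expected lead time exceeds her
life-table remaining life expectancy at diagnosis (computed in her own
stratum, for consistency with the weighting). The exclusion set is
monotone in `mst`. Non-screen-detected women are never excluded.

**Pooling.** Per grid time, the `m` cumulative excess hazards and their
variances are combined by Rubin's rules ($\bar Q$, within $\bar W$,
between $B$, total $T = \bar W + (1 + 1/m)B$, degrees of freedom
$\nu = (m-1)(1 + \bar W/((1+1/m)B))^2$, infinite when $B = 0$) and
transformed back. Pooling is done on the cumulative-hazard scale
because Rubin's rules assume approximate normality, which holds there
better than on the bounded survival scale; the scale is a documented
choice, not an observable of the original analysis.

**Known limitation — residual bias under the null.** The suite's
bias-removal experiment (null-benefit generator, 5,000 screen-detected
women, 20 replicates) finds the uncorrected 5-year net survival about 6
points above truth and the corrected estimate within about 0.4 points
of truth — a large but not complete removal, and the residual is
statistically resolvable at that replication (about 4.4 Monte-Carlo
standard errors, where the suite's property demands 3). The mechanism
is identifiable in oracle experiments: women whose background death
falls inside the lead-time window have corrected times at or below
zero and are floored to day-one events, creating spurious early excess
deaths (~1.5% of the cohort at the defaults); this is partly offset by
the conditional expectation using the sojourn rate where the posterior
rate given death would be slightly smaller. Both behaviours follow from
the stated correction rules (floor-don't-redraw; closed-form
conditional mean), so the property is reported honestly as failed
rather than the rules being bent to pass it. Users comparing
screen-detected with symptomatic groups should treat corrected
estimates as possibly a few tenths of a point conservative (low).

## 4. Smoothing

`smooth_curve()` applies a tricube-weighted local *linear* fit at each
grid point (classic LOWESS with no robustness iterations, delegated to
`stats::lowess`). Defaults: `span = 0.5` — a deliberately conservative
window, chosen because net-survival curves for small strata are noisy
and heavier smoothing manufactures spurious stability; the span is a
package default, not an estimate from the source analysis, which stated
only that smoothing was conservative. `min_points = 5`: shorter curves
are returned bit-identical and flagged unsmoothed, since with fewer
points than that a local fit shows nothing the raw points do not.
Local linear fits reproduce constants and straight lines exactly, which
the suite asserts. Corrected (lead-time-adjusted) curves are never
smoothed unless explicitly overridden: the corrected comparisons have
few informative points and smoothing would hide their variability.
Smoothing never alters the grid, and no confidence bands are produced
for smoothed values.

## 5. The synthetic world

`simulate_cohort()` generates the world the analysis assumes, with
known truth:

* **Demographics**: ethnic mix 2.9% / 0.9% / 96.2% (Asian/Black/White),
  deprivation-quintile mix per ethnicity, age and diagnosis-period
  mixes — all defaulted to the registry cohort margins the package's
  descriptive fixture also encodes, so descriptive output looks like
  real registry output.
* **Screening**: invitations every 3 years from age 50 (not before the
  programme start in April 1989), each attended independently with
  probability 0.75 (typical programme uptake); sojourn time exponential
  with mean 4 years; a woman is screen-detected at the first attended
  invitation inside her preclinical window, and her recorded diagnosis
  advances by the true lead time. Interval / lapsed / never-attended
  categories follow from the invitation-attendance history;
  2.8% of non-screen-detected histories are marked unresolvable.
* **Survival**: the excess (cancer) hazard is constant per deprivation
  group — defaults 0.0211 and 0.0285 per year, calibrated so true
  5-year net survival is 90.0% and 86.7% — and its clock starts at
  *symptomatic* diagnosis, so under the default `benefit_hr = 1` screen
  detection confers pure lead time (the null the correction must
  recover); a real benefit can be switched on. Background death is
  drawn by inversion from the woman's own life-table hazard path;
  follow-up is censored at 31 July 2012. A few percent of records are
  flagged recurrent or in situ so the eligibility filter has real work
  to do.

What the generator does **not** emulate: tumour growth or stage
progression (extent of disease is drawn from marginal frequencies,
independent of survival), length bias (faster-growing tumours being
less screen-detectable), screening sensitivity below 1 within the
sojourn window, geographic structure, and any dependence of excess
hazard on age or period. A green recovery test therefore establishes
that the estimator chain is correct *under its own assumptions* — not
that those assumptions hold in registry data.

## 6. Other conventions and degenerate inputs

* Survival time is days from diagnosis / 365.25; report tables are on
  the percent scale, rounded to one decimal only when written to CSV.
* Ethnicity with multiple recorded codes resolves by count, then most
  recent date, then case-insensitive alphanumeric order; mixed
  Black/Asian-heritage codes group with the minority, other mixed and
  'other' codes with White. The code dictionary is an editable CSV.
* Screening-status reports pool never-attenders with unresolvable
  histories into one `non_attender_other` column, matching how such
  categories are reported in practice.
* Any analysis stratifying on screening status has the correction
  forced on; requesting it off is an error, because an uncorrected
  screen-detected versus symptomatic comparison is biased by
  construction.
* Empty strata yield `n = 0` rows with no estimates; strata missing
  from a stratified life table are a hard error; an empty risk set
  truncates a curve with a warning; `B = 0` in pooling gives infinite
  degrees of freedom (normal reference).
* All randomness (simulation, imputation draws) is seed-controlled;
  identical seeds give byte-identical cohorts and corrected datasets.
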