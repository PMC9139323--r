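---
title: "Analytical validation statistics with assayval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical validation statistics with assayval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assayval)
```

## Scope

`assayval` implements the statistical core of an analytical validation of a
quantitative in-vitro diagnostic assay — the kind of multi-marker serum assay
used, for example, to estimate glomerular filtration rate (GFR) from NMR-measured
metabolites (creatinine, valine, myo-inositol) together with cystatin C, age
and sex. The package covers six validation stages, each following the
corresponding CLSI guideline family's statistical recipe:

1. **Detection capability** (EP17-style): limit of blank (LoB), limit of
   detection (LoD), limit of quantification (LoQ).
2. **Linearity** (EP6-style): polynomial hierarchy and degree of
   non-linearity over an 11-level intermixture dilution series.
3. **Precision** (EP05-style): nested variance components expressed as CV%,
   single-site (day / run / replicate) and multi-site (site / day /
   replicate).
4. **Trueness**: Passing–Bablok method comparison and spike recovery.
5. **Sample stability** (EP25-style): per-donor drift regression and the
   confidence-band / drift-limit intersection rule.
6. **Interference** (EP07-style): two-stage screen and dose–response.

Raw instrument data for such validations are rarely published, so the package
pairs every stage with a synthetic-experiment generator that reproduces the
standard study designs. The generators are first-class, tested code: they
define the statistical conditions under which the estimators are verified.

## The data model

Every stage consumes one long-format table: one row per individual
measurement, tagged with the design factors it may need (`pool_id`, `site`,
`day`, `run`, `replicate`, `timepoint_days`, `level`, `arm`, `lot`). A
measurement either has a finite nonnegative `value` with `status = "ok"` or
no value with `status = "no_result"` — a lost result, as happens when an
interfering substance suppresses quantification. Lost results are retained,
not dropped, because the acceptance rules of every stage budget missing data
(at most 10% per pool/condition/comparison by default), and "missing" counts
both absent rows relative to the declared design and `no_result` rows.

The CSV dialect is deliberately rigid (UTF-8, comma separator, decimal
point, header row, empty string for absent fields) so tables round-trip
exactly between tools; `write_measurements()` writes values at full
precision.

## Detection capability

With `B` pooled blank results, the parametric LoB is
$\mathrm{LoB} = \bar{x}_B + z_{1-\alpha}\, s_B$ and the nonparametric LoB is
the value at fractional rank $0.5 + B(1-\alpha)$ of the sorted blanks, with
linear interpolation between adjacent order statistics (positions beyond the
largest order statistic are clamped to it). In `auto` mode the nonparametric
path is taken when a Shapiro–Wilk test rejects normality of the pooled
blanks at 0.05; the guidelines leave the distribution check open, and
Shapiro–Wilk is the most powerful omnibus choice at these panel sizes
(≈ 180 blanks in the standard 4-pool × 45-replicate layout).

LoD starts from Cochran's C test on the per-pool variances of the low-level
panels, $C = s^2_{\max} / \sum_i s^2_i$, with the closed-form critical value
$C_{crit} = \left[1 + (k-1)/F_{1-\alpha/k}(\nu, (k-1)\nu)\right]^{-1}$.
When homogeneity is accepted the classical path applies:
$\mathrm{LoD} = \mathrm{LoB} + c_p\, SD_{pooled}$ with
$c_p = z_{1-\beta}\,/\,(1 - \tfrac{1}{4f})$ at $\beta = 0.05$ and
$f = N - k$ total degrees of freedom (the bias-corrected one-sided normal
multiplier; the $f = N - k$ convention matches the pooled-SD denominator).
When homogeneity fails, the nonparametric variant applies: the LoD is the
lowest pool mean at which at least 95% of that pool's results exceed the
LoB — the 95% exceedance constant is $1-\beta$ for the same $\beta = 0.05$.

LoQ is computed per reagent lot as the minimum pool mean whose
within-laboratory CV (day-nested, see below) is below 20%, and the overall
LoQ is the **maximum** over lots — a new lot can therefore only keep or
raise the overall LoQ, never lower it. The three limits must satisfy
LoB ≤ LoD ≤ LoQ; a violated ordering is *flagged*, never silently
reordered, because an inversion is diagnostic of a mis-designed panel.

## Linearity

On an equidistant dilution series (11 levels by default; at least 5 are
required), the package fits the polynomial hierarchy
$y = b_0 + b_1 x$, $y = b_0 + b_1 x + b_2 x^2$,
$y = b_0 + b_1 x + b_2 x^2 + b_3 x^3$ by ordinary least squares over **all
replicate points** and t-tests $b_2$ (order-2 model) and $b_3$ (order-3
model) against zero. If neither is significant at 0.05 the series is linear.
If one is, the best non-linear model — smaller residual standard error, ties
toward the lower order — is compared with the straight line at the assigned
level concentrations, and the degree of non-linearity is
$\max_\ell |\hat{y}_{nl}(x_\ell) - \hat{y}_{lin}(x_\ell)| / |\hat{y}_{lin}(x_\ell)| \times 100$.

The composite verdict requires, over at least five consecutive levels: per
level missing data ≤ 15%, per-level repeatability CV < 15% (denominator:
the level's replicate mean), Pearson *r* ≥ 0.95 on replicate points, and
either no significant non-linear term or a degree of non-linearity < 10%.
Two conventions are worth stating because published reports often leave them
implicit: *r* is computed on replicate points (not level means), and the
degree of non-linearity is evaluated at the assigned level concentrations
(not continuously). The upper limit of the linear range (LoL) is the highest
assigned concentration inside the longest consecutive stretch of passing
levels; it feeds the detection-limit record, which otherwise only knows the
lower end of the range.

## Precision

Variance components are estimated by method-of-moments on the nested ANOVA
mean squares — the guideline's canonical estimator — rather than REML,
because the moment estimator makes the treatment of negative estimates
explicit: a mean-square difference below zero truncates the component to 0
at the variance scale before conversion to CV%, which is why precision
tables can legitimately print an exact 0.0 between-day CV next to a nonzero
repeatability. For the single-site design (day ⊃ run ⊃ replicate):

$$\hat\sigma^2_{rep} = MS_E,\qquad
\hat\sigma^2_{run} = \frac{MS_{run(day)} - MS_E}{n_{rep}},\qquad
\hat\sigma^2_{day} = \frac{MS_{day} - MS_{run(day)}}{n_{rep} n_{run}}$$

with CV% $= 100\,\hat\sigma / \bar{y}$ on the pool's unweighted grand mean,
and within-laboratory CV the root-sum-of-squares of the three components.
The multi-site design (site ⊃ day ⊃ replicate, one run per day) has no run
component; within-laboratory CV combines repeatability and between-day, and
reproducibility additionally folds in the between-site component. For
near-balanced tables (a few lost results) the expected-mean-square
multipliers use average group sizes; all the standard designs are balanced,
where this is exact.

Aggregation always happens on unrounded components and rounding (one
decimal, half away from zero) only at report rendering — aggregating already
rounded components can differ by one unit in the last decimal, which is
exactly the kind of discrepancy that confuses table readers.

## Trueness

Passing–Bablok regression is implemented from its definition: all pairwise
slopes $S_{ij} = (y_j - y_i)/(x_j - x_i)$, $i<j$; slopes equal to $-1$
excluded; equal-$x$/unequal-$y$ pairs contribute signed infinite slopes;
equal-$x$/equal-$y$ pairs contribute nothing; the slope is the median
shifted by $K$, the number of slopes below $-1$ (this shift makes the
estimate invariant to exchanging the two methods), with even counts
averaging the two central order statistics after the shift. The intercept is
$\mathrm{median}(y_i - b\,x_i)$; confidence intervals use the rank-based
normal approximation with $z = 1.96$. The estimator assumes positively
correlated methods, as method-comparison data always are.

Acceptance follows analyte-specific tolerances (defaults: slope within
$1.0 \pm 0.15$ for creatinine and myo-inositol, $1.0 \pm 0.075$ for valine;
$r \ge 0.90$ for all), resolved from a config so other analytes can be
added. Where no reference method exists, `spike_recovery()` evaluates
trueness by known additions: per-pair recovery
$(spiked - mock)/added \times 100$ and a Passing–Bablok fit of observed
spiked results on expected values $mock + added$. Correlations are computed
on the pairs as given; if replicate site measurements exist, averaging them
first is the caller's decision.

## Stability

Per donor and storage condition, the measurand is regressed on storage time
by ordinary least squares over all replicates, with the baseline anchored to
the **mean of the day-0 replicates** (not the regression intercept — the
drift limits are defined relative to what was actually measured at $t_0$).
Drift limits are $\pm 10\%$ of that baseline mean by default. If the slope
is significant (two-sided $p < 0.05$), the stability duration is the
earliest time in $[0, horizon]$ at which the one-sided 95% **pointwise**
confidence bound of the regression mean (upper bound vs upper limit for
positive slopes, lower vs lower for negative) reaches the limit; if the
slope is not significant or the band never reaches the limit within the
tested period, the duration is the study horizon. A pointwise rather than
simultaneous band is the established practice for this rule; a simultaneous
band would be more conservative but is not what validation reports compute.
The crossing is solved by a 1025-point grid scan (the bound need not be
monotone, since the band narrows toward the mean timepoint) followed by
bisection to $10^{-3}$ days. On a noiseless course the band collapses onto
the fitted line and the rule returns the exact line crossing; a perfectly
flat noiseless course has an undefined t-statistic and is treated as
non-significant. The per-condition result is the minimum duration over
donors. The duration object records which branch fired (`non_significant`,
`crossing`, `no_crossing`), so a horizon-valued duration is auditable.

## Interference

The screen compares ten spiked and ten unspiked aliquots of the same pool:
mean relative bias $= (\bar{y}_{test} - \bar{y}_{ctrl})/\bar{y}_{ctrl}
\times 100$, flagged two-sided when $|bias| > 10\%$ — interference can bias
a score in either direction — or when the test arm's no-result fraction
exceeds the 10% missing-data allowance (including a fully lost arm, where
the bias is undefined but the substance clearly interferes). Flagged
substances go to a five-level dose–response (0/25/50/75/100% of the
worst-case spike), evaluated against independent pools from the screen; the
confirmed threshold is the lowest fraction that trips either rule. Both the
tripping fraction and the last non-tripping concentration are reported,
since prose reports usually phrase the threshold as "greater than" the last
safe concentration.

With $n = 10$ per arm and a 3% assay CV, the standard error of the bias is
about $3\sqrt{2/10} \approx 1.3$ points, so the fixed 10% flag threshold
yields a near-zero false-positive rate and essentially full power against a
true 15% bias; the acceptance suite verifies both by simulation. The flag
threshold is a clinical-relevance bound, not a test level.

## The synthetic-experiment generators

All generators share one noise model: multiplicative Gaussian noise on the
CV scale, i.e. effects additive on the relative scale, with hierarchical
effects shared exactly along the design nesting (day within study, run
within day; site above day in multi-site mode). Validation reports quote
only CV%, never distributions, and CV-parameterised Gaussian components map
one-to-one onto the moment estimators being tested. Values are truncated at
zero after noise (concentrations are nonnegative), and truncation events are
counted in an attribute.

Default designs and conditions (each generator's defaults are the standard
layout of its stage):

* precision single-site: 20 days × 2 runs × 3 replicates per pool
  (480 results over 4 pools), CVs 3 / 1.5 / 2% (repeatability / run / day),
  pool means spanning impaired to normal scores (≈ 53–87 mL/min/1.73 m²);
* precision multi-site: 3 sites × 5 days × 1 run × 6 replicates (360 over 4
  pools), with a 2% between-site component;
* detection: 4 blank + 4 low pools × 45 replicates over a crossed 3-lot ×
  3-day grid; Gaussian blanks (mean 10, SD 2 µmol/L) and low pools at
  20–40 µmol/L with 15% CV — chosen so the blank floor sits clearly below
  the low range, as a dialysed-serum blank does;
* linearity: 11 equidistant levels × 3 replicates, 3% CV;
* stability: serum condition at days 0–8, on-board condition at days
  0, 1, 4, 7, 9, 10, with 3–5 replicates and 2% CV;
* interference: 10 aliquots per arm, 3% CV.

Lost results are modelled as per-measurement Bernoulli events without an
attributed cause; real no-result events cluster by mechanism (a failed fit
of one marker's spectral region), so the generator reproduces the *rate*
accounting, not the correlation structure. More generally the generators
emulate the variance structure and design geometry of real studies, not
instrument physics: no spectral overlap, no carry-over, no drift within a
run, and Gaussian tails rather than the occasional gross outlier of real
instruments. Passing tests therefore demonstrate that the estimators are
correct under the designs' assumptions — not that any particular instrument
meets the acceptance thresholds.

A composite power-law score (`surrogate_score()`) stands in for the
proprietary published estimating equation where a marker-to-score mapping is
needed: strictly decreasing in creatinine, myo-inositol, valine and cystatin
C, decreasing in age, with a female sex factor, scaled to 90 mL/min/1.73 m²
at a typical adult serum profile. It is a documented closed form, not an
approximation of the published coefficients.

## Reproducibility and problem sizes

Every generator takes an explicit integer seed and is bit-for-bit
reproducible; `run_study()` derives per-substudy subseeds from one global
seed so each pool/donor/substance stream is independently reproducible. The
test and acceptance suites use desk-scale Monte-Carlo sizes chosen to keep
binomial/standard errors well inside the asserted bands: 500 simulated
studies for variance-component recovery (asserted within ±0.5 CV points),
10,000 fresh blanks for the LoB exceedance rate, 1,000 series for the
linearity false-rejection rate, 1,000 courses for the zero-drift stability
rate, and 2,000 screens per interference operating point. The verification
scripts regenerate everything from code; no measurement data ship with the
package.

## Known limitations

* Unbalanced designs are handled with average-group-size multipliers, which
  is approximate; severely unbalanced tables should be analysed with a
  dedicated mixed-model tool.
* No confidence intervals on variance components are produced (validation
  tables do not report them).
* Passing–Bablok CIs use the large-sample rank approximation; for n < 10
  they are indicative only.
* Only linear drift models are fitted in the stability stage.
* Component CVs inherit the small-sample downward bias of taking the square
  root of an (unbiased) variance estimate; at the standard design sizes the
  mean bias of the smaller components is a few tenths of a CV point, visible
  in the recovery simulations.

## A worked example

```{r example}
rep <- run_study(list(study_kind = "precision_single", seed = 7))
writeLines(render_table(rep, "table2"))
```
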