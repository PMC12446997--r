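---
title: "Model and methods: a distributional cost-effectiveness microsimulation of Medicaid expansion and CVD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model in one paragraph

Two arms are simulated for the same cross-section of nonelderly US adults:
one in which Medicaid-eligible individuals (uninsured, aged 19–64, family
income below 138% FPL) receive Medicaid, and one in which they do not. Each
individual moves through an annual-cycle Markov chain — no CVD or history of
CVD, with possible myocardial infarction (MI), stroke, CVD death and non-CVD
death — until death or age 85. Receiving Medicaid shifts two risk factors
once at entry (systolic blood pressure −3.03 mm Hg; HbA1c −0.14 percentage
points, each with a published 95% CI used for probabilistic analysis), and
changes the economics: recipients' out-of-pocket (OOP) costs fall, their
health-care utilization rises, and the financed increase is spread over
higher-income groups. Outcomes are discounted costs (2021 USD) and QALYs per
person, summarized as incremental net health benefit
`INHB = ΔE − ΔC/λ` and, distributionally, as the incremental Atkinson
equally-distributed-equivalent of health (IEDEH) across income, education
and race/ethnicity subgroups.

## Transition probabilities

Annual MI and stroke risks use a proportional-hazards form on a composite
CVD equation: `rate = −log(S0) · exp(lp − lp_mean)` with per-sex
coefficients on log age, log total and HDL cholesterol, log systolic blood
pressure (treated/untreated), smoking and diabetes. The composite rate is
split into MI and stroke by fixed type shares (defaults 0.50 and 0.35; the
remainder represents other CVD manifestations not modeled as events). The
published sources for this equation do not print coefficient values, so the
package ships *synthetic fixture tables* (`inst/extdata/*_synthetic.csv`),
plausible in structure and magnitude and fully overridable; every test binds
to the fixtures, not to the literature.

Risks are then weighted by the ratio of the individual's hazard under a
pooled-cohort-style sex-by-race equation to that of an age–sex-matched
reference profile (config: SBP 125 untreated, TC 190, HDL 50, nonsmoker,
nondiabetic, "other" race group), including the stratum baseline hazards, so
an individual identical to the reference has weight exactly 1. Published
descriptions of such "weighting" rarely specify mechanics; a multiplicative
hazard ratio was chosen because it preserves the composite equation's event
split while importing the race/SBP/diabetes gradients, and because it
commutes with the history-of-CVD multiplier (×2), which is applied after
weighting. Diabetes is linked to HbA1c by a 6.5% threshold, so the HbA1c
intervention can flip diabetes status.

Fatal-to-total fractions are age–sex logistics (fixture), nondecreasing in
age. Non-CVD death subtracts MI and stroke underlying-cause death rates from
all-cause rates at each (age, sex); the residual rate is converted to a
probability by `1 − exp(−rate)`, as are all rates. Events within a cycle are
resolved by drawing non-CVD death first, then a single categorical draw over
{MI, stroke, no event}: recurrent events across cycles are allowed (the ×2
history multiplier implies they matter), but at most one event per year.
`p_mi + p_stroke` is capped at 0.99 by proportional rescaling with a warning
if it ever binds (it does not, for the packaged fixtures).

## Simulation mechanics

One uniform-draw array of dimension (persons × cycles × 3) is generated per
run from a single seed — slices for non-CVD death, event category, and
fatality. The arm label never enters the seed or the layout, which *is* the
common-random-numbers guarantee: under a null intervention (zero effects,
unit cost multiplier, no preventive/administration cost, unchanged OOP
share) the two arms produce bit-identical results, and the test suite
asserts exactly that. Arithmetic in the recipient cost path is grouped so
that the null case is exact to the last bit, not merely close.

Half-cycle correction is implemented as half-weight accrual of QALYs, annual
costs and person-years in the entry and death cycles (the standard
life-table convention; half-cycle corrections are usually named without the
variant).
Costs and QALYs are discounted at 3%/year to entry; person-years and event
counts are not discounted.

## Economics

Annual health-care cost and SF-6D utility come from linear prediction
equations over demographics, SES strata, CVD history, diabetes, smoking, BMI
and event-cycle flags — again synthetic fixture coefficients standing in for
an unpublished regression. Event years multiply cost by 1.33 and apply an
event utility decrement; utility is clipped to [0, 1], one cycle's utility
is one cycle's QALY contribution before half-cycle weighting.

Productivity costs: a fixed absenteeism/short-term-disability cost in any
event year ($7,043 default), and 100% of average annual earnings ($58,260,
2021) for every year from a premature death (any cause) to the retirement
age of 65. The death year counts in full — the worked-example convention
(death at 63, no discounting → exactly 2 × earnings) — even though the death
cycle's other flows take half weight; the asymmetry is deliberate and
documented here rather than hidden.

The expansion transfer works per cycle, for recipients under 65 (everyone
switches to Medicare at 65 in both arms, after which no new cost differences
arise, though risk-factor effects persist):

* recipient's total cost → `base × multiplier + preventive`, with
  multiplier 2.13 (a reported 113% increase in recipients' total annual
  costs, exposed as config and flagged below), preventive care $320/yr;
* recipient's OOP share drops from the uninsured share (0.40) to the
  Medicaid share (0.05); administration adds $555/enrollee × 0.096
  (CVD-attributable share);
* the financed increase — utilization increase + administration + the OOP
  reduction, i.e. the non-OOP increase — is levied equally per weighted
  person across income groups above 150% FPL, with the levy denominator
  being the half-cycle-weighted alive person-time of those groups in that
  cycle, so that transfer neutrality (weighted attributed costs = weighted
  real resources) holds exactly per cycle and is asserted to 1e-9 relative.

Each person's DCEA-attributed cost is their own total health-care cost plus
productivity losses in both arms (the incidence of baseline costs is assumed
identical across arms, so its attribution cancels in incrementals);
recipients are attributed their baseline non-OOP plus their new OOP, and
levy-payers their own costs plus the levy.

The "low" income band straddles the 150% FPL line; it defaults to the
levy-paying side, a config switch (`income_above_150`). The five-band
fractions are those of the study's reporting table; the bands' dollar
cutpoints are never printed and stay config-level.

## Distributional analysis

Equity metrics operate on per-subgroup mean net health (group-mean
`NHB = QALYs − cost/λ`, weighted by population fractions), matching the
reporting table's structure, not on person-level NHB. The Atkinson EDEH is
`(Σ wᵢ hᵢ^(1−ε))^(1/(1−ε))` (geometric mean at ε = 1); it requires positive
group NHB — on the lifetime QALY scale NHB is strongly positive — and the
package *refuses* nonpositive values rather than silently shifting, with an
explicit `shift` argument for users who accept an affine-shifted index. The
ε grid is {0, 0.5, 1, 1.5, 2, 2.5, 3} with base case 0.5; the break-even ε
at which IEDEH crosses zero is found by bisection on [0, 20] (tolerance
1e-4), reported as "none in range" without a sign change. The
equity-efficiency plane takes λ as a parameter rather than fixing one
threshold for it.

## Uncertainty

PSA distribution families are declared, not hidden: normal for the two
intervention effects with SDs derived from their printed 95% CIs
(`sd = (hi − lo)/(2·1.959964)`), gamma for cost-type parameters, beta for
shares and the utility intercept; every row of `params$psa` is overridable
and zero-SD rows are degenerate (so an all-degenerate PSA reproduces the
deterministic run bit-for-bit, which is tested). Replications resample
individuals with replacement and share all draws across arms. The ±20%
one-way tornado excludes parameters that affect transition probabilities
(the intervention effects); the discount rate is swept. Rubin's rules pool
across imputation replicates; the generator emits complete data, and
`population_imputations()` produces M perturbed replicates purely to
exercise that plumbing — imputation itself is out of scope.

## What the synthetic generator does and does not emulate

It reproduces: the schema, the weighted stratum fractions (largest-remainder
allocation hits targets within ±0.02 at n ≥ 5,000, verified), eligibility
derived from (uninsured, age, income) so the invariant cannot be violated,
correlated risk-factor margins via a Gaussian copula with NHANES-like
correlations, and lognormal survey weights scaled to a weighted population
of 189,980,531.

It does not reproduce: real joint distributions beyond the copula (e.g.
income–risk-factor gradients are not modeled, so synthetic subgroup
*incidence* gradients are flatter than survey reality), survey design
(strata/PSU) variance, or item nonresponse. Passing tests therefore
demonstrate correctness of the machinery and direction of effects, not
replication of survey-based point estimates.

## Known limitations and levers

* The base-case sign of the total INHB is dominated by the recipients'
  utilization multiplier (2.13 on the full annual cost equation); the
  tornado analysis ranks it first by a wide margin. The magnitude of this
  increase — and which cost base it applies to — is the model's main open
  lever, deliberately left in config rather than asserted.
* Cost and risk coefficients are synthetic fixtures; absolute incidence and
  cost levels should be read as internally consistent, not externally valid.
* The uninsured's lower baseline utilization is not modeled (the cost
  equation has no insurance term), which overstates recipients' baseline
  cost and hence the absolute size of the utilization increase.
* Administration costs accrue in the expansion arm only, per enrollee.

## Problem sizes

The analysis scripts use n = 8,141 individuals for deterministic runs and
3 imputations × 25 bootstraps at n = 2,000 for the PSA; the test suite uses
n = 2,000–5,000 for pipeline properties and 20 fixed-seed replications for
the direction-of-effect check. These sizes were chosen so the full workflow
runs in minutes on one core; all replication counts scale by config.
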