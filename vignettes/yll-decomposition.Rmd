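---
title: "Decomposing changes in years of life lost: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing changes in years of life lost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylldecomp)
```

## The model

Years of life lost to premature death are computed per age group as
deaths times the conditional life expectancy at that age, from a single
reference life table:

$$\mathrm{YLL}_{abs,t} = \sum_i D_{it}\,LE_i, \qquad
\mathrm{YLL}_t = \sum_i PW_{it}\,LE_i\,DR_{it},$$

where $D_{it}$ are deaths, $PW_{it} = P_{it}/P_t$ population shares,
$DR_{it} = D_{it}/P_{it}\times 1000$ death rates per 1000, and $LE_i$ the
remaining life expectancy at the bin's start age.  The rate form controls
for population size (per 1000, the scale on which indicators such as the
infant mortality rate are reported) and is algebraically identical to
$\mathrm{YLL}_{abs,t}/P_t \times 1000$ — an identity the test suite checks
to $10^{-9}$ relative tolerance on random inputs.

Two assumptions matter.  First, $LE_i$ is **shared** between the two
instances being compared: a death at a given age is valued the same in
both, so differences in YLL reflect differences in mortality and
demography, never differences in the yardstick.  Second, $LE_i$ is read by
**exact match on the bin start age** with no within-bin placement — the
per-age-group life expectancy is treated as a given constant.  Users whose
life tables are indexed differently (midpoint conventions, single-year
tables) should re-index before loading; `harmonize()` never interpolates.

## The decomposition

The change $\Delta\mathrm{YLL} = \mathrm{YLL}_1 - \mathrm{YLL}_0$ splits
into an age-structure gradient and a death gradient,

$$\Delta\mathrm{YLL}_{age} = \sum_i (PW_{i1}-PW_{i0})\,LE_i\,DR_i^{w},
\qquad
\Delta\mathrm{YLL}_{death} = \sum_i PW_i^{w}\,LE_i\,(DR_{i1}-DR_{i0}),$$

where the superscript $w$ marks the weighting convention: the *partial*
approach holds the **baseline** schedule fixed (Laspeyres-like), the
*total* approach the **comparison** schedule (Paasche-like).  Neither is
privileged; each leaves a residual

$$\mathrm{residual}_{partial} = \sum_i LE_i\,(PW_{i1}-PW_{i0})(DR_{i1}-DR_{i0})
 = -\,\mathrm{residual}_{total},$$

the interaction term that single-weighting index decompositions always
carry.  Because the residuals are exactly antisymmetric, the unweighted
mean of the two approaches — the Fisher-index analogue — is exactly
additive; the package reports it as the *residue-free estimate* and bases
percentage contributions on it.

The death gradient splits further.  With
$r = \sum_i w_i DR_{i1} / \sum_i w_i DR_{i0}$ the ratio of overall
(weight-averaged) death rates,

$$\Delta\mathrm{YLL}_{age\ at\ death} =
   \sum_i w_i LE_i DR_{i1} - r \sum_i w_i LE_i DR_{i0}, \qquad
\Delta\mathrm{YLL}_{death\ rate} = (r - 1) \sum_i w_i LE_i DR_{i0}.$$

The second term of the age-at-death gradient is the burden of a
counterfactual society that reached the comparison's overall death rate by
scaling every baseline age-specific rate uniformly (`adjusted_death_rates()`
returns that schedule; `plot_death_rates()` draws it).  Subtracting it from
the observed comparison burden isolates the effect of *where in the age
range* deaths occur, at a fixed overall rate.  The death-rate gradient is
the complementary uniform-scaling effect.  Both use the **same** ratio $r$,
which makes
$\Delta\mathrm{YLL}_{death} = \Delta\mathrm{YLL}_{age\ at\ death} +
\Delta\mathrm{YLL}_{death\ rate}$ an exact algebraic identity rather than
an approximation.

**Rates, not counts, in the scaling ratio.**  The death-rate gradient is
sometimes written with raw death counts $D_i$ inside the ratio.  The two
second terms of the sub-gradients are only equivalent — and the additive
split above only exact — when the ratio is formed from rates $DR_i$ under
the same weights as everything else.  This package uses $DR_i$ in all four
sub-gradient formulas; with count-based ratios the split acquires a
spurious residual whenever the two instances' population denominators
differ.

**Sign convention.**  Negative gradients mean reduced burden: a negative
death-rate gradient is lower overall mortality, a negative age-at-death
gradient means deaths were delayed to older ages.  Percentages divide by
the *signed* $\Delta\mathrm{YLL}$, so a component opposing the overall
change shows a negative share and the three shares still sum to 100%.

## Degenerate and edge cases

* **Empty age bins** ($P_i = 0$): the death rate and population weight are
  defined as 0, not NaN, so every weighted sum stays finite and the bin
  simply contributes nothing.
* **Deathless baseline** ($\sum w_i DR_{i0} = 0$ with deaths in the
  comparison): no baseline age-at-death pattern exists, so the
  age-at-death gradient is defined as 0, the death-rate gradient carries
  the whole death gradient, and a classed warning is raised.  This mirrors
  the neonatal situation, where the age at death cannot change by
  definition and any change must come through the rate.
* **Zero overall change** ($\Delta\mathrm{YLL} = 0$): percentage
  contributions are undefined; the gradients are reported, the percentage
  fields are `NA`/null, and a flag plus warning record why.
* **Tolerances**: additivity identities are exact in exact arithmetic; in
  floating point the package's tests require $10^{-9}$ relative (or
  $10^{-12}$ absolute on well-scaled quantities).  Reported percentages
  are rounded to two decimals with halves away from zero — the convention
  that matches hand-prepared tables — and unrounded values are always
  carried alongside.

## Harmonization of mismatched schedules

Comparisons are only made bin-by-bin, so two instances on different age
schedules must first be brought onto common bins.  `harmonize()`
aggregates — never disaggregates — and only when one schedule nests in
the other (every boundary of the coarser appears in the finer; anything
else errors).  Counts sum.  Merged life expectancy is the death-weighted
mean of the member bins, weighted by the instance that lives on the finer
schedule (the baseline, when it is the finer one), so that instance's
absolute YLL is conserved exactly through the merge; bins with no deaths
fall back to population weights, then bin widths.  The merged table is an
*effective* life table: its values need not satisfy the raw monotonicity
property of a published table, and it is deliberately exempt from that
check.

## The synthetic generator

`scenario_spec()`/`simulate_pair()` exist so every algebraic property of
the decomposition is testable with known ground truth and no external
data.  The baseline emulates a population in demographic transition: an
exponentially decaying age pyramid (decay 0.03 per year of age over
eighteen 5-year bins — a young, high-fertility structure) and a
bathtub-shaped mortality curve (infant rate 60 per 1000 falling with a
2-year e-folding age, an adult plateau of 0.5, and a Gompertz-like old-age
term $0.05\,e^{0.085\,a}$ that roughly doubles every 8 years).  The
synthetic life table declines linearly at 0.9 years per year of age from
82 at birth, floored at 2 — the slope below 1 enforces the life-table
consistency property by construction.  These defaults were chosen once as
a plausible high-mortality developing-country profile and are not tuned.

Each perturbation pins a known set of gradients to zero *by construction*:

| perturbation | comparison instance | zero by construction |
|---|---|---|
| `none` | identical | everything |
| `age_structure_shift` | pyramid decay reduced by `shift` (ageing), rates kept | death, death-rate, age-at-death, residual |
| `uniform_dr_scale` | every rate multiplied by `scale` | age-structure, age-at-death, residual |
| `death_redistribution` | old-ward multiplicative tilt of rates that conserves the baseline-weighted overall rate exactly | age-structure, residual, death-rate (baseline-weighted) |
| `mixed` | all three combined | nothing |

Deaths are deterministic expected counts (`dr * population / 1000`) by
default because the decomposition identities are algebraic, not
statistical; a Poisson sampling mode exists for realism but is never used
in ground-truth-zero tests.  What passing these tests shows is that the
arithmetic of the decomposition is correct and its invariants hold; what
they do not show is robustness to features of real data the generator
does not emulate — migration, cohort effects, uncertainty in the source
estimates (no confidence intervals are propagated), or cause-specific
mortality structure.

## Numerical and interface choices

* Age bins are half-open `[start, end)` in years; a blank `age_end` marks
  the open-ended last bin, matching abridged life-table conventions.
* CSV files are UTF-8, comma-separated, `.`-decimal; the rates dialect
  carries its total population in a `# total_population:` header comment
  because shares and rates alone cannot reconstruct counts.
* Problem sizes in the shipped checks — 1000 random pairs of 3–18 bins for
  the property sweep, 18-bin synthetic scenarios — are the package's
  choice of a sweep dense enough to catch sign and weighting errors while
  running in well under a minute.
* `decompose_yll(b, a)` relates to `decompose_yll(a, b)` by negating the
  overall change and exchanging the roles of the partial and total
  approaches (with signs flipped); the test suite asserts this swap
  antisymmetry, which is the quickest end-to-end check that the weighting
  conventions are applied consistently.

## Known limitations

Only the mortality component of the disability-adjusted life year is
decomposed; the years-lived-with-disability component would need its own
treatment.  Exactly two instances are compared — multi-period chaining is
out of scope.  The reference life expectancy is global and fixed;
region-specific life tables would change the valuation of deaths, not the
decomposition algebra, but are not provided.  No uncertainty intervals are
produced for the decomposed estimates.
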