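---
title: "Linking generalizability theory to cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking generalizability theory to cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcea)
```

`gcea` joins two analyses that are usually run by different people with
different software: a generalizability analysis of a performance
assessment (where does score variance come from, and how reliable would a
cheaper configuration be?) and a cost-effectiveness analysis (is the
reliability bought by each station, form, rater or site worth its price?).
This vignette documents the statistical model, the conventions the package
commits to, and what its validation does and does not establish.

## The measurement model

A balanced multifacet design is declared by a formula: `"p x t x r"` for a
person-by-task-by-rater crossed design, `"p:s x f x st"` for persons
nested within sites, crossed with forms and stations. The first identifier
is the object of measurement; `:` reads "nested within" and `x` (or `*`)
"crossed with". Scores decompose additively into one zero-mean random
effect per *admissible effect* of the design. Admissible effects are the
ancestrally closed subsets of facets — any effect involving a nested facet
carries that facet's nesting parents in its nesting-index part — so a
fully crossed design with $k+1$ facets has $2^{k+1}-1$ effects, and
`p:s x f x st` has 11 (effects that would be confounded in the balanced
nested layout, such as a pure person main effect separate from
person-within-site, are merged by construction). The unique maximal effect
is the residual.

Every facet is treated as random: the levels actually used (the stations
written, the raters hired) are regarded as a sample from an indefinitely
large universe of admissible levels, which is what licenses projecting to
configurations that were never administered.

## G study: expected-mean-squares estimation

For each effect the package computes the balanced-design sum of squares by
the T-term method (squared cell totals over cell counts, combined by
inclusion–exclusion over contained effects), divides by the classical
degrees of freedom $\prod_{\text{primary}} (n_i - 1) \prod_{\text{nesting}}
n_j$, and solves the expected-mean-squares system

$$E[MS_\alpha] = \sum_{\beta \supseteq \alpha} \Big(\prod_{f \notin \beta}
n_f\Big)\, \sigma^2_\beta$$

exactly: the coefficient matrix is triangular in the canonical effect
order (effects sorted by the size of their index set, ties broken by facet
order), so the solution is unique and deterministic. We chose ANOVA
estimation rather than REML because for balanced designs the two coincide
for nonnegative solutions, the ANOVA solution is closed-form and fast
enough to resample thousands of times, and its mean squares carry the
exact chi-square sampling law the uncertainty machinery relies on. The
price is that raw solutions can be negative; following the standard
convention they are truncated to zero *after* the full system is solved,
with the raw value and a flag retained so that sensitivity analyses are
not silently biased.

Balance is a hard requirement, not a default: expected-mean-squares
algebra is exact only for complete crossings, so unbalanced or incomplete
tables are rejected with the first offending cell named rather than
averaged over. Nested facets may be labelled either within parent (person
1..50 in every site) or globally (unique person IDs); globally unique
labels are re-indexed within their parent automatically.

## D study: projecting the coefficient

A plan assigns a projected size to every non-object facet. Relative error
averages each effect involving the object of measurement (except the
object effect itself) over the plan sizes of its other facets; absolute
error adds the effects not involving the object, averaged over all their
facets. The coefficient is $\sigma^2_{object} / (\sigma^2_{object} +
\sigma^2_{error})$ — the generalizability coefficient under relative
error, the dependability coefficient under absolute error, the latter
being appropriate for pass/fail decisions against a fixed standard.

Two conventions deserve explicit statement because the design space was
genuinely open:

* **Nested object of measurement.** When persons are nested within sites,
  the universe-score variance is the nested component
  $\sigma^2_{p:s}$, and the site main effect contributes to absolute error
  only (divided by $n_s$). Person-by-facet interactions nested in sites
  (e.g. $\sigma^2_{pf:s}$) are averaged over $n_s$ as well as over the
  interacting facet — the package treats every non-object facet of an
  effect symmetrically. The classical alternative (averaging person-level
  interactions only over the crossed facet, since each person sits in one
  site) is equally defensible; for the site counts typical of multi-site
  exams the difference is second-order, but users comparing against
  hand calculations should be aware of it.
* **Integer plans.** Plan sizes are counts of stations, forms, sites;
  fractional sizes are refused rather than interpolated.

Coefficients are reported in full precision; the conventional 4-decimal
display is applied only when printing.

## Costs, ICERs and the acceptability curve

Costs are facet-linear: a unit cost per level of each facet plus an
optional fixed term. This mirrors how assessment budgets are actually
tabulated (per-site logistics, per-form authoring, per-station
development) and makes plan cost an exact inner product — the package
reports exact sums and leaves any rounding of published unit costs to the
user. The ICER between an intervention and a base plan is
$\Delta C / \Delta E$ with signs preserved, so a cheaper, less effective
proposal gets a positive ICER by cancellation; equal effectiveness is an
error (dominance should be argued on costs directly, not hidden in a
division by zero). Because one full unit of a reliability coefficient is
an absurd increment, ICERs are conventionally rescaled to money per 0.01
of the coefficient; display rounding is half-away-from-zero to the nearest
currency unit and is never used in computation.

The acceptability curve draws $(\Delta C_i, \Delta E_i)$ independently
from configurable distributions — degenerate, normal (effectiveness
differences truncated to $[-1, 1]$ by clamping), or lognormal on each
plan's cost with a moment-matched coefficient of variation — and reports,
for each willingness-to-pay $\lambda$ on the rescaled axis, the fraction
of draws with positive incremental net benefit $\lambda \Delta E_i -
\Delta C_i$. Ties count as not cost-effective. With point-mass
distributions the curve is a step located exactly at the ICER: for a
cost-saving, less effective proposal the acceptance probability is 1
*below* the ICER and 0 above it, the direction the net-benefit algebra
dictates ($\lambda \Delta E > \Delta C$ with $\Delta E < 0$ flips the
inequality). Independence of $\Delta C$ and $\Delta E$ is a deliberate
minimal assumption: the two are measured by entirely different
instruments (budgets vs. rating data), and any correlation structure a
user can defend can be injected by supplying user-side draws.

Coefficient uncertainty for the effectiveness arm comes from a parametric
bootstrap that exploits the exact balanced-design result $MS_\alpha \sim
E[MS_\alpha]\,\chi^2_{df_\alpha}/df_\alpha$ with independent mean squares:
resample mean squares, re-solve, truncate, recompute the coefficient. A
delete-one jackknife over object-of-measurement levels (deleting the same
within-site index across sites, which preserves balance) and a
user-supplied pass-through are also provided. Per-component confidence
intervals are out of scope; only the aggregate coefficient uncertainty
feeds the CEAC.

## The simulator, and what validation shows

`simulate_scores()` generates data from the same additive normal model the
estimator assumes: independent draws per effect level-combination, summed
per cell. The packaged demonstration (`inst/extdata/demo_config.yaml`)
mimics the shape of a six-site graduating OSCE — 6 sites, 4 forms, 18
stations, 50 persons per site — with illustrative components chosen once
so that the current configuration's dependability lands near 0.8, a value
typical of well-run OSCEs; it is labelled synthetic and reproduces no real
examination.

Validation therefore establishes *internal* correctness: sums of squares
agree with `anova(lm())` term by term; analytic EMS coefficients match
Monte-Carlo expectations of mean squares over $10^4$ simulated datasets
within three standard errors (designs up to four facets, level counts up
to three); components at a realistic size (100 persons, 8 tasks, 4 raters,
200 replicates) are recovered with under 10% bias; the projected relative
coefficient equals the explicit crossed-design formula to $10^{-12}$ over
1000 random inputs; and the large-draw CEAC converges to the closed-form
normal-theory probability. These problem sizes were chosen to make the
Monte-Carlo error small relative to each tolerance while keeping the
default suite fast. What passing them does **not** show is robustness to
features real rating data have and the model lacks: ordinal and bounded
score scales, rater severity drift, item difficulty structure,
missingness, and unbalanced administration. Normal effects make ANOVA
estimates efficient, but the estimator itself is moment-based, so mild
non-normality degrades precision before it degrades validity.

## Numerical and reproducibility policy

Tiny negative sums of squares from floating-point cancellation (below
$10^{-10}$ relative to the total) are clamped to zero; genuine negative
*component* solutions are not — they are truncated with the raw value
kept. Currency display rounding snaps to 12 significant digits first so
that binary representation error in decimal inputs cannot flip an exact
half downward. Every stochastic entry point (simulation, bootstrap, CEAC)
requires an explicit seed and restores the caller's RNG state; the
pipeline refuses configurations that enable a stochastic step without one,
and two runs of one configuration produce byte-identical reports.

## Known limitations

All facets random; balanced complete designs only; two-plan comparisons
(no multi-plan efficiency frontiers or extended dominance); no
discounting or inflation adjustment of costs; no optimization toward a
target coefficient (sweep user-supplied plans with `dstudy_grid()`
instead); effectiveness is a single reliability coefficient, which is one
slice of an assessment's validity argument, not the whole of it.
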