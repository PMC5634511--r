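---
title: "Methods: watershed water-source indices and the three-level diarrhea model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: watershed water-source indices and the three-level diarrhea model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`watershedd` implements, end to end and at desk scale, an analysis linking
the condition of upstream watersheds to childhood diarrheal disease (DD):
two spatially routed water-source indices summarize how much of the water
arriving at a location fell as rain on human- or livestock-impacted land and
on tree-covered land; a three-level random-intercept logistic model relates
those indices (together with household socioeconomics and climate) to a
binary child-level diarrhea outcome; and at-means marginal effects convert
the fitted coefficients into policy-comparable probability changes. Because
the health surveys such analyses rely on are access-restricted and the
environmental layers are bulky global rasters, every stage here runs on
synthetic landscapes and surveys with known generating parameters — which is
what makes the whole pipeline testable against ground truth.

## Water-source indices

Each cell of a raster landscape contributes monthly runoff

$$ q = \max(P - \mathrm{AET},\, 0) $$

(precipitation minus actual evapotranspiration, both mm/month, floored at
zero). Runoff is routed over a D8 drainage network: every cell drains to its
steepest-descent 8-neighbor, with slopes measured as drop over
center-to-center distance and ties broken by a fixed neighbor precedence
(N, NE, E, SE, S, SW, W, NW). Synthetic elevation is a Gaussian-smoothed
random field plus a deterministic tilt, then pit-filled by Planchon–Darboux
relaxation so that every cell has a strictly descending path to the grid
edge; this mirrors the fact that real analyses use hydrologically
conditioned (pit-resolved) flow networks. Because each pointer is strictly
downhill, sorting cells by decreasing elevation gives a valid topological
order for accumulation.

A cell's *tagged fraction* marks land regarded as a contamination (or tree)
source:

* human part: each person is assumed to impact 3.65 m² of ground per year,
  so a cell of area $A$ with population $n$ has human fraction
  $\min(1, 3.65\,n/A)$;
* pasture part: the cell's entire pasture fraction counts as impacted
  whenever its cattle headcount is positive;
* the two parts combine by capped sum (the sources are stated separately,
  with no combination rule given, so the simplest conservative choice is
  used);
* for the tree index the tagged fraction is simply the cell's tree-cover
  fraction.

Accumulating both total and tagged water volumes down the network and taking
their ratio gives, per cell, the percent of accumulated water that fell as
rain on tagged land — the *upstream human-activity index* and *upstream
tree-cover index*, each in $[0, 100]$. A dry cell (zero accumulated water)
has index 0 by definition, which resolves the 0/0 case: no water means no
influence. Every index value is checked in the test suite against a
brute-force oracle that enumerates a cell's full upstream set and sums
contributions directly; mass conservation at outlets, bounds, monotonicity
in upstream tree cover and dilution by untagged water are verified as
properties.

Cluster-level exposures average each index over all cells whose centers fall
in a square window (default 10 km side) centered on the cluster's *reported*
coordinates. A square window is used because it is exact on the raster; the
10 km default matches the resolution at which such environmental layers are
commonly aggregated.

## The synthetic survey

The survey generator emulates a two-stage cluster design: clusters placed at
grid-cell centers (urban clusters preferentially on populated cells), then
households within clusters, then children within households. Reported
cluster coordinates are randomly displaced as in published health-survey
GPS data: up to 2 km for urban clusters, up to 5 km for rural ones, with a
further 1% of rural clusters displaced 5–10 km. The far-rural draw is taken
from (5 km, 10 km] so that the fraction of rural displacements beyond the
ordinary 5 km cap is the stated 1%. Displaced points are clipped to the
study region, which can only shorten a displacement.

Outcomes come from the same three-level logit the analysis fits:

$$ \mathrm{logit}\, p_{ijk} = \beta_0 + \beta_1\,\mathrm{Age}_{ijk} +
\beta_2\,\mathrm{Wealth}_{jk} + \beta_3\,\mathrm{Education}_{jk} +
\beta_4\,\mathrm{Sanitation}_{jk} + \beta_5\,\mathrm{Water}_{jk} +
\beta_6 P_{t-1,k} + \beta_7 \Delta P_k + \beta_8 T_{t-1,k} +
\beta_9 \Delta T_k + \beta_{10}\,\mathrm{Human}_k +
\beta_{11}\,\mathrm{Tree}_k + v_{0k} + u_{0jk} $$

with $v_{0k} \sim N(0, \sigma_k^2)$ independent across clusters and
$u_{0jk} \sim N(0, \sigma_{jk}^2)$ independent across households within
clusters. Child age is uniform on 0–59 months (all children under five).
Household covariates are drawn with urban/rural-specific probabilities;
improved water defaults to 63% urban vs 22% rural, the contrast such surveys
report, and the remaining probabilities are plausible survey-like values.
Water sources and sanitation facilities are emitted as category labels and
recoded downstream through an editable WHO/JMP improved/unimproved mapping,
mirroring a real workflow. Climate enters as cluster-level z-scores of the
previous month's long-term mean precipitation and temperature plus
standardized month-over-month changes; the survey month's lag wraps January
to December. Standardization is over the pooled analysis sample, matching a
single pooled model.

Default generating values (all overridable through `generating_params()`):

* $\sigma_k = 0.448$, $\sigma_{jk} = 0.722$ — obtained by inverting
  latent-scale intra-class correlations of 0.05 (cluster) and 0.18
  (household, cumulative) with logistic residual variance $\pi^2/3$;
* $\beta_0 = -1.8$ with modest covariate effects, giving a simulated DD
  prevalence near 10%, the scale reported for under-five diarrhea in the
  two-week-recall window;
* 500 clusters × 5 households × 2 children (5,000 children), 35% urban.

Cluster sizes and households per cluster are not standardized quantities in
such surveys, so they are configuration with these defaults rather than
asserted constants. One root seed drives named substreams (landscape,
clusters, displacement, climate, survey), so each stage is independently
reproducible. The generator also accepts a tree-cover × unimproved-water
interaction coefficient (default 0); it exists purely to construct designed
experiments for the subgroup machinery and is not part of the analysis
model.

What the generator does *not* emulate: survey sampling weights, multi-country
stratification, asset-based wealth-index construction (quintiles are drawn
directly), spatially varying survey timing, or measurement error in the
outcome. Passing tests therefore demonstrate the correctness of the
machinery under the stated model, not robustness to the many ways real
survey data violate it.

## Estimating the three-level model

The marginal likelihood integrates both nested random intercepts out of the
Bernoulli likelihood. It factors by cluster:

$$ L_k = \int \phi(v;\sigma_k) \prod_{j \in k} \left[ \int
\phi(u;\sigma_{jk}) \prod_{i \in j} p_{ijk}^{y_{ijk}} (1-p_{ijk})^{1-y_{ijk}}
\, du \right] dv $$

and is evaluated with a nested Gauss–Hermite product rule (default 7 nodes
per level), entirely in logs with log-sum-exp, in compiled code with an
analytic gradient. `nlminb` maximizes it; standard errors come from the
numerically differentiated observed information, and 95% odds-ratio
intervals are exponentiated Wald intervals.

Why quadrature rather than the Laplace approximation most mixed-model
software defaults to: with binary outcomes and only two children per
household — exactly the design simulated here — the Laplace approximation is
unreliable. In our benchmarks, Laplace-based fits of the study-condition
design converged to a degenerate solution (cluster variance collapsing to
zero with the household variance inflated several-fold) whose *approximated*
log-likelihood exceeded the value at the truth, while the quadrature
likelihood is stable: estimates at 7 nodes agree with 25 nodes to four
decimals because the per-group integrands (2–10 Bernoulli terms) are smooth
and well scaled. The test suite nevertheless cross-checks the estimator
against an independent Laplace implementation in a large-group regime where
Laplace is sound, and against ordinary logistic regression in the collapse
limit.

Numerical edge cases, decided and documented here:

* variance components are boxed to $[0, 5]$ on the SD scale; an SD of 5
  corresponds to an ICC of ~0.88, beyond anything meaningful for clustered
  prevalence data, and non-adaptive quadrature is not accurate there;
* with one child per household *and* one household per cluster the random
  intercepts are unidentifiable (a flat likelihood ridge trades the
  variances against the shape of the link), and the fit collapses exactly
  to ordinary logistic regression with both variances zero;
* a variance estimate at the zero boundary is excluded from the observed
  information before inversion (profiled out of the covariance);
* fits are invariant to row order and ID labels because rows are sorted
  internally by cluster and household;
* non-convergence is accepted only if the gradient norm is negligible,
  otherwise it is an error carrying the optimizer diagnostics; a
  single-class outcome or a degenerate starting logistic fit (complete
  separation) is an error up front.

Intra-class correlations use the latent-variable convention with logistic
residual variance $\pi^2/3$. The household figure is *cumulative* by
default — $(\sigma_k^2 + \sigma_{jk}^2)/(\sigma_k^2 + \sigma_{jk}^2 +
\pi^2/3)$, the correlation between two children of the same household —
because that is the quantity that exceeds the cluster ICC in the motivating
analyses (0.18 vs 0.05); the non-cumulative share is available via
`icc(fit, cumulative = FALSE)`.

Subgroup machinery refits the identical specification to urban vs rural
children, improved- vs unimproved-water households, or clusters above vs
below the sample-mean upstream human activity. The mean used for the
high/low split is the mean of the table passed in (typically the rural
subset), a choice the source analyses leave open; covariates constant
within a subgroup (the split variable itself, usually) are dropped from that
subgroup's design with a message. Cluster-level covariates are *not*
re-standardized within subgroups: scaling is fixed once on the full sample.
The alternative specification replaces age by year-band dummies (reference:
under 12 months) and the tree index by quartile dummies (reference: below
the 25th percentile) with half-open bins $[q_{25}, q_{50})$ etc.; a dummy
that is structurally empty (every child in the reference band) is dropped
rather than kept as a zero column.

## Marginal effects at means

Effects are evaluated at the sample means of the design columns (binary
covariates at their proportions) with both random intercepts at zero — the
median of their distribution; the source analyses state an at-means
computation without fixing the random-effect convention, and zero is the
natural point. For a binary variable the effect is the exact difference of
two inverse-logit predictions (the variable at 1 vs 0). For the continuous
tree-cover index the effect of a scenario is the instantaneous rate
$\beta_v\,\bar p(1-\bar p)$ times the increase, evaluated for additive
increases of 10, 20 and 30 percentage points of the index (the index is
itself a percentage, so percentage *points* are its natural units).
Linearity in the scenario size is exact under this approximation.
Confidence intervals are delta-method intervals through the fixed-effect
covariance; the gradient of the binary effect is
$p_1(1-p_1)x^{(1)} - p_0(1-p_0)x^{(0)}$ and of the scenario effect
$\Delta[\mathbb{1}_v \bar p(1-\bar p) + \beta_v(1-2\bar p)\bar p(1-\bar p)
\bar x]$. For synthetic runs the pipeline reports both the at-means baseline
probability and the raw prevalence, since the two need not coincide.

## Problem sizes and what the tests establish

The test suite verifies: routing against the upstream-enumeration oracle on
random grids up to 50×50 (exact to 1e-9); displacement caps exhaustively
over 10,000 draws; the collapse limit against `glm` to 1e-4; coverage of all
twelve fixed-effect 95% intervals within [90%, 98%] over 200 simulated
surveys of ~5,000 children at the default generating parameters, with mean
ICC estimates recovering the generating 0.05/0.18 (tolerances 0.03/0.05,
fixed in advance to allow the small-sample ML bias expected with two
children per household); and designed simulations reproducing the expected
qualitative patterns (a tree-cover effect present only under unimproved
water shows up only in that subgroup; configured policy-effect orderings
survive into the marginal-effects table). These sizes were chosen as the
smallest at which the checks are statistically meaningful; all run on one
CPU.

Known limitations: single-direction (D8) routing with no multi-direction
partitioning; a static climatology with no sub-monthly dynamics; no survey
weights or imputation (listwise deletion with a logged count); Wald rather
than profile or bootstrap intervals; and the watershed indices follow the
verbal definition of the water-source-share metric — a linear tagged/total
share — which cannot be asserted identical to any particular hydrological
platform's full implementation.
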