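---
title: "Estimating spatiotemporal seed dispersal effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spatiotemporal seed dispersal effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdeland)
```

## The model

Seed dispersal effectiveness decomposes a frugivore's service to a plant
into a quantity and a quality component. `sdeland` estimates both over a
factorial frame of fruiting periods $j$, deposition microhabitats $k$ and
disperser groups $i$:

$$\mathrm{QT}_{ijk} = d_{jk}\, f_{ijk}, \qquad
  \mathrm{QL}_{jk} = v_j\, p_{jk}\, g_{jk}\, s_{jk}, \qquad
  \mathrm{SDE}_{ijk} = \mathrm{QT}_{ijk}\, \mathrm{QL}_{jk}.$$

Here $d_{jk}$ is seed rain density (seeds/m²), $f_{ijk}$ the relative
contribution of group $i$ among identified seeds, and the quality factors
are sequential conditional probabilities: viability of a dispersed seed
($v_j$, period-level), escape from post-dispersal predation ($p_{jk}$),
germination given viability ($g_{jk}$) and first-summer seedling survival
given emergence ($s_{jk}$). Because each factor conditions on the previous
transition, their product is the cumulative probability that a dispersed
seed recruits. The default frame (`default_frame()`) is the lentisc
design: a nine-month season split into three three-month periods, three
microhabitats, and eleven bird species in three migratory-strategy groups
— 27 effectiveness cells in all.

Assumptions worth stating explicitly:

- **Representative subsample.** Group frequencies are estimated from the
  barcoded subset of trapped seeds (≈44% in the study) and applied to the
  full density; cells where that subset is empty while density is positive
  raise an error rather than being imputed.
- **Per-seed counting.** Frequencies count seeds, not samples: a dropping
  with three seeds contributes three. Identification failures are excluded
  with renormalisation, so $f_{ijk}$ is a contribution *among identified
  seeds*.
- **Pooled binomial estimates.** Subcomponent proportions pool seeds
  across depots/stations within a cell; unit-level clustering is not
  modelled here (a mixed-model treatment is outside this package's scope),
  so intervals are exact for the pooled binomial but can be mildly
  anti-conservative under strong clustering.
- **Trap-period replication.** The replication unit for densities and the
  ANOVA is the trap × period total, not the individual fortnightly survey.

## Aggregation across periods

The season-overall effectiveness per group and microhabitat uses a
quantity-weighted quality,

$$\overline{\mathrm{ql}}_{ik} =
  \frac{\sum_j \mathrm{qt}_{ijk}\,\mathrm{ql}_{jk}}{\sum_j \mathrm{qt}_{ijk}},$$

because different fractions of a group's seed rain arrive in each period.
Weighting by the group-specific $\mathrm{qt}_{ijk}$ (rather than by
quantities pooled over groups) is the design choice made here: it is the
only weighting under which the stated weighted mean is well defined per
group and it makes the overall effectiveness exactly additive,
$\mathrm{SDE}_{ik} = \sum_j \mathrm{SDE}_{ijk}$ — the central correctness
property the tests enforce. A microhabitat-pooled quality can still be
obtained by aggregating the cell table directly. Totals and landscapes use
policy-adjusted quality by default (`zero_policy = "paper"`), matching how
the composite is meant to be read; `"raw"` is available throughout.

## Tunable parameters

- `level` (default 0.95) and `ci_method`: `"clopper-pearson"` (default;
  exact, conservative — guaranteed ≥ nominal coverage, verified in the
  tests by tail enumeration) or `"wilson"` (shorter, slightly
  anti-conservative). The exact interval is the default because several
  subcomponents sit near 0 or 1, where Wald-type intervals fail.
- Zero policy: estimated predation escape is set to a constant
  `p_constant = 0.01` in every cell (observed predation was near-total
  with no detectable variability, so the raw 0s and 0.007s reflect sample
  size, not structure), and zero survival estimates are replaced by the
  minimum non-zero survival across cells. The policy is idempotent and
  every replacement is flagged in the output. If all survival values are
  zero no minimum exists and an explicit constant is required.
- Isoclines: `n_isoclines` (default 8) levels spaced geometrically between
  the smallest and largest positive effectiveness, so every point lies on
  the isocline of its own value; linear spacing is available.

## Numerical choices and degenerate inputs

- Density intervals are t-intervals on $\ln(x+1)$ per-trap densities,
  back-transformed — the same transformation as the factorial test. The
  lower bound is clamped at zero; with one trap or tied densities the
  interval degenerates to the mean. For extremely skewed per-trap
  densities the back-transformed interval tracks the transformed-scale
  mean and can sit below the arithmetic mean it accompanies; at the
  design's scale the two agree closely.
- The factorial ANOVA uses type-II sums of squares; with empty design
  cells the interaction is dropped with a warning, and with literally no
  variation in the response all F statistics are reported as 0.
- The period-effect test is a likelihood-ratio $G^2$ (saturated versus
  pooled binomial), the LRT analogue of a Wald test on a binomial
  logit-link model; its exact Wald statistics are not reproduction
  targets.
- Undefined cells — no traps, no identified seeds, no tested seeds, all
  stations lost — are carried as explicit `NA`s with zero trials, excluded
  from totals with a warning, and never silently zeroed. The one fatal
  combination is a defined positive quantity with undefined quality.

## What the generator emulates — and what it does not

`generator_config()` encodes the data-generating process the analysis
assumes: homogeneous Poisson deposition per trap and survey within a
period (the analysis only consumes period totals, so no within-period
phenology curve is modelled); a period-structured species pool whose
within-period abundances control composition independently of deposition
rates; aggregation of seeds into droppings (≈97% singletons); collection
of droppings for barcoding with probability 0.44 and identification
failure 0.047; per-seed Bernoulli viability (0.63 / 0.35 / 0.05 by
period); Bernoulli fates in depots (escape 0.0067) and sowing stations
(germination and survival per cell, germination week normal around period
means 8.1 / 11.3 / 6.9); and station losses of 13% (germination scoring)
and 25% (survival scoring), with germination loss implying survival loss.
One RNG stream with a fixed draw order (surveys → species → droppings →
barcoding → viability → depots → stations) makes a config + seed pair
byte-reproducible.

The study-scale defaults (`paper_like_config()`) reproduce the field
design's size — 37 traps, 18 fortnightly surveys, ≈1,030 trapped seeds, 72
depots and 72 stations — and the reported orderings (threefold mid-period
deposition peak; trees 2–3× below shrubs; germination lowest and slowest
mid-period; survival highest beneath fruit-bearing shrubs; overall
germination ≈0.30 and survival ≈0.28). Per-cell deposition rates and group
mixtures are not published quantities; the shipped values are one-time
calibrations to those reported scales, documented as illustrative. The
generator does not simulate bird movement, gut passage, spatial seed
shadows or within-season phenology, so passing recovery tests demonstrate
that the estimators recover the parameters of *this* observation model —
not that field data satisfy it.

Problem sizes used in the shipped checks are deliberately modest and
stated here as the package's own choices: property tests run on reduced
designs (9 traps, 3 depots and 6 stations per cell, exhaustive barcoding
so no cell is undefined by chance); the recovery study uses 500 replicates
of the study-scale design, at which the Monte-Carlo standard error of a
95% coverage estimate pooled over the three viability periods is about
0.005; the workflow scripts use 200 replicates.

## Known limitations

- No uncertainty propagation into SDE: the composite is reported as point
  values (bootstrap propagation is a natural extension).
- No per-species (11-way) effectiveness decomposition; groups are the unit
  of inference.
- No mixed-effects or time-to-event modelling of the post-dispersal
  experiments; pooling is the estimator, clustering enters only the
  field design.
- Clopper–Pearson conservatism is real: at small success probabilities
  (e.g. viability 0.05 with ≈90 tested seeds) exact coverage runs near
  0.97–0.98, which matters when interpreting coverage summaries near their
  nominal level.
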