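# sdeland

Spatiotemporal seed dispersal effectiveness (SDE) analysis for
animal-dispersed plants with long fruiting seasons, built around the
study system of a Mediterranean shrub (lentisc, *Pistacia lentiscus*)
dispersed by frugivorous birds over a nine-month fruiting phenophase.

Seed dispersal effectiveness is the product of a **quantity** component
(how many seeds a disperser moves) and a **quality** component (the
probability that a dispersed seed becomes an established seedling).
`sdeland` estimates both across a factorial design of fruiting *periods*
(early / mid / late) and deposition *microhabitats* (beneath oak trees,
fruit-bearing shrubs, and shrubs without fleshy fruits), for disperser
groups defined by migratory strategy (residents, sub-Saharan migrants,
European wintering migrants):

- **Quantity** — QT<sub>ijk</sub> = d<sub>jk</sub> × f<sub>ijk</sub>, where
  d<sub>jk</sub> is the seed rain density (seeds/m²) from seed-trap surveys
  in period *j* and microhabitat *k*, and f<sub>ijk</sub> is disperser group
  *i*'s relative contribution among DNA-barcoded seeds. A two-way ANOVA on
  ln(x + 1) densities tests period, microhabitat and their interaction.
- **Quality** — QL<sub>jk</sub> = v<sub>j</sub> × p<sub>jk</sub> ×
  g<sub>jk</sub> × s<sub>jk</sub>: seed viability (flotation), escape from
  post-dispersal predation (seed depots), germination and first-summer
  seedling survival (sowing stations), each with binomial (Clopper–Pearson
  or Wilson) confidence intervals, a likelihood-ratio period test, and an
  explicit zero-replacement policy for collapsed estimates.
- **Effectiveness** — SDE<sub>ijk</sub> = QT<sub>ijk</sub> × QL<sub>jk</sub>,
  aggregated across periods with quantity-weighted quality (which makes the
  season-overall SDE exactly additive in its per-period parts), period
  totals, contribution shares, and quantity × quality landscapes with
  isoclines.
- **Synthetic data** — a generator with known ground truth emulating the
  full observation process (Poisson deposition, seasonal assemblage
  turnover, barcoding subsample and identification failures, near-total
  predation, station losses), plus a parameter-recovery study
  (bias, RMSE, CI coverage).

## Worked example

Simulate one study-scale season and run the full pipeline:

```r
library(sdeland)
frame  <- default_frame()            # 3 periods x 3 microhabitats x 3 groups
bundle <- generate_study(paper_like_config(), seed = 20140801)
res    <- run_sde_pipeline(bundle, frame)
res$period_totals
#> # A tibble: 3 × 2
#>   period sde_total
#>   <chr>      <dbl>
#> 1 early    0.0400
#> 2 late     0.00164
#> 3 mid      0.0667
```

The totals say that, per m² of microhabitat, about 0.040 and 0.067
recruiting seedlings are expected from dispersal in the early and mid
periods, but an order of magnitude fewer (0.0016) from late dispersal —
late-season seed rain is still substantial, but most late seeds are
unviable. The per-group season aggregates show the compensation between
components:

```r
head(res$overall, 3)
#> # A tibble: 3 × 5
#>   group    microhabitat qt_total ql_weighted sde_overall
#> 1 European fb_shrubs      125.     0.000449     0.0563
#> 2 European nfb_shrubs     132.     0.000129     0.0170
#> 3 European trees           51.8    0.0000811    0.00420
```

European migrants dominate quantity, yet groups whose dispersal is
concentrated in the high-quality early period keep a disproportionate
share of effectiveness beneath fruit-bearing shrubs
(`res$shares`). `plot_landscape(res$landscape_overall, colour = "group")`
draws the corresponding effectiveness landscape with isoclines of constant
quantity × quality.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → quantity → quality → effectiveness → recovery),
printing what each stage found and writing tidy tables under `results/`.
Field data can be analysed identically by pointing `read_study_tables()`
at delimited tables (with an optional column mapping for externally
deposited files) instead of the generator.

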