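# richstack

Ocean-scale species **richness maps from stacked per-species range
estimates**, for reef-associated marine taxa whose occurrence data are
sparse compilations of survey records. `richstack` is aimed at
biogeographers and biodiversity-informatics researchers who want the whole
workflow — from occurrence tables and an environmental raster stack to
richness maps and latitudinal/longitudinal diversity gradients — in one
reproducible, testable R package.

Two complementary overlays are produced and can be compared:

* **SDM overlay** — a from-scratch presence/background **maximum-entropy
  distribution model** per species, fitted on PCA-reduced environmental
  predictors. For species presences \(x_1,\dots,x_m\) and a background
  sample \(B\), the model is the Gibbs distribution
  \(q_\lambda(x) = e^{\lambda\cdot f(x)}/Z(\lambda)\) over \(B\), with one
  linear and one quadratic feature per principal component, fitted by
  maximising the L1-penalised log-likelihood
  \(\tfrac1m\sum_i \lambda\cdot f(x_i) - \log Z(\lambda) -
  \sum_j \beta_j|\lambda_j|\) (convex; accelerated proximal gradient).
  Ten replicate models per species (random 80/20 splits, test AUC against
  background) are merged and thresholded at the **equal
  sensitivity–specificity** cutoff into a binary range.
* **MCP overlay** — the **minimum convex polygon** of each species'
  records, rasterised by cell-center containment.

Both overlays are *hybrids*: species that support neither a model nor a
polygon (fewer than three records, collinear records, too few distinct
cells) enter as merged **500 km geodesic buffers** around their records.
Every range is clipped to the analysis mask — reef habitat dilated by
100 km — and range-limited species are additionally constrained to
2,500 km discs around their records. Ranges are summed cellwise into
richness maps and summarised as 3°-binned boxplot gradients along latitude
and longitude. A synthetic-biodiversity generator with known ground-truth
niches makes the entire pipeline testable without external data.

## Worked example

A reduced study (12 species, 1° grid) runs in a few seconds:

```r
library(richstack)

cfg <- richness_config(
  extent = c(90, 170, -30, 30), cell_size = 1,
  synthetic = list(n_species = 12, n_sites = 120, n_records_total = 520,
                   n_layers = 6, correlation = 0.7, reef_coverage = 0.12,
                   n_rare = 2, n_range_limited = 2),
  pca = list(n_sample = 2000),
  sdm = list(n_replicates = 5, background_size = 2000),
  seed = 2024)
run <- run_richness_pipeline(cfg)
#> simulate: 12 species on a 1-degree grid
#> mask: dilating reef habitat by 100 km
#> pca: 2000 sampled cells
#> pca: 3 component(s) retained (70.1% of variance)
#> sdm: 9 of 12 species modelable
#> stack: max richness 8 (MCP) / 7 (SDM)

glance(run)
#> # A tibble: 1 x 13
#>   n_species n_sdm n_mcp n_buffer_sdm_map mean_auc_test median_auc_test ...
#> 1        12     9    10                3         0.795           0.812 ...

head(run$routing)
#> # A tibble: 6 x 7
#>   species_id n_records n_presence_cells range_limited mcp_route sdm_route reason
#> 1 sp01              35               12 FALSE         MCP       SDM       <NA>
#> 4 sp04               2                2 FALSE         buffer500 buffer500 2 dis...

run$sdm[["sp01"]]
#> <sdm_ensemble> species 'sp01': 5 replicates, mean test AUC 0.830,
#>   threshold 0.465, 12 presence cells
```

Reading the output: three species were too data-poor for a model and enter
both maps as 500 km buffers (`buffer500`); the modelable species average a
test AUC of 0.80 ("good" discrimination); at most 8 of the 12 species
overlap in any one cell of the MCP map. `autoplot(run$richness_sdm)` draws
the richness map, `autoplot(run$gradients$sdm_latitude)` the layered
gradient chart (maxima, whiskers, quartiles, median), and
`write_richness_run(run, "out/")` writes rasters (ESRI ASCII), gradient
tables, the routing table and a JSON manifest from which the run can be
re-executed.

A command-line driver with the same knobs ships in
`inst/scripts/run_pipeline.R`.

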