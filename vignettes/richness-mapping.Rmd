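---
title: "Stacked range models for marine species richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked range models for marine species richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richstack)
```

## The problem

Reef-associated taxa such as symbiont-bearing larger benthic foraminifera
are distributed across entire ocean basins, but their occurrence records are
sparse, heterogeneous, and concentrated at a few hundred sampled sites. To
map species richness at that scale one estimates a *range* for every species
and counts, in each grid cell, how many ranges overlap. `richstack`
implements this stacked-range workflow twice over, so the two estimates can
be compared:

1. an **SDM overlay** — per-species presence/background maximum-entropy
   distribution models on PCA-reduced environmental predictors, thresholded
   into binary maps;
2. an **MCP overlay** — per-species minimum convex polygons around the
   records, with no habitat weighting.

Both overlays are *hybrids*: species that cannot support a model or a
polygon are represented by merged 500 km geodesic buffers around their
records. All ranges are clipped to an analysis mask, the reef habitat
dilated by 100 km, because these taxa only occur in and near shallow
warm-water carbonate habitat.

## The maximum-entropy model

For one species with presence cells $x_1,\dots,x_m$ and a background sample
$B$ of the analysis mask, the model is the Gibbs distribution over
background cells

$$q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z(\lambda)},\qquad
  Z(\lambda) = \sum_{x \in B} \exp(\lambda \cdot f(x)),$$

with feature vector $f(x)$ containing one linear and one quadratic term per
principal component, each affinely scaled to $[0,1]$ on the background
(unscaled cells may map outside that interval; no clamping is applied).
Starting from the uniform distribution ($\lambda = 0$), the weights maximise
the L1-penalised log-likelihood

$$\ell(\lambda) = \frac{1}{m}\sum_i \lambda \cdot f(x_i) - \log Z(\lambda)
  - \sum_j \beta_j |\lambda_j|.$$

This is a convex problem; `fit_maxent()` solves it with accelerated proximal
gradient ascent (backtracking line search, soft-thresholding, restart on
overshoot), stopping when the objective improves by less than `1e-7` or
after 500 iterations. At the optimum the KKT conditions pin every feature's
discrepancy: $|E_q[f_j] - \bar f_j^{\text{presence}}| \le \beta_j$, with
equality on active features, and with $\beta = 0$ the fit reduces to exact
moment matching. The per-feature penalty is
$\beta_j = \beta_0 \, \mathrm{sd}_B(f_j) / \sqrt{n_{\text{train}}}$
(default $\beta_0 = 1$), shrinking harder when training data are few.

Quadratic features suffice to represent a Gaussian niche optimum along each
component axis, which is why the feature classes stop there: hinge, product
and threshold features would add flexibility the synthetic truth does not
need and real sparse records rarely support.

Predictions use the logistic output
$p = e^{H} q / (1 + e^{H} q)$, where $H$ is the entropy of $q_\lambda$
over the background. Under this default-prevalence convention an
uninformative model scores exactly 0.5 on every background cell, so maps of
different species are on a comparable scale.

### Ensembling, evaluation, thresholding

Each modelable species gets `n_replicates = 10` models, each trained on a
fresh random 80 % of its presence cells and evaluated on the held-out 20 %
with the rank-based AUC against the background sample (ties count one
half). The wording "bootstrap" in common SDM usage covers exactly this
replicated-split scheme; we resample the split *without* replacement, since
an 80/20 train/test description is a partition, not a with-replacement
resample. Replicate surfaces are averaged first, and the **equal
sensitivity–specificity threshold** is then computed once on the merged
surface — candidates are the observed scores, the minimiser of
$|\text{sens} - \text{spec}|$ wins, and ties break toward the smaller
threshold (the more inclusive range). AUC bands follow the usual
convention: above 0.9 very good, above 0.8 good, above 0.7 useful.

Eligibility requires **8 distinct presence cells**: with fewer, the 20 %
test split degenerates. Species below the floor fall back to 500 km
buffers. Species flagged *range-limited* additionally have their binary map
intersected with the union of 2,500 km geodesic discs around their records,
because a purely environmental model will happily predict suitable but
unreachable habitat an ocean away.

## Geometry on a 180°-centred grid

The study domain spans the Indian and Pacific Oceans, so all longitudes are
recentred to $[0°, 360°)$; Pacific ranges are contiguous at the
antimeridian and convex hulls are computed as planar hulls in the
recentred coordinates — standard MCP practice at tropical latitudes, where
the planar distortion is modest. Hull vertices are returned
counter-clockwise; rasterisation marks a cell when its **center** lies
inside or on the polygon (even-odd rule, boundary inclusive), which makes
richness counts bit-reproducible. Occupied record cells are always kept in
an MCP range even when a boundary record's cell center falls marginally
outside the hull — records are direct evidence of presence.

All geodesic calculations (buffers, range discs, the reef-mask dilation)
use the haversine distance on a spherical Earth of radius 6,371 km; the
error against ellipsoidal geodesics is below half a percent, far below a
grid cell at the radii involved.

## The synthetic study

Real occurrence compilations for these taxa are not openly deposited, so
the package ships a generator that emulates the study conditions and — more
importantly — carries a known ground truth per species, making the whole
pipeline testable.

Defaults, chosen once as the study conditions:

| parameter | default | why |
|---|---|---|
| species | 68 | size of the real species pool being emulated |
| sites / records | 507 / 2,964 | the compilation's sampling effort |
| extent | 40°–260°E, 34°S–33°N | Indo-Pacific realm; sites span 33°N–34°S |
| cell size | 0.5° | desk-scale runtime; the 2.5-arcmin production resolution stays expressible via `cell_size` |
| layers | 7 in 4 correlated families | mimics marine climatology stacks (temperature, productivity, nutrients, radiation families) whose within-family correlation (target 0.7) makes PCA reduction meaningful |
| reef coverage | 8 % of marine cells | clustered, warm-water (|lat| ≤ 40°) habitat |
| rare species | 6 with < 3 records | exercises the buffer-fallback routes |
| range-limited species | 8, discs of 1,500–2,500 km | exercises the range constraint |

Environmental layers are sums of latent smooth surfaces (white noise on a
6° knot lattice, bilinearly interpolated) plus, for the temperature-like
first layer, a latitudinal gradient; each species' niche is an axis-aligned
Gaussian in layer space whose optimum is drawn from the environment at an
anchor reef cell near a richness hotspot (default 125°E, 10°N) and whose
tolerances are 0.6–1.5 layer standard deviations — a realistic niche
breadth relative to the available gradient. Records are drawn from the
fixed site set with probability proportional to true suitability and
jittered uniformly within their cell, so point-to-cell snapping is
exercised. Every stage draws its seed from one master seed through a
stable string hash (`child_seed()`), so adding one species never
reshuffles another's draws and a run regenerates bit-identically.

What the generator deliberately does **not** emulate: depth structure of
the photic zone, spatial sampling bias along ship tracks, taxonomic error,
and niche axes oblique to the environmental layers. Passing recovery tests
on this fixture therefore demonstrates the machinery is correct and
well-calibrated on Gaussian niches — not that real-data maps are accurate.

## PCA of the environmental stack

`fit_env_pca()` performs correlation-matrix PCA (each variable standardised
to unit variance) on a without-replacement sample of 10,000 valid cells;
the Kaiser rule (eigenvalue > 1) — meaningful only on a correlation matrix
— selects the retained components, which are then projected to every grid
cell with the sample's standardisation constants. Eigenvector signs are
fixed (largest-magnitude loading positive) so runs are reproducible. On
the 7-layer default stack three components typically pass Kaiser,
capturing ~70 % of the variance.

## Richness maps and gradients

`stack_ranges()` sums the boolean per-species grids; cell values are
bounded by the species count and grow monotonically as ranges are added.
`classify_richness()` bins positive values into display classes of width 5;
`anchor =` the map maximum reproduces the atlas legend convention in which
the top class closes at the observed maximum (e.g. 52–56).
`richness_gradient()` groups analysis-mask cells into 3° bins along either
axis and reports per-bin boxplot statistics: type-7 (linear interpolation)
quartiles, Tukey whiskers (most extreme values within 1.5 IQR of the
quartiles — the whisker rule is a fixed package choice), and the bin
maximum kept as its own series; empty bins are flagged, never zero-filled.
Only mask cells contribute — structurally absent open-ocean and land cells
would otherwise flatten every bin toward zero. Gradients are computed on
binary stacked richness, not on summed suitability probabilities.

```{r example, eval = FALSE}
cfg <- richness_config(seed = 1)
run <- run_richness_pipeline(cfg)
glance(run)
autoplot(run$richness_sdm)
autoplot(run$gradients$sdm_latitude)
write_richness_run(run, "richness-out")
```

## Numerical choices, in one place

* maxent convergence: penalised-objective improvement `< 1e-7`, cap 500
  iterations, start at `lambda = 0`; convexity makes the optimum
  initialisation-independent.
* threshold tie-break: smallest candidate score (most inclusive range).
* AUC: average-rank formulation, exact under ties.
* quantiles: R type 7 (linear interpolation), for cross-implementation
  reproducibility.
* rasterisation: cell-center containment, boundary inclusive, even-odd.
* degenerate inputs: constant PCA columns error; constant features are
  dropped with a warning; an all-identical score vector has no threshold
  and errors; hull requests with < 3 distinct or collinear records signal
  a typed fallback condition that range assembly converts into the buffer
  route.
* rare multiplicities: duplicate records collapse to one per (species,
  cell) for modeling; raw counts are preserved in provenance tables.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run the default 68-species study
on the 0.5° grid (about 59,000 cells, ~6,000 mask cells after the 100 km
dilation, backgrounds capped at 10,000 cells), which completes in roughly a
minute on one core; unit tests use 2° fixtures. These sizes are the
package's own reference configuration for reproducible examples.

## Known limitations

* Planar hulls and center-based rasterisation are resolution-dependent
  near range edges; at coarse test resolutions a boundary record's cell can
  leave the hull (hence the record-cell guarantee above).
* The Kaiser rule is sensitive to eigenvalues hovering near 1; retention
  is deterministic per fit but can differ across resampled grids.
* Linear+quadratic features cannot represent niches oblique to the
  principal axes; recovery degrades gracefully (rank correlations fall,
  AUC remains honest).
* The equal sensitivity–specificity threshold equates error *rates*, not
  error costs; with very few presences it is coarse.
* Richness gradients summarise the binary stack; a suitability-weighted
  gradient would differ where many species sit just below threshold.
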