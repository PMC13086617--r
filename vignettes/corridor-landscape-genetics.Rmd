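---
title: "Corridor-based landscape genetics with boosted trees and resistant kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corridor-based landscape genetics with boosted trees and resistant kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescape)
```

## The problem

Landscape genetics asks which features of a landscape impede or facilitate
gene flow. The data are individual-based: a modest number of georeferenced
animals genotyped at codominant markers (microsatellites), a stack of
landscape rasters, and the premise that genetic dissimilarity between two
individuals reflects the accumulated cost of moving between them
(isolation by resistance) rather than straight-line separation alone
(isolation by distance).

`rescape` implements a corridor-based workflow for this problem:

1. **Diversity and marker checks** — per-locus heterozygosity and fixation
   statistics, exact Monte-Carlo Hardy–Weinberg tests, and the
   standardized index of association $\bar r_d$ as a multilocus
   linkage-disequilibrium screen.
2. **Pairwise genetic distances** — proportion of shared alleles
   ($d_{ps}$), symmetrized Queller–Goodnight relatedness (as the
   dissimilarity $1 - r$), and Euclidean distance on allele dosages; none
   assumes Hardy–Weinberg equilibrium.
3. **Spatial genetic structure** — Mantel tests, Mantel correlograms, and
   rarefied allelic richness inside overlapping spatial genetic
   neighborhoods whose radius is the distance at which autocorrelation
   first turns non-positive.
4. **Resistance modeling** — landscape variables averaged inside 1-km-wide
   buffered transects between sample pairs; gradient-boosted trees of
   pairwise genetic distance with leave-one-spatial-cluster-out
   cross-validation and forward feature selection; per-pixel prediction of
   resistance with geographic distance held at its median; an iterative
   loop replacing straight lines with least-cost paths until held-out
   error stops improving.
5. **Connectivity** — resistant kernels: accumulated-cost spread from many
   random source points over the (1–100 rescaled) resistance surface,
   summed per pixel.

The statistics are authored here; standard infrastructure is delegated:
Dijkstra shortest paths run on `igraph`, the boosting engine is `xgboost`
(squared-error objective, no row subsampling, depth capped at 2 so trees
express at most two-way interactions), polygon point-tests use `mgcv`.

## The model

For a pair of individuals $(i, j)$ the response is a genetic distance
$g_{ij}$ and the predictors are the coverage-weighted means of each
landscape layer inside the buffered transect connecting them, plus the
pairwise geographic distance $d_{ij}$ (always a candidate; it absorbs
isolation by distance so landscape variables are not selected as its
proxies). A boosted-tree ensemble $f$ is fit to
$g_{ij} \sim f(\bar x_{ij}, d_{ij})$.

Because pairs sharing an endpoint are not independent and samples are
spatially clustered, model quality is judged by *spatial*
cross-validation: samples are grouped into $k$ contiguous clusters
(default 6), and fold $m$'s training set contains only pairs with
*neither* endpoint in cluster $m$, while its test set is every pair with
at least one endpoint there. Test sets are therefore large (typically well
over half the pairs). Cluster candidates (k-means restarts plus two
hierarchical cuts) are scored by nearest-neighbor-distance matching: the
pooled distribution of withheld-point-to-training distances should match
the distribution of prediction-location-to-training distances
(1-Wasserstein distance), so held-out data resemble the prediction task.

Forward feature selection evaluates every two-variable model, keeps the
best, then greedily adds variables. An addition must strictly reduce mean
RMSE on the withheld clusters *and* clear a one-standard-error rule on the
paired per-fold differences. The second condition matters: with pairwise
transect data, even a white-noise raster acquires some genuine
cross-validated predictive value, because transects that share a corridor
or an endpoint carry correlated layer means, and every test pair shares an
endpoint with training pairs by construction. The one-SE rule rejects
additions whose apparent gain rests on one lucky fold; it does not fully
eliminate the leakage channel (see *Limitations*).

Relative influence is the per-variable sum of squared-error reductions
over all splits, normalized to 100. Accumulated local effects (ALE) curves
summarize each predictor's effect from local prediction differences on
quantile bins, so correlated predictors do not contaminate each other's
curves; uncertainty comes from bootstrap refits and a reference band from
the central 95% envelope of ALE values for injected uniform-noise
predictors.

Predicted resistance is the model evaluated per pixel with $d$ fixed at
the median pairwise distance. For least-cost paths and kernels the surface
is first min–max rescaled to $[1, 100]$ — the conventional resistance
scale, which also fixes the meaning of cost units: edge cost between
adjacent cells is the mean of their resistances times the center-to-center
distance in meters (diagonals $\times \sqrt 2$), so a threshold of
1,100,000 cost units corresponds to 110 km of travel at a low resistance
of 10.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| transect buffer | 500 m | corridor half-width (1-km-wide transects) |
| pair separation floor | 0 (study choice: 3–4 km) | drop near-duplicate pairs from clustered sampling |
| folds $k$ | 6 | spatial CV clusters; each must keep ≥ 2 samples |
| learning rate | 0.005 | with tree counts searched at checkpoints 250–2000 |
| min obs per node | {5, 25, 50} | terminal-node size grid |
| interaction depth | {1, 2} | trees consider at most two-way interactions |
| kernel threshold | 1,100,000 | cost-distance units; 110 km at resistance 10 |
| kernel sources | 2000 | random points inside the population polygon |
| water override | 100 at > 3 km² | large water bodies set to maximal resistance |

The checkpointed tree-count search evaluates held-out error along a single
training run per fold, which makes the Table-style grid affordable;
iteration stops (in the corridor loop) on the first non-improvement of
mean RMSE, and the reported best model is the global minimum, which may be
the straight-line model.

## The synthetic-data generator

Real genotype data of the motivating kind are typically not
redistributable, so every stage is exercised against a generator with
known truth. It emulates:

* a terrain field driving **slope** (degrees, a sigmoid of terrain — flat
  valleys, steep mountains) and **colluvial** parent material (a
  high-terrain indicator; the colluvial–slope correlation is tuned toward
  0.87, a realistic degree of collinearity between surficial geology and
  topography, with slope carrying a partially independent terrain
  component so it is not a deterministic transform of the soil map);
* valley-bottom **organic/fluvial/lacustrine** indicators (anti-correlated
  with slope), **water** blobs, and **major roads** as valley-following
  polylines three pixels (~540 m) wide;
* **snowfall** as a latitude-plus-terrain gradient; and eight **decoy**
  layers of pure per-pixel noise;
* a **true resistance** surface $R = 1 + \sum_v \beta_v \,\text{layer}_v$
  (defaults $\beta$ = 3 colluvial, 10 slope, 4 roads), linear so that
  resistance spans the conventional 1-to-low-tens range;
* **samples** in uneven roadside clusters (85% placed within ~500 m of a
  road, emulating road-mortality collection);
* **genotypes** at 14 loci with 4–11 alleles and ~1% missing data. Pairwise
  cost distances through the true surface are embedded by metric MDS into
  two latent axes; each allele's log-frequency is a smooth stationary
  random field over those axes (random Fourier features) whose correlation
  length is the declared *neighborhood scale* expressed in cost units
  (geographic scale × median resistance, calibrated by a fixed internal
  factor of 0.55 so the genetic correlogram of generated data crosses zero
  near the declared scale). Genotypes are two independent draws from the
  local frequencies — local Hardy–Weinberg equilibrium. Setting the cline
  strength to zero yields panmixia.

What the generator does **not** emulate: coalescent genealogies and drift
(allele identities are labels, there is no mutation model), sex-biased
dispersal, temporal structure in sampling, null alleles, and genotyping
error. A passing recovery test therefore shows the *pipeline* can find
structure of the assumed kind at these sample sizes; it does not validate
the population-genetic realism of any particular dataset.

## Numerical choices

* **Transect coverage weights.** Interior pixels get weight 1; boundary
  pixels of straight-line corridors are clipped exactly
  (Sutherland–Hodgman polygon clipping, so weights sum to the corridor
  area to machine precision); buffered least-cost polylines use a
  regular subgrid per boundary pixel (default 8 × 8; bulk extraction uses
  4 × 4, which differs from exact weights by well under 1%). Flat end
  caps are the default: the corridor covers only area *between* the
  endpoints; round joins cover interior vertices of polylines.
* **Cost graph.** 8-connected lattice; on uniform surfaces the
  discretization elongates paths by at most
  $\sqrt2\cos(\pi/8) \approx 1.082$.
* **Exact HWE test.** The statistic is the conditional probability of the
  genotype array given allele counts (Levene); permutations shuffle the
  $2n$ gene copies and re-pair them, and
  $p = (1 + \#\{P_{perm} \le P_{obs}\}) / (1 + B)$, never exactly zero.
* **$\bar r_d$.** Per-locus pair distance 0/0.5/1 by shared allele copies;
  missing genotypes contribute the locus mean distance; permutations
  shuffle genotypes among individuals independently per locus.
* **Queller–Goodnight.** Ratio-of-sums across loci, reference frequencies
  from the full sample (focal pair included), symmetrized
  $(r_{xy} + r_{yx})/2$; degenerate denominators (possible at biallelic
  loci when $p_a + p_b = 1$) propagate `NA`.
* **Correlogram.** Equal-width distance classes (default 10 km; narrower
  on small synthetic extents), per-class sign-flipped Pearson correlation
  with the class indicator, two-sided permutation p-values, zero crossing
  at the midpoint of the first class with $r \le 0$.
* **Rarefaction size.** $g$ = twice the smallest member count among
  qualifying neighborhoods (> 10 members); loci with fewer typed copies in
  a neighborhood are rarefied at their own copy count.
* **Ties/degenerate inputs.** Monomorphic loci: $F$ undefined (`NA`), HWE
  test refused; constant surfaces cannot be rescaled; pairs with no shared
  typed locus get `NA` distance with a warning; unreachable pairs are
  dropped from the corridor loop with a count.

## Problem sizes used by the test suite

The full-size default scenario (116 individuals, 300 × 300 pixels at
180 m, 15-km neighborhood scale) is what the generator's defaults
describe. The automated end-to-end checks run a structurally identical
scenario at 110 individuals on a 140 × 140 grid with an 8-km neighborhood
scale, five sampling clusters, a 4-km pair separation floor, and a compact
hyperparameter budget (learning rate 0.08, up to 250 trees); these sizes
keep a ten-seed recovery study in the minutes range on a single core while
preserving roughly the paper-scale ratio of neighborhood scale to sampled
extent and the 5,000–6,500-pair regime.

## Design decisions that were genuinely open

* **Linear truth.** With an exponential true surface, even an oracle model
  (true variables, known folds) correlates only ~0.5–0.6 with the truth on
  the Pearson scale, because tree predictions of a bounded response cannot
  reproduce a heavy right tail. The linear form is equally defensible as a
  ground truth and keeps the recovery comparison meaningful.
* **GP allele fields rather than monotone clines.** A monotone logit cline
  crosses zero in the correlogram near half the sampled extent regardless
  of its steepness, so a declared neighborhood scale would be
  uninterpretable; stationary fields with a finite correlation length put
  the crossing where the scale says.
* **One-SE acceptance in forward selection** (see *The model*): a bare
  strict-improvement rule admits several noise layers per run through the
  corridor-fingerprint channel.
* **Single-direction kernels.** Kernels spread from source points outward;
  no symmetrization over directions is attempted.

## Limitations

* Pairwise observations are treated as independent by the loss function;
  spatial cross-validation mitigates but does not remove the dependence
  (no MLPE or mixed-effects correction is attempted).
* Endpoint sharing between training and test pairs is intrinsic to
  leave-one-cluster-out CV on pairwise data. In synthetic experiments this
  lets white-noise layers carry a small amount of genuine cross-validated
  signal; with the one-SE rule a noise layer still occasionally enters the
  selected set, and the second of two strongly collinear true drivers
  (colluvial vs. slope at r ≈ 0.87) often adds no detectable increment, so
  driver recovery should be read as "at least one of a collinear pair plus
  independent drivers", not as exact support recovery.
* Transect means compress a corridor to one number per layer; features
  narrower than the buffer (roads) are diluted, and their fitted marginal
  sign can be dominated by sampling geometry (roadside collection makes
  road coverage a proxy for short, within-valley pairs).
* Planar coordinates only; no geodesic corrections. Circuit-theory
  (random-walk) connectivity is out of scope.
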