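---
title: "Inferring landscape permeability from genetic structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring landscape permeability from genetic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permscape)
```

## The problem

In fragmented agricultural landscapes, gene flow of small mammals is shaped
by the matrix of land cover between patches of preferred habitat. When
spatially explicit Bayesian clustering delineates genetic populations at fine
scales, the *location* of cluster boundaries carries information about which
land-cover classes impede movement and which facilitate it. permscape
implements a segment-based inference pipeline on top of such a clustering:

1. **Segment definition.** Within a study cell, pairwise distances between
   sample sites of the same population are pooled (populations holding a
   single site are excluded) and their median forms a distance threshold.
   For every pair of populations, the minimum-distance site pair qualifies as
   a *between-population (B) segment* when closer than the threshold — genetic
   separation despite geographic proximity implicates a barrier other than
   distance. Each multi-site population contributes exactly one
   *within-population (W) segment*: the site pair whose distance best matches
   the joining B segment's length (or a configurable fallback length,
   default 776 m, when no B segment touches the population). One W segment
   per population avoids pseudo-replication under strong spatial
   autocorrelation.
2. **Composition extraction.** Around each segment axis a rectangle of width
   3, 10, 25, 50, 100, 200, 400 or 1000 m is rasterized against a 30 m
   categorical land-cover grid of nine classes; the per-class pixel
   proportions and the mean of the modal membership probability (from a
   100 x 100 per-pixel posterior surface spanning the sites' bounding box)
   are recorded per width.
3. **Models.** Two regression frameworks relate composition to genetic
   structure, each with the eight predictors excluding agriculture (which is
   nearly the complement of forest in this mosaic): a logistic model of
   segment category (B = 0, W = 1), and a linear model of the
   arcsine-square-root transformed mean membership probability. Stepwise AIC
   selection runs inside a nonparametric bootstrap (B = 1000 resamples of the
   segments); a variable is *selected* when retained in at least 900
   iterations. Reported are conditional coefficient means, bootstrap SEs,
   percentile CIs, percent deviance explained (logistic) and adjusted R^2
   (linear).
4. **Validation.** Within every bootstrap iteration, repeated random 20%
   subsets of its segments are scored against the iteration's own model:
   classification accuracy under the strict "probability > 0.5 is W" rule,
   and coverage of 95% t-based prediction intervals on the transformed scale.

## Statistical choices worth knowing about

- **Stepwise AIC** starts from the full model and applies the single
  add/drop move with the largest AIC decrease until no move improves it, so
  the result is a local AIC optimum and `AIC(selected) <= AIC(full)` always.
  AIC counts one parameter per included column (plus intercept, plus the
  Gaussian error variance), including aliased columns — which is why
  duplicated predictors collapse to a single survivor instead of lingering.
- **The inner fitter** is an iteratively reweighted least-squares logistic
  solver with step-halving. Step-halving matters: bootstrap resamples of
  small segment datasets are frequently quasi-separated, where plain IRLS
  can diverge. Resamples whose fit flags separation are kept (their
  predicted categories are well defined even though coefficients diverge)
  and counted in `n_nonconverged`; resamples holding a single response class
  are redrawn with bounded retries.
- **Conditional coefficient means.** Bootstrap means, SEs and percentile CIs
  are computed over the iterations where a variable was included. An
  unconditional mean would shrink estimates toward zero for variables
  retained in only part of the iterations.
- **Null deviance.** Both the analytic full-data null deviance and the mean
  of the per-resample null deviances are reported; the two differ because a
  bootstrap resample rebalances the B/W counts.
- **Permutation p-values** throughout (pairwise Weir-Cockerham F_ST, Mantel
  isolation-by-distance) use the (b + 1)/(m + 1) estimator, so p = 0 cannot
  occur. The Mantel test linearizes genetic distance as F_ST/(1 - F_ST) and
  excludes pairs with F_ST = 1, whose linearization is infinite.
- **Modal membership probability.** A segment spanning two clusters has no
  single "probability of membership" per pixel; the pipeline averages the
  per-pixel *modal* posterior (maximum over clusters), the only single-valued
  reduction defined for all pixels. A named focal cluster can be substituted.
- **Threshold scope.** The B-segment distance threshold defaults to the
  global median over all multi-site populations of the analysis set; a
  pair-scope variant (pooling only the two candidate populations) is
  available, since either reading of the rule is defensible.
- **Rectangle geometry.** Rectangles run exactly site-to-site (no end caps);
  pixel membership is by pixel center, closed on the along-axis interval and
  half-open on the perpendicular band, a deterministic raster-GIS tie-break.

## The synthetic-data generator

No genotype data are distributed with the pipeline, so every stage is
exercised against synthetic scenarios with known ground truth:

- **Land cover** is a patch mosaic grown by quota-constrained region growing
  on a coarse lattice (default 8-pixel cells), with largest-remainder
  apportionment of coarse cells to classes. Realized class fractions are
  exact at coarse-cell granularity, and patches are contiguous, so segment
  compositions vary smoothly with bandwidth. The default mix is the study
  condition: 88% agriculture, 8% forest, the remaining seven classes sharing
  4%. The default mean patch size (4 coarse cells at 8 x 8 pixels x 30 m,
  about 23 ha) reflects the small woodlots, fencerows and remnant patches of
  a fragmented agricultural basin.
- **Territories** for the true cluster partition grow from mutually distant
  seeds by cost-weighted shortest paths (igraph Dijkstra), with elevated
  traversal cost on barrier classes (default: water at 25x), so boundaries
  co-locate with barrier habitat.
- **Sites** follow the survey's stratified-random design: forest, grassland
  and water strata at 27.8% each, urban 13.9%, agriculture 2.8%
  (largest-remainder rounding; forest further stratified by patch size
  classes < 5, 5-50, > 50 ha), at most 45 sites per cell.
- **Genotypes** follow the F-model: ancestral allele frequencies are
  symmetric-Dirichlet, population frequencies Dirichlet-concentrated around
  them with concentration (1 - theta)/theta, so the drift parameter equals
  the expected Weir-Cockerham theta — a property the test suite checks by
  simulation. Twelve loci with eight alleles each emulate a polymorphic
  microsatellite panel.
- **Membership surfaces** soften the true territory map through a softmax of
  distance-to-territory, then shift the modal probability's logit by a
  habitat-composition term with configurable true coefficients plus Gaussian
  noise.

What the generator does *not* emulate: linkage, null alleles, genotyping
error, isolation-by-distance within territories, observation uncertainty of
an MCMC clustering, and spatially autocorrelated sampling effort. Green
tests on synthetic data therefore demonstrate the *procedural* correctness
and calibration of the pipeline, not field realism.

## The parameter-recovery experiment

The recovery experiment (`recovery_config()`) injects true logistic effects
of published-table magnitude — forest +2.5, grassland +8.5 — into segment
datasets of n = 70 (pooled over four independently generated cells, as field
segments pool over cells) and asks the pipeline to find them with B = 100
bootstrap iterations per scenario.

Two design points deserve explanation:

- **Class mix.** The recovery mosaic keeps agriculture dominant (60%) but
  gives forest 20% and grassland 12%. This is a power consideration fixed
  before running the experiment: a logistic slope of 2.5 at n = 70 is
  reliably detectable only when the predictor's standard deviation across
  segments is roughly 0.3; at a sub-1% grassland area share, most scenarios
  would contain almost no grassland exposure and the experiment would
  confound estimator performance with absent exposure.
- **What is scored.** Sign recovery is read off what the procedure reports:
  the conditional mean coefficients of the *selected* true-signal variables
  (a variable retained in fewer than 90 of 100 iterations reports no
  estimate, exactly as an unselected variable appears in no published
  table). Retention rates are aggregated across scenarios: the two
  true-signal variables must show the highest mean retention. Per-scenario
  retention *ranks* are noisy by construction — a slope of 2.5 on a
  predictor of sd ~ 0.3 is a Wald z ~ 2.4 signal, and the maximum over six
  dataset-lucky null variables races close to it — and that noise is a
  property of stepwise selection at this effect size, not of the
  implementation.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the pipeline at reduced sizes
chosen to exercise every code path at full fidelity: bootstraps of 25-100
iterations for unit checks and B = 100 for the recovery experiment (100
scenarios), validation with 10-100 subsample repetitions, permutation counts
of 60-999, and 50 replicate genotype simulations for the drift calibration.
Defaults in `run_config()` remain at the field-scale settings (B = 1000,
retain = 900, 1000 validation repetitions, widths 3-1000 m).

## Known limitations

- The membership surface stand-in (leave-one-out allele-frequency assignment
  plus inverse-distance-weighted smoothing) is deterministic and carries no
  posterior uncertainty; real MCMC surfaces can be slotted in through
  `read_surface()`.
- No spatial autocorrelation correction in the regressions; segments sharing
  a site are treated as independent rows, as in the motivating design.
- Least-cost corridors and resistance surfaces are out of scope; segments
  are straight rectangles.
- The Mantel test accepts either site- or population/cell-level distance
  matrices; the caller chooses the aggregation.
```
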