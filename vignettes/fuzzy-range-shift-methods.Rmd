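---
title: "Threshold-free range-shift indices: models, conventions and validation"
author: "fprs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free range-shift indices: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fprs)
```

## The problem

Species distribution models project habitat suitability as a continuous
surface — typically the logistic output of a presence-only model — on a
regular geographic grid, for a current and one or more future climates.
Turning two such surfaces into a statement like "the range will contract and
move north-east, uphill" usually requires choosing a suitability threshold
that declares each cell "inside" or "outside" the range. That choice is
arbitrary, differs between studies, and changes the answer; it is the main
obstacle to comparing range-shift projections across many species.

`fprs` avoids the threshold entirely by treating a suitability map as a
**fuzzy set**: the membership of cell $(i,j)$ in the range is its
suitability $\mu_{ij} \in [0,1]$. Everything downstream is built from three
fuzzy-set primitives on aligned grids:

* **cardinality** $c(F) = \sum_{ij} \mu_{ij}$ — the fuzzy analogue of range
  area in cells;
* **intersection** $\min(\mu^a_{ij}, \mu^b_{ij})$ and **union**
  $\max(\mu^a_{ij}, \mu^b_{ij})$ — the classical Zadeh operators.

From a current range set $F_p$, a future range set $F_f$, and a digital
elevation model, five indices summarize the projected shift:

$$I = \frac{c(F_f) - c(F_p)}{c(F_p)}, \qquad
  O = \frac{c(F_p \cap F_f)}{c(F_p \cup F_f)},$$

$$C_x = \frac{\sum \mu_{ij} X_{ij}}{\sum \mu_{ij}},\quad
  C_y = \frac{\sum \mu_{ij} Y_{ij}}{\sum \mu_{ij}},\quad
  C_z = \frac{\sum \mu_{ij} Z_{ij}}{\sum \mu_{ij}},$$

$$D_x = C_{x,\mathrm{end}} - C_{x,\mathrm{start}}, \qquad
  D_y = C_{y,\mathrm{end}} - C_{y,\mathrm{start}}, \qquad
  D_z = C_{z,\mathrm{end}} - C_{z,\mathrm{start}}.$$

$I$ is the relative change in fuzzy range area (negative = contraction),
$O \in [0,1]$ the degree of overlap (0 = disjoint, 1 = congruent), and
$(D_x, D_y, D_z)$ the displacement of the membership-weighted range center
in degrees longitude, degrees latitude and meters of elevation. On binary
maps these reduce exactly to the classical relative area change, the
Jaccard overlap, and the displacement of the ordinary centroid — the
crisp-set limit anchors the fuzzy definitions.

## Conventions the package fixes

Several points are genuinely open at this level of description; the package
resolves each one explicitly and tests the consequence.

**Overlap normalization.** "Proportion of overlap" can mean
$c(\cap)/c(\cup)$ (fuzzy Jaccard) or $c(\cap)/c(F_p)$. Only the Jaccard
form satisfies both endpoint statements — 0 for disjoint supports *and* 1
exactly when the two maps are congruent — so it is the default. The
current-normalized form (which reaches 1 whenever the future range covers
the current one) is available via
`rangeOverlap(..., convention = "current_normalized")`, and every output
row records which convention produced it.

**Fuzzy, not binary, centroid.** The centroid is always
membership-weighted; a thresholded (binary) centroid is recoverable by
thresholding upstream but is deliberately not a supported mode, since it
reintroduces the threshold problem the indices exist to avoid.

**One DEM for both periods.** $C_z$ for current and future ranges is
evaluated against the same elevation model, so $D_z$ measures the range
center moving across the terrain. Supplying per-period DEMs is an error by
construction (`computePRS` takes a single `dem`).

**Plain coordinate differences.** $D_x$ is a longitude difference in
degrees with no $\cos(\mathrm{lat})$ correction, matching the angular-degree
units of the indices; likewise cardinality is an unweighted membership sum.
A $\cos(\mathrm{lat})$ area weighting is exposed as
`fuzzyCardinality(g, areaWeighted = TRUE)` for users who want
latitude-corrected areas, but the index pipeline never uses it.

**Grid convention.** Cell $(i,j)$ (column from the west, row from the
south, 1-based) has its center at
$(x_0 + (i-\tfrac12)\,\delta,\; y_0 + (j-\tfrac12)\,\delta)$ with
$\delta$ the cell size. NoData cells are excluded from every sum, and any
cell masked in either operand of a binary operation is masked in the
result. Grids must arrive pre-aligned (checked to $10^{-9}$ degrees);
reprojection and resampling are out of scope.

## Ensemble consensus

Projection uncertainty is handled upstream by an ensemble: one member model
per combination of general circulation model and predictor set (five by
five, hence 25 members, in the design this package mirrors;
`buildEnsembleIndex()` enumerates the Cartesian product). The consensus map
is the **cell-wise median** of the members — robust to individual outlier
projections and idempotent on unanimous stacks. With an even member count
the median is the mean of the two central order statistics (the 25-member
design never exercises this; the conventional definition is used). A cell
masked in any member is masked in the consensus — the conservative choice,
since a median over a varying subset of members would not be comparable
across cells.

## Model evaluation

`maxOverThresholds()` scores a vector of predicted suitabilities against
presence/absence labels with three standard measures: rank-based
(Mann–Whitney) AUC with ties counted one half, and Cohen's $\kappa$ and the
true skill statistic TSS maximized over the 19 thresholds
$0.05, 0.10, \ldots, 0.95$. The thresholds are generated as exact integer
multiples $k/20$ so the grid never drifts in floating point. At a
threshold, a score exactly equal to it counts as predicted present — the
$\geq$ rule keeps a cell whose suitability equals the cutoff inside the
range, the convention presence-only modellers expect. AUC here assumes a
labelled presence/absence table; pseudo-absence sampling strategies are out
of scope.

## Group statistics

Index values are aggregated per genus and, by pooling genera
(`familyPool()`), per family. The significance protocol is:

1. **One-sample two-sided t tests against zero** ($\alpha = 0.05$;
   `tVsZero()`) for $I$, $D_x$, $D_y$, $D_z$ — zero is the
   no-range-shift null. Means are flagged `**` below $p = 0.01$ and `*`
   below $0.05$. $O$ is bounded in $[0,1]$ with no meaningful zero null,
   so it is summarized but not tested against zero.
2. **One-way ANOVA across scenarios** ($\alpha = 0.05$;
   `anovaScenarios()`), treating species as independent replicates within
   each scenario. Scenarios are in truth repeated measures on the same
   species; the plain one-way layout is the package's default because it is
   the conventional protocol for these tables, and it is conservative for
   between-scenario differences when species effects are positively
   correlated across scenarios. A repeated-measures alternative was
   considered and deliberately left out of the first release rather than
   shipped untested.
3. **LSD-t pairwise comparisons** ($\alpha = 0.10$; `lsdT()`), gated on a
   significant ANOVA: Fisher's least-significant-difference t statistics
   use the pooled ANOVA mean square error and its degrees of freedom.
   Results are summarized as a compact letter display built from the
   maximal cliques of the "not significantly different" relation, so
   scenarios sharing a letter never contradict a pairwise decision. A
   blocked gate yields a "not performed" result (the `/` entry in tabular
   output); `strict = TRUE` turns it into an error.

No multiple-testing correction is applied beyond the ANOVA gate, and the
standard deviation uses the $n-1$ denominator throughout. Two-sided
p-values everywhere.

## The PRS_Chart

`chartGeometry()` resolves an index record into drawing primitives and
`renderChart()`/`renderPanel()` draw them:

* the current range is a **unit circle** (thin solid black);
* the future range is a concentric circle (broad dashed blue) whose
  **drawn area** is proportional to the cardinality ratio, i.e. radius
  $\sqrt{c(F_f)/c(F_p)}$. A literal radius-proportional reading is
  available via `radiusMode = "radius"`, but the area reading is the
  default because the chart encodes $I$ as an area difference, and areas
  should therefore compare like cardinalities;
* a red **sector** of the unit circle with area fraction exactly $O$,
  starting at 12 o'clock and sweeping clockwise (a purely cosmetic
  convention);
* a blue **horizontal arrow** in the actual movement direction with length
  $1 + \log_{10} d$ chart units for a movement of $d$ degrees — so 1
  degree draws 1 unit and 10 degrees draw 2 units — and a black **vertical
  arrow** of $1 + \log_{10}(|D_z|/100)$ units, one unit per 100 m. The
  two printed anchor points (1 degree → 1 unit, 10 degrees → 2 units;
  100 m → 1 unit) are the whole contract of the log scaling; movements of
  at most 0.1 degree or 10 m fall at or below zero length and are omitted
  rather than drawn as dots, since the transform is not anchored below one
  unit.

SVG output comes from a deterministic text emitter (numbers formatted to a
fixed four decimals), so identical geometry produces byte-identical files —
a property the test suite pins with a golden comparison. PNG and PDF go
through the standard graphics devices.

## The virtual-species generator

Real inputs to this pipeline require climate layers, occurrence atlases and
fitted distribution models. For validation the package instead generates
**virtual species**: anisotropic Gaussian membership surfaces
$\mu(x,y) = p \exp\!\big(-\tfrac{(x-c_x)^2}{2\sigma_x^2}
- \tfrac{(y-c_y)^2}{2\sigma_y^2}\big)$ evaluated at cell centers
(`makeVirtualSuitability()`), over flat, uniformly sloped, or ridged DEMs
(`makeDEM()`). Gaussians are used because their continuum cardinality
($2\pi p\,\sigma_x\sigma_y$ per unit cell area) and centroid (the mode)
are closed-form, so `makeShiftPair()` can state exact expectations for the
indices: translating by $(d_x, d_y)$ and scaling both sigmas by
$\sqrt{e}$ at equal peak gives $I = e - 1$, $D_x = d_x$, $D_y = d_y$, and
$D_z = s\,d_y$ on a slope of $s$ m/degree. Truncation by the grid edge is
the only discretization bias; the generator refuses (rather than silently
biases) any configuration losing more than 0.1% of its continuum
cardinality off-grid.

What the Gaussian world does *not* emulate: multimodal or fragmented
ranges, spatially autocorrelated model error, membership saturation at 1
over core habitat, and coastline-shaped masks. Passing recovery tests
therefore demonstrates that the index arithmetic is correct and unbiased on
smooth unimodal surfaces — not that any particular ecological projection is
right.

Evaluation samples (`makeEvalSample()`) draw scores from two Beta(2,2)
distributions rescaled to $[0, 1-s]$ (absences) and $[s, 1]$ (presences),
so the class means differ by exactly the separation $s$ and the supports
become disjoint for $s > 0.5$ (forcing AUC = 1), while $s = 0$ makes the
classes exchangeable. `growingSeasonAridity()` houses the bioclimatic
aridity definition used with these models:
$\ln(\sum \mathrm{PET}_m / \sum P_m)$ over months with mean temperature
strictly above 0 °C. Months at exactly 0 °C are excluded (the definition
says *greater than*), and PET is an input — no evapotranspiration model is
fitted.

## Numerical choices and validation scale

Cardinality sums run through R's long-double accumulator, which holds
$10^6$-cell grids stable to well below $10^{-9}$ relative error (tested).
The threshold grid uses integer arithmetic; the chart emitter formats with
fixed precision; all generators are deterministic given their parameters
and seed.

The test suite validates at these problem sizes, chosen to exercise each
property at realistic resolution while staying quick to run:

* recovery experiments on 240 × 180 grids at 5-arcminute (1/12°) cells —
  the analysis resolution typical of national-scale projections — over a
  3 × 3 design of shift (0–2°) × expansion (0.5–2), plus a 300 m/°
  sloped-DEM composition;
* oracle equivalence on 1000 random AUC samples of size ≤ 12 against
  exhaustive pair counting, and 200 random ANOVA layouts of total n ≤ 30
  against a direct sums-of-squares oracle;
* type-I calibration of the t test at 10,000 Gaussian-null replicates
  (empirical rate within 0.05 ± 0.01);
* the fuzzy-set identities ($c(\cap)+c(\cup)=c(a)+c(b)$, overlap symmetry,
  scaling invariance) over 1000 random grid pairs, and translation
  equivariance over 50 random translations.

## Known limitations

* Raster I/O is plain-text ESRI ASCII grid only; the format carries no CRS
  metadata, so geographic decimal degrees are assumed (with a message).
  Grids must be delivered pre-aligned — there is no reprojection,
  resampling, or multi-resolution support.
* Distribution-model fitting, downscaling of climate layers, and
  occurrence-data preparation are all upstream of this package; it consumes
  suitability rasters and labelled score tables.
* Indices are planar-degree quantities: no geodesic distances in
  kilometers, and no latitude-area correction in the default pipeline.
* The statistics module offers only the fixed protocol described above —
  no mixed models, bootstrap intervals, or spatial autocorrelation
  corrections.
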