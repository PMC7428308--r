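---
title: "Methods: quantifying cerebrocerebellar mossy fiber maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cerebrocerebellar mossy fiber maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mossymap)
```

## Scope and data model

`mossymap` analyses mono-trans-synaptic tracing data of the disynaptic
cerebrocerebellar pathway (cortex → precerebellar nucleus → cerebellar
granule cell layer). The unit of observation is a labeled mossy fiber
terminal: a 3D point (µm) annotated with animal, cortical origin (M1,
S1, PPC, V1, A1, AuD), cerebellar side relative to the injection,
lobule, and AldoC stripe. A companion table counts labeled
precerebellar cells per (animal, nucleus, pontine/extra-pontine
category). Wet-lab procedures, imaging and point-marking are out of
scope; tables of annotated points are the input.

The coordinate frame is a right-handed section-stack frame: x
mediolateral (signed, midline at 0), y dorsoventral, z rostrocaudal.
In sectioned material the z of a terminal is section index × section
thickness (40 µm), so cross-section distances are a modelling choice;
all spatial analyses accept `planar = TRUE` to restrict distances to
the section plane. The default is fully 3D.

## Atlas and normalization

The atlas stores the 16 lobules with total volumes from 16.4T MRT
measurements (e.g. V(I) = 0.14 mm³ … V(Fl) = 0.79 mm³) at their
printed precision, with no unit conversion inside the atlas. Terminal
density represents each hemisphere separately:

$$D = \frac{N_{MF}}{V_i \cdot \tfrac12}\ \ \text{(terminals per mm}^3\text{)}.$$

Injection-site cores are treated as elliptic cylinders,
$V = \pi a b h$ (a: mediolateral radius, b: rostrocaudal extent, h:
dorsoventral height, all mm).

Gross divisions follow the functional grouping: lobules I–VIII vermis;
Sim, crus I, crus II, PM, Cop hemisphere; IX, X, PFl, Fl
vestibulocerebellum. Anatomically IX and X are vermal lobules, and some
summaries group them that way; because the functional text and the
division-level percentages treat them as vestibulocerebellar, the
default map puts them there and the division column of the atlas is an
ordinary configurable field.

Percentages are computed within each (animal, origin) and then
averaged across animals with s.e.m.; pooled-count percentages are a
separate explicit mode (`percent_of_total()` /
`cell_category_split()`), used for the pooled pontine vs extra-pontine
cell split. Whether lobule-level percentages should be normalized over
both sides combined ("% of total cerebellar input") or within each
side is genuinely ambiguous for some published displays; both modes
are implemented (`normalization = "combined"` is the default,
`"per_side"` the alternative) and every result table records which was
used. Ratios and correlations are computed per animal first and then
summarized — never on pooled points — except where pooling is the
stated procedure (precerebellar cell totals).

The laterality contrast compares per-animal ipsi:contra ratios of the
primary group (M1, S1, V1, A1) against the association/secondary group
(PPC, AuD) with a plain two-sample t-test. The variance model of the
original test is unstated; pooled variance is the default and a Welch
variant sits behind `variance_mode = "welch"`.

## Co-innervation classifier

Counts are pooled across animals per origin. Per (lobule, side):

1. *Input floor.* The lobule must receive strictly more than
   `input_floor` (default 4%) of that side's total input, else
   `excluded`.
2. *Dominance.* The dominant origin has the largest within-lobule
   share (count share by default; a density-based mode exists and is
   equivalent within a lobule). Ties are flagged and broken
   lexicographically, never silently.
3. *Multimodality.* Let S be the combined within-lobule share of all
   non-dominant origins. With at least `min_origins` (default 2)
   distinct non-dominant origins present, the lobule-side is `high` if
   S > `multimodal_threshold` (default 15%), else `moderate`.

Both thresholds are strict inequalities: equality at the floor
excludes, equality at 15% yields `moderate`. The stated rule ("more
than 15% from at least two regions in addition to the dominant one")
admits a second reading — each of two non-dominant origins
individually above 15% — implemented behind `share_mode = "each"`; the
combined-share default reproduces the intended partition on shares
consistent with the published summaries (e.g. a lobule with a 96%
dominant origin and two minor origins sharing 4% is moderately
multimodal). Shares entering the 15% rule are normalized within the
lobule, not within the side total. Lobule-sides above the floor but
with fewer than `min_origins` non-dominant origins cannot be
classified as moderately multimodal; they are reported `excluded` with
`reason = "too_few_origins"` so the two exclusion causes stay
distinguishable.

The classifier is invariant to uniform count rescaling, monotone in
both thresholds, and on synthetic studies with planted mixing
proportions reproduces the analytically forced labels whenever
per-lobule counts are large enough that sampling noise cannot cross a
threshold (checked at counts ≥ 500 over 20 seeds).

## Stripe model

A stripe map lists, per lobule and rostrocaudal bin, strictly
increasing mediolateral boundaries with alternating AldoC+/AldoC−
labels. Assignment uses half-open intervals [left, right): boundary
points are assigned deterministically to the stripe on their right,
and points outside the mapped extent (or in unmapped lobules) are
`unassigned`. Assignment is translation-equivariant and total. The
rostrocaudal bin structure abstracts the few coronal levels at which
stripe boundaries are typically charted; bins default to infinite z
extent when a single chart covers the lobule. Cross-animal consistency
of stripe-resolved (or lobule-level) frequency vectors is validated by
pairwise Pearson correlation within each origin group; enrichment in
one stripe class is tested with an exact binomial test against the
area expectation (AldoC+ extent / mapped extent), with degenerate maps
(expected share 0 or 1) flagged instead of tested.

## Point-pattern statistics

**Pairwise distances.** All pairwise Euclidean distances at or below
500 µm are split into same-label and cross-label pairs relative to a
seed origin (self-pairs excluded), summarized as mean ± s.e.m. over
pairs, and compared with the two-sample t-test. Pairs sharing a point
are not independent, so the t-test here is a descriptive screen (as in
the original procedure), not an exact test; when either side has fewer
than two pairs the statistic is reported as NA. The default
granularity is per lobule, pooled across animals, configurable by
pre-filtering the event table.

**k-nearest neighbors.** For each event the k = 5 nearest other events
are indexed by origin, with ties broken by (distance, stable input
index) and exact k (no tie expansion); proportions are aggregated per
seed label and sum to one.

**Ripley's K.** For n points in an axis-aligned cuboid of volume V
with intensity λ̂ = n/V:

$$\hat K(t) = \frac{V}{n(n-1)} \sum_{i \ne j} w_{ij}\, \mathbf 1[d_{ij} \le t],$$

with w ≡ 1 (uncorrected) or the translation correction
$w_{ij} = V / \prod_a (L_a - |\Delta_a|)$ for cuboid side lengths L.
The uncorrected estimator doubles as the brute-force oracle; the
translation correction is the analytic, standard choice for box
regions (the correction used by the original GUI tool is not restated
there, so translation is this package's declared choice). Under CSR,
E K(t) = (4/3)πt³; a guard rejects t beyond the shortest region side
where the correction degenerates. The region for observed data is the
bounding cuboid of the points (optionally padded) — lobule-shaped
regions are not modelled.

**CSR Monte Carlo test.** `n_sim` (default 100) CSR patterns with the
same n and region are simulated; the default p-value is the
distribution-free empirical rank
$(1 + \#\{K_{sim} \ge K_{obs}\})/(n_{sim}+1)$ (one-sided, clustered
alternative; never anti-conservative), reported alongside a two-sided
version (doubled smaller tail, capped at 1). A `kde_tail` mode
reproduces the density-based tail-area reading (Gaussian kernel,
Silverman bandwidth). Evaluation distance defaults to t = 60 µm.
Fewer than 20 simulations are rejected as too coarse. No
multiple-testing correction is applied across lobules (per-lobule
p-values are the reported quantity); Benjamini–Hochberg can be applied
downstream if desired.

## Synthetic study generator

The generator defines the study conditions under which the pipeline is
validated:

- **Design.** Three animals per cortical origin. Per-origin terminal
  totals default to the reported study scale (10⁴ for M1 and S1, 580
  for AuD; the unreported origins are set to plausible intermediates:
  3000 PPC, 2000 V1, 1500 A1).
- **Laterality.** Contralateral fractions 0.85 (S1), 0.74 (M1, V1,
  A1 — matching the primary-group ipsi:contra ratio ≈ 0.35) and 0.58
  (PPC, AuD — association ratio ≈ 0.73). Per-animal fractions get Beta
  jitter (concentration 50, ≈5 pp sd), in line with the reported
  ±2–3 pp s.e.m. over three animals.
- **Lobule mixing.** A row-stochastic origin × lobule matrix
  qualitatively matching the reported biases (M1 → crus II/Sim/PM,
  S1 → crus I/PM/Cop/IV-V, V1 → PFl, A1 → vermis, …). Animal-level
  mixing is a Dirichlet perturbation with one concentration parameter
  (default 30, giving per-lobule percentage s.e.m. of roughly 3–7 pp
  across three animals at mid-size shares, the order seen in the
  study; `Inf` disables variability).
- **Geometry.** No per-lobule shapes are published; each lobule-side
  is an axis-aligned cuboid of volume V_i/2 with mediolateral :
  dorsoventral : rostrocaudal aspect 2:1:1, sides abutting the midline
  and lobules staggered along z. This keeps Ripley regions analytic.
- **Clustering.** Optional Thomas-type process (Poisson parents,
  Poisson offspring, isotropic Gaussian displacement). Thomas rather
  than Matérn for its closed-form expected count
  λ_parent · V · μ_offspring; offspring falling outside the region are
  re-displaced (resample-inside), which keeps the count distribution
  simple at the cost of slightly inflating interior intensity near
  edges. Within-lobule inhomogeneity parameters are not reported
  anywhere, so clustering defaults are this package's choice and off
  by default.
- **Stripes.** A synthetic stripe map with equal AldoC+/− extents per
  lobule; `stripe_bias` is the probability a terminal falls in an
  AldoC+ stripe (0.5 = area-proportional), applied by resampling the
  mediolateral coordinate within the chosen stripe class.
- **Cells.** Per (animal, origin), the mossy-fibers-per-cell ratio is
  drawn as Normal(50, 12) (truncated at 5) matching the reported
  between-animal dispersion, the cell count set to terminals/ratio,
  and cells split 73% pontine vs 27% extra-pontine across named
  nuclei. Because animals with fewer cells contribute larger ratios,
  the *pooled* terminals/cells ratio is slightly below 50 (Jensen's
  inequality); recovery is therefore assessed on the mean of
  per-animal ratios, which is the quantity the reported 50 ± 12
  describes.

Everything is a pure function of (config, seed); per-animal streams
derive deterministically from the single study seed. The generator
emulates counts, laterality, mixing, clustering and stripe occupancy —
it does **not** emulate section distortion, registration error,
lobule-shaped boundaries, or spatially correlated mislabeling, so
passing tests demonstrate correctness of the estimators under the
stated model, not robustness to those artifacts.

## Numerical choices and degenerate inputs

- Percentage rows sum to 100 within 1e-9; density round-trips
  D · V_i/2 = N to float precision.
- Pearson correlations use the product-moment formula with the
  t-transform p-value (n − 2 df); constant vectors and n < 3 are
  errors, not NA.
- Zero contralateral counts make laterality ratios undefined (error),
  as do empty pair sets in the distance analysis and zero variance in
  both t-test samples.
- Dominance ties in the classifier are flagged and broken by origin
  name; stripe boundaries must be strictly increasing or the map is
  rejected.
- CSR p-values are never 0: the +1 rank convention bounds them below
  by 1/(n_sim + 1).

## Problem sizes

The test suite and the acceptance script keep simulations at desk
scale as the package's own validation choices: brute-force K
comparisons at n ≤ 50 (100 instances), CSR-unbiasedness at n = 300
over 200 seeds, type-I calibration over 200 CSR replicates at n = 100
with the default 100 simulations each, power against a dense Thomas
alternative (σ = 20 µm, ≈450 points in a 1 mm cube) over 50 seeds,
classifier recovery on 20 planted studies of 10⁴ terminals per origin,
and parameter recovery over repeated full-scale default studies
(≈8 × 10⁴ terminals each). These sizes give Monte Carlo standard
errors comfortably inside the asserted tolerances.

## Known limitations

- Cuboid lobule geometry and bounding-box CSR regions are
  simplifications; with real lobule shapes the translation correction
  no longer applies exactly and a different edge correction would be
  needed.
- The pairwise-distance t-test ignores pair dependence (descriptive
  use only).
- The stripe map is an input abstraction: no image-based stripe
  segmentation is attempted.
- Terminal counting is direct (marked rosettes); no stereological
  correction is applied.
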