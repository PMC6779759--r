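---
title: "Methods: assemblage-level colour diversity along an elevational gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assemblage-level colour diversity along an elevational gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the analysis model

Ectotherm colouration is under thermal selection: darker (lower
brightness, higher saturation) individuals absorb heat faster and are
favoured in colder environments — the thermal melanism hypothesis. If
cold environments constrain moth assemblages toward a darker region of
colour space, the *diversity* of colour traits within an assemblage
should fall with elevation. `mothcolr` implements the full analysis
chain needed to test this at the assemblage level:

1. **Specimens to features.** Each specimen image is reduced to a
   nonnegative feature vector encoding colour (hue x saturation,
   brightness, and saturation x brightness histograms; per-part mean S
   and V) and shape (a radial profile of the segmented outline). The
   trait distance between two species is the cosine distance of their
   representative vectors; a species' representative image is the one
   sampled closest to its mean elevation.
2. **Assemblages.** Species are grouped into half-open 100-m bins of
   species mean elevation; empty bins are dropped. Within-assemblage
   diversity is the mean cosine distance over all unordered species
   pairs, regressed on the bin midpoint by Gaussian OLS with an
   F statistic on (1, n-2) degrees of freedom.
3. **Uncertainty.** Two resampling procedures: the *pairwise bootstrap*
   redraws, per repeat and assemblage, m pairwise distances with
   replacement (m defaults to the pair count of the smallest
   assemblage, equalizing effective sample size) and refits the trend;
   the *family bootstrap* redraws four families with replacement per
   assemblage and pools their species, a grouped control for taxonomic
   composition. Both report 2.5/97.5 percentile intervals.
4. **Variance partitioning.** The feature vectors of *all* individual
   images are projected to a one-dimensional trait axis by classical
   MDS on cosine distances (one common axis over the regional pool, so
   assemblage variances are comparable). Per assemblage we compute
   T_IC/IR, the ratio of within-assemblage individual variance to
   regional variance (low = external filtering), and T_IP/IC, the
   pooled within-species variance over the within-assemblage variance
   (low = internal filtering). Population = species within an
   assemblage; individual = one specimen image. Variances use
   denominator n, under which the law of total variance holds exactly
   and is asserted on every computation.
5. **Melanism indices.** After HSV conversion, B = Bf/Bw and S = Sf/Sw
   compare the resting-exposed parts (body + forewings) to the whole
   specimen; assemblages take unweighted species means. Hue is never
   averaged anywhere in the pipeline — as a circular, categorical
   quantity its mean is not meaningful.
6. **Path model.** The causal chain temperature -> relative brightness
   -> log T_IC/IR is fit as sequential standardized OLS edges; for a
   recursive chain with single predecessors these coincide with the
   structural-equation estimates, each coefficient equalling a Pearson
   correlation. No global fit index (chi-square, CFI) is produced —
   a documented limitation of the sequential formulation.
7. **Colour-space simulation.** Independently of any specimen data,
   colours sampled uniformly in HSV regions with a brightness ceiling
   and saturation floor show that a darker region yields a smaller
   trace of the RGB covariance matrix, the mechanism by which thermal
   constraint reduces measurable colour diversity.

## The synthetic specimen generator

No external image corpus is required: `generate_dataset()` renders
procedural moths (body ellipse, two forewing and two hindwing
quadrilaterals, optional spots and stripes) on a uniform light-grey
background, with ground-truth part masks, under a fully seeded RNG.
The generator's defaults are the study conditions the rest of the
package assumes:

* **Gradient:** species mean elevations span 0–2500 m; temperature is
  exactly `sea_level_temp - lapse_rate * elevation/1000` (23 °C, 6.5
  °C/km); precipitation is a noisy hump over the gradient with no
  planted effect on colour.
* **Melanism:** mean species brightness V falls by 0.2 per km and mean
  saturation S rises by 0.1 per km (clipped to [0.05, 0.95]).
* **External filtering:** the between-species SD of the filtered HSV
  channels shrinks by 30 % per km (floored at 5 % of its sea-level
  value). Between-species SDs default to 0.12 (S and V) and 40°(hue);
  within-species SDs to 0.03 and 4°. These magnitudes are free
  parameters of the artifact — chosen so that within-species scatter
  is clearly smaller than between-species scatter, as expected for
  species-diagnostic wing colouration — and are not calibrated to any
  real collection.
* **Hindwing coupling:** hindwings track the species base colour only
  partially (`hindwing_couple = 0.4` toward the configured anchor,
  plus offsets +0.18 in V, −0.05 in S). Because melanism is expressed
  fully on the exposed body and forewings but only partially on the
  concealed hindwings, the relative indices B = Bf/Bw and S = Sf/Sw
  acquire the planted elevational trends; with a purely additive
  offset the ratio indices would be flat or even inverted.
* **Hue** is wrapped-normal per species and carries no elevational
  signal, mirroring its exclusion from the averaged indices.
* **Sampling regime:** `paper_regime_config()` reproduces the study's
  structure — six empty 100-m intervals leaving 19 occupied bins, at
  least 11 species per occupied bin with one bin held at exactly 11
  (so the smallest assemblage contributes choose(11,2) = 55 pairwise
  distances), 250 species with 2–3 images each. In this stratified
  regime each specimen's sampled elevation is drawn from a truncated
  normal (SD 150 m) bounded by its species' home bin, so the species'
  observed mean elevation cannot drift into a configured gap; in the
  free regime (`min_species_per_bin = 0`) sampling is truncated only
  by the overall range.
* **Families** are assigned round-robin (8 by default) so every
  assemblage contains several families and the four-family bootstrap
  is always feasible.

What the generator does *not* emulate: photorealistic wing texture,
real moth morphometrics, collection effort or light-trap bias,
heterogeneous photographic backgrounds, and phylogenetic signal in
colour (families are colour-neutral labels). Passing tests therefore
demonstrate that the statistical machinery recovers known planted
structure through the full image pipeline — not that the biological
conclusions hold for any particular real fauna.

## Segmentation

`cluster_segment()` is a deliberately classical stand-in for neural
background removal, in three deterministic stages: two-means on RGB
with fixed initialization (darkest/lightest luminance decile means),
border-majority background identification (ties break toward the
lighter cluster), and two 3x3 majority smoothing passes for spatial
continuity. Plain two-means proved insufficient on its own: a specimen
with both dark forewings and pale hindwings presents three colour
modes, and the pale wings are absorbed into the light background
cluster. We therefore added a *background-consistency reclamation*
step between clustering and smoothing: since the imaging protocol
guarantees a uniform background, any background-cluster pixel whose
colour departs from the border-estimated background colour (median
border RGB) by more than `max(0.06, 8 * MAD)` is flipped to
foreground. `repair_mask()` then keeps the largest connected component
and fills interior holes (flood fill from the border defines the
exterior), fixing background-coloured wing spots and satellite stains;
it is idempotent. Quality is scored by mean intersection-over-union
over the labels present in either mask.

Part segmentation of real images is intentionally out of scope — the
five-part masks come from the generator's ground truth; the clustering
stage handles whole-specimen background removal only.

## Numerical choices and edge cases

* Cosine distances are clamped at 0 against roundoff; on nonnegative
  embeddings they lie in [0, 1]. External signed embeddings widen the
  range to [0, 2]; nothing downstream assumes the narrower bound.
* Classical MDS truncates negative eigenvalues (cosine distances need
  not be Euclidean) to zero. Axis signs are fixed by nonnegative
  correlation with elevation when supplied, else by making the
  largest-magnitude loading positive — pure reporting conventions; all
  T-statistics are invariant to affine rescaling of the axis, which is
  asserted by test.
* The elevation regressor is ridge-penalized (default lambda = 1)
  because the embedding dimension (default 256) can exceed the image
  count; species predictions average per-image predictions.
* Assemblages with fewer than two species cannot contribute a
  diversity value and are excluded from trend fitting. Diversity is
  regressed on the bin *midpoint*; the choice affects only the
  intercept.
* Ties in representative-image selection break to the
  lexicographically smallest image id.
* Percentile (not BCa) bootstrap intervals are reported. The bootstrap
  refits every statistic (intercept, slope, R², F) per repeat.
* A known calibration limitation, measured by the test suite's null
  experiments: resampling *pairwise distances* treats the
  choose(n, 2) distances of an assemblage as independent draws,
  which omits the between-species component of the sampling variance
  of a mean pairwise distance (the dominant term of the corresponding
  U-statistic variance). The resulting percentile interval for the
  diversity–elevation slope is therefore anti-conservative under the
  null, while the t-based OLS intervals used for the T-statistic,
  brightness and path coefficients are nominal. We keep the
  pair-resampling design because it is the procedure this pipeline is
  specified to implement; a species-level bootstrap would be the
  calibrated alternative.
* The same null experiments show that the brightness -> log T_IC/IR
  path edge covers zero less often than its nominal rate even with all
  planted slopes switched off: the assemblage mean brightness index
  and the within-assemblage trait variance are computed from the same
  specimens through a nonlinear feature map, so they remain weakly
  (negatively) associated under the generator's null. A zero-slope
  configuration is a null for every *elevational* trend, but not for
  every cross-statistic association.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
250 species / roughly 600 images of 64x64 pixels, with 5000 pairwise
and 1000 family bootstrap repeats for single analyses and 500 repeats
inside the 100-seed null-coverage experiment; segmentation quality is
scored on 50 rendered specimens and the colour-space simulation uses
10^4–10^5 Monte-Carlo samples. These sizes were chosen so a complete
analysis is a desk-scale computation (seconds per run) while every
planted effect is still comfortably detectable.
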