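---
title: "Methods: quantifying RNA accumulation at the invasive front"
author: "frontfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying RNA accumulation at the invasive front}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontfish)
```

## The biological problem

During collective 3D invasion, cancer cell strands are led by "leader"
cells whose front cytoplasm protrudes into the extracellular matrix.
Specific transcripts (e.g. *RAB13*, *NET1*) accumulate at this invasive
front, while a diffusely distributed control RNA (*RHOA*, or *GAPDH* in
tissue) detected in the same cells does not. frontfish implements the
image-quantification chain with which such front bias is measured and
tested, together with the companion measurements used in the same studies:
the spheroid-invasion "complexity" metric, perimeter intensity profiles of
matrix stains relative to the protrusion tip, the Peripheral Distribution
Index (PDI) of single cells, and GA-content scans of 3'UTR sequences used
to position antisense morpholinos.

## The core statistic: normalized front distance

The invasive and nuclear edges of a leader cell are drawn manually (the
package reads them from a small JSON dialect, in pixel or micrometer
units). For each detected RNA spot $i$, the minimum Euclidean distances to
the invasive edge ($Id_i$) and to the nuclear edge ($Nd_i$) are computed
by segment-wise projection onto the polylines. The local protrusion length
is $L_i = Id_i + Nd_i$, and the normalized distance

$$d_i = \frac{Id_i}{Id_i + Nd_i} \in [0, 1]$$

is 0 on the invasive edge and 1 on the nuclear edge. Per cell and per RNA
species, the arithmetic mean $\bar d$ of the $d_i$ is the unit of
analysis. Design notes:

* **Distance to the polyline, not to a line or along a geodesic.** The
  edges are short open transects of the front cytoplasm; point-to-polyline
  Euclidean distance is the simplest faithful reading and is what the
  dense-sampling oracle in the test suite verifies to $10^{-6}$ µm.
* **Per-spot normalization.** $L$ is indexed by spot; normalization
  happens before averaging. The alternative — average raw distances, then
  normalize once per cell — is available via
  `summarize_cell(normalization = "average_then_normalize")` but is not
  the default, because the per-spot form keeps every $d_i$ in $[0,1]$ with
  a scale-free interpretation even when the protrusion tapers.
* Spots with $L$ below 0.1 µm (edges effectively touching) carry no
  positional information and are dropped with a warning.
* Swapping the two edges maps $d \mapsto 1-d$, and rescaling all
  coordinates leaves every $d$ unchanged; both are asserted as invariants.

Densities of per-cell means are estimated on $[0,1]$ by a Gaussian kernel
with **boundary reflection** at 0 and 1 (the estimator used for bounded
supports), bandwidth by Silverman's rule unless overridden, renormalized
to integrate to 1 by the trapezoidal rule. If all means coincide the
estimator falls back to a narrow (0.001) kernel with a warning rather than
failing.

### Statistical comparisons

* Target vs internal control within the same cells: two-sided **Wilcoxon
  signed-rank** on per-cell differences, paired strictly by `cell_id`
  (exact null for $n \le 25$ without ties, normal approximation with
  continuity correction otherwise, zero differences dropped). The test
  statistic and exact p are verified against full sign-assignment
  enumeration in the suite.
* Across conditions: one-way **ANOVA with Dunnett's** many-to-one
  contrasts (via multcomp), or **Kruskal–Wallis with Dunn's** tie-corrected
  many-to-one $z$ tests, Bonferroni-adjusted over the family. Dunn's test
  is implemented in the package because no installed package provides it;
  when every observation is tied the $z$ statistic is defined as 0 (no
  evidence of a shift, adjusted p = 1). Null calibration (200 replicates,
  $n = 30$/group) keeps the per-family type-I error within 0.07 at nominal
  0.05 in the acceptance suite.

## Spot detection

The studies' spot detector is not specified, so frontfish provides the
standard single-molecule choice: a **single-scale Laplacian-of-Gaussian**
detector. The response is $-\sigma^2 \nabla^2 (G_\sigma * I)$ with
replicate boundaries; candidates are 3×3 local maxima above a threshold of
$k$ robust standard deviations (MAD) of the response (default $k = 5$),
restricted to an optional mask; greedy non-maximum suppression enforces a
minimum separation (default $2\sigma$); positions are refined by per-axis
quadratic interpolation (offset clamped to half a pixel). Ties are broken
by response, then $(y, x)$ order, so detection is deterministic. Because
the LoG is linear and annihilates constants, detection is invariant to
intensity rescaling (with the relative threshold) and to additive offsets
— both asserted as invariants. Dense-cluster decomposition and 3D fitting
are out of scope; consequences are discussed below.

## Synthetic scenes

The generator makes every stage testable without raw images. A scene is a
tapering front cytoplasm: a straight invasive-edge transect at $d = 0$ and
a straight nuclear-edge transect at $d = 1$, `protrusion_length_um` apart,
the region widening from 60% of `protrusion_width_um` at the tip to the
full width at the nuclear end, joined to a round cell body containing a
disk nucleus. Per species, spot normalized distances are i.i.d.
**Beta($\alpha, \beta$)** draws mapped onto the protrusion axis — the Beta
family is supported on $[0,1]$ exactly like $d$ and has the analytic mean
$\alpha/(\alpha+\beta)$ that the recovery tests pin. Two deliberate
choices keep the recorded ground truth exact:

* the edge transects are straight (zero curvature), and
* transverse placement is uniform within the central band spanned by both
  transects,

so the perpendicular foot of every spot lies on both polylines and the
recorded `d_true` equals the Beta draw identically. A curved cap or
full-width placement would decouple the generative parameter from the
measured quantity and leave the recovery tests without an analytic anchor.

Rendering places an isotropic Gaussian PSF of unit integral times an
amplitude at each spot over a constant background, with additive Gaussian
read noise (Poisson realism is intentionally not modeled; the tests need
controllable SNR, not camera physics). All randomness flows from the
single `seed`, and equal configs are bit-identical.

Default conditions (changeable per call, chosen once as realistic study
conditions): pixel 0.1 µm and PSF sigma 0.15 µm (a 63×/1.4 oil confocal
class instrument), protrusion 25 × 10 µm, background 100 counts, read
noise 10, peak SNR 8, 25 spots per species, target bias Beta(2, 6) against
a uniform Beta(1, 1) internal control. The spot density deserves a note:
single-molecule quantification assumes the **sparse regime** in which
diffraction-limited spots are individually resolvable. At these optics,
pairs closer than ≈ 0.4 µm merge into one LoG maximum; because a
front-biased species crowds hardest near the invasive edge, overcrowding
produces a *selection* bias (merged front spots go missing and the
recovered mean $d$ drifts up) even though localization itself is unbiased.
At 25 spots per species ≈ 7% of spots are unresolvable and the recovery
remains unbiased within counting noise; the generator therefore defaults
to this sparse regime, which is also the regime in which the laboratory
method itself is quantitative. What passing recovery tests show is that
the pipeline is faithful *for resolvable data*; they do not certify
behavior on densely packed transcripts, which would require cluster
decomposition (a non-goal).

Spheroid silhouettes are built directly as simple star-shaped polygons: a
256-gon disk body with radial constant-width strands at seeded angles
(overlapping strand roots are merged). The exact polygon perimeter and
area are recorded as ground truth next to the rasterized mask, so the
raster measurement chain can be checked against shoelace/segment-sum
values at $10^{-9}$.

## Spheroid complexity

$$\text{complexity} = \frac{P^2}{4\pi A}$$

the reciprocal isoperimetric quotient: 1 for a circle, $4/\pi$ for a
square, larger for branched silhouettes. Segmentation is Gaussian
smoothing → Otsu → largest connected component → hole filling. Perimeter
and area come from the sub-pixel iso-0.5 contour (marching squares via
`contourLines`) of the mask indicator after a light Gaussian smooth
(sigma 1 px). The smoothing matters: the raw binary contour walks the
pixel staircase and overestimates a smooth perimeter by ≈ 5%, which enters
complexity squared; with the smooth the r = 100 px disk measures within
1.2% of 1 (documented discretization tolerance: 2% for shapes ≥ 50 px
across, with agreement between raster and exact-polygon complexity within
3% for shapes ≥ 100 px). Tiny objects whose smoothed indicator never
reaches 0.5 fall back to the raw contour; a single-pixel mask yields its
half-unit diamond ($A = 0.5\,\mathrm{px}^2$). Masks touching the border
are closed against a zero frame and flagged. Because the upstream tool
used in the original studies does not state its perimeter estimator,
absolute complexity values are comparable only within one estimator;
relative/ordinal statements (more branches → higher complexity, strictly,
as asserted on exact polygons) are the claims this implementation makes.

## Perimeter profiles and the confidence band

The front-cytoplasm contour is resampled at 0.5 µm arc-length steps; at
each sample the mean intensity over a disk of radius 1 µm (rotation
invariant, unlike a normal-line transect) is recorded against the signed
arc length from the protrusion tip (tip snapped to the nearest sample;
sign follows traversal direction, so reversing the contour mirrors the
profile). Aggregation across cells optionally normalizes each profile by
its own mean (default, removing per-cell exposure differences - the
aggregate is then invariant to any per-cell intensity rescaling),
interpolates linearly onto a common grid, truncates grid points with
fewer than 3 contributing cells, and reports the mean with a pointwise
t-based 95% confidence band (descriptive, no multiplicity adjustment).

## Peripheral Distribution Index

The cited index calculator is not reimplemented feature-for-feature; the
package pins the one property its output is defined by — **a diffuse
signal scores 1** — with an explicit moment convention:

$$\mathrm{PDI} = \frac{\sum_j w_j\, r_j^2 \,/\, \sum_j w_j}
{\overline{r^2}_{\text{uniform cytoplasm}}}$$

where $r_j$ is the distance of signal (pixel intensities or spot
coordinates) from the **nucleus centroid**, and the denominator is the
same second moment for a uniform distribution over the cytoplasm (cell
mask minus nucleus mask). Uniform signal gives exactly 1 by construction;
peripheral enrichment gives > 1, perinuclear concentration < 1; the index
is invariant to intensity scaling and rigid motion and strictly increases
as mass moves radially outward (all asserted on synthetic annulus
families). Values are self-consistent within this convention but may
differ in detail from other PDI implementations.

## GA-content scan

`ga_window_profile` slides a fully contained window (default 30 nt, step
1) over the sequence and reports $100 (\#G + \#A)/w$ per window, with
$L - w + 1$ values; U is treated as T, N occupies positions without
counting, invalid characters error with their (0-based) position.
`call_ga_rich_regions` turns supra-threshold runs into 0-based half-open
sequence intervals, merging overlaps — the support for placing antisense
morpholinos against GA-rich localization elements. Output coordinates are
0-based half-open (BED-like); the step-1 sliding window is assumed.

## Numerical choices and degenerate inputs

* Coordinates are (x, y) µm, origin at the top-left pixel corner, pixel
  centers at half-integers; rasters are indexed [row = y, col = x].
* Float TIFF samples are stored normalized to [0, 1] with the scale
  recorded in the run manifest (restored via `intensity_scale`); every
  statistic in the package is invariant to this scale.
* Distance records with $L < 0.1$ µm, cells with zero spots of a species,
  and all-zero paired differences each have documented non-fatal paths
  (drop + warn, exclude + warn, p = 1 + warn).
* Detection rejects scales below one pixel; empty masks yield empty spot
  sets, not errors.
* The distance brute-force oracle in the tests samples $10^4$ points per
  segment; its own resolution error grows like $\Delta^2/(8d)$ near the
  polyline, so test configurations closer than 0.25 µm are redrawn — a
  limit of the oracle, not of the implementation.

## Problem sizes

The test and acceptance suites run at desk scale, chosen as the smallest
sizes at which each claim is statistically meaningful: 40 rendered scenes
for end-to-end recovery (pooled detection F1, grand-mean $d$ within 3 SE
of the Beta(2,6) mean, paired signed-rank rejection), 200 replicates for
null calibration of the tests, $10^4$ ground-truth spots for Beta-mean
checks, $10^3$ random configurations for the distance oracle, $10^4$
uniform draws for the PDI diffuse anchor, 100 replicates for
confidence-band coverage.

## Known limitations

* No automatic leader-cell identification or nuclear segmentation: edges
  are manual inputs, as in the source workflow.
* No 3D analysis; z-stacks are max-projected before everything else.
* No dense-cluster decomposition: quantification assumes resolvable spots
  (see the density discussion above).
* Absolute complexity values depend on the perimeter estimator; compare
  only within one estimator.
* The synthetic scenes emulate geometry, bias, PSF and read noise — not
  Poisson statistics, autofluorescence, probe background, or segmentation
  error of real images; passing recovery tests demonstrates correctness
  of the computations, not robustness to every imaging artifact.
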