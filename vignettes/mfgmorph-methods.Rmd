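---
title: "Image-based morphometry of milk fat globules: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based morphometry of milk fat globules: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfgmorph)
```

## The problem

Milk fat globules (MFGs) are triacylglycerol droplets, roughly 1–15 µm in
diameter, bounded by a trilayer membrane. Their size distribution matters for
milk quality assessment and for modelling lipid digestion, because lipase
activity scales with accessible surface area. Bulk laser diffraction (LD)
estimates a volume-weighted size distribution from angular scattering but is
blind to particle shape; bright-field imaging of a milk smear sees every
particle individually and can therefore distinguish *individual* globules from
*agglomerates* — fused clusters of two or more globules that project as a
single low-circularity silhouette.

`mfgmorph` implements the full image-based morphometric analysis (IBMA) chain
for such data: segmentation of dark particles on a light background,
per-particle shape descriptors, quality-control (QC) filtering, the
individual/agglomerate classification, number- and volume-weighted size
metrics, and the statistical machinery for comparing two sizing methods on the
same samples. Because raw micrographs from the original study are not publicly
available, the package also ships (a) a synthetic scene generator with exact
per-particle ground truth, which is what the test suite exercises end to end,
and (b) the study's printed per-sample tables, which serve as numerical
regression targets.

## Segmentation

Bright-field MFG images show dark particles on a light background. The
binarisation rule uses the two acquisition-SOP numbers: with a calibration
intensity $c$ (fraction of full grayscale taken as the background reference,
default 0.80) and an intensity tolerance $t$ (default 0.20), a pixel is
foreground iff its value is strictly below

$$\theta \;=\; c \cdot 255 \cdot (1 - t) \;=\; 163.2 .$$

The instrument's own edge detector is proprietary; this documented threshold
scheme uses both SOP parameters with their plain meanings and reproduces
dark-particle detection on rendered scenes exactly. Connected components are
labeled on the pixel-adjacency graph at 8-connectivity by default, so globules
that touch — even diagonally — fuse into one object; that is a prerequisite,
not a nuisance, because fused silhouettes are what the agglomerate class is
defined on. Watershed splitting is deliberately absent for the same reason.
Components below 25 px are discarded (detection floor), components touching
the frame are discarded by default (truncated silhouettes bias every shape
descriptor), and the 1.5–130 µm circle-equivalent (CE) diameter gate is
applied later, at QC, so the gate's effect is auditable per particle.

## Shape descriptors

For a particle of projected area $A$ (µm²) and perimeter $P$ (µm):

* CE diameter $= 2\sqrt{A/\pi}$,
* HS circularity $= 4\pi A / P^2$ (1 for a circle),
* convexity $=$ convex-hull perimeter / $P$,
* solidity $= A\,/$ hull area,
* elongation $= 1 - \text{width}/\text{length}$,
* intensity mean and population SD of the grayscale values under the mask.

### The perimeter estimator

Every circularity threshold in the classification chain hinges on how $P$ is
estimated: naively counting exposed pixel edges overestimates a digital
disk's circumference by $4/\pi - 1 \approx 27\%$, which would push perfectly
circular globules far below the 0.920 circularity boundary. The package
traces the outer contour (Moore neighbourhood, 8-connected) through boundary
pixel centers and scores the chain as

$$P \;=\; \Big( N_e + \sqrt{2}\,N_d - k\,N_c \Big)\,s \;+\; \pi s ,$$

with $N_e$ axial steps, $N_d$ diagonal steps, $N_c$ chain-code direction
changes, and $s$ the pixel size. The corner constant is derived analytically,
not fitted: the raw $(1,\sqrt2)$ chain length of a digitised circle of radius
$r$ tends to $8(2\sqrt2-2)\,r$ while its direction-change count tends to
$16(1+\sqrt2-\sqrt5)\,r$, so

$$k \;=\; \frac{(8\sqrt{2}-8)-\pi}{8\,(1+\sqrt{2}-\sqrt{5})} \;\approx\; 0.12077$$

makes digital disks converge to $\pi d$ exactly, while straight axis-aligned
and 45° runs (which have no direction changes) remain exact. The additive
$\pi s$ accounts for the half-pixel margin between pixel centers and the
physical particle edge: dilating a convex silhouette by half a pixel adds
exactly $\pi s$ of perimeter. The same half-pixel correction is applied to the
convex hull (computed on boundary pixel centers): hull perimeter gains
$\pi s$, hull area gains $Ps/2 + \pi s^2/4$. Consequences worth knowing:

* a single pixel has perimeter $\pi s$ (its unit-cell value);
* a digital disk of diameter 100 px measures within 0.3% of $\pi d$ and has
  HS circularity ≈ 0.994;
* an $s$-pixel square's circularity converges to $\pi/4$ from above
  (0.788 at 200 px);
* a 1-px-wide bar is the worst case: its center-line trace has zero width, so
  a 1×10 bar reports ≈ 21.1 against the 22-unit rectangle boundary — a bias
  bound of about 1 px that only affects structures the 25-px detection floor
  normally removes.

Circularity, convexity and solidity are clipped to $[0,1]$; discretisation
can push their raw values a fraction of a percent above 1 for convex shapes.

### Length, width, elongation

Length and width come from a 1° rotating-caliper sweep over the contour
points, using the minimal-width bounding-box convention: width is the
*minimum* Feret diameter and length the extent perpendicular to the width
direction (each plus one pixel for the pixel footprint). Defining length as
the maximum Feret diameter instead would measure a $2{:}1$ rectangle along
its diagonal and report elongation ≈ 0.20; the convention used here gives the
geometrically expected 0.5 for that rectangle, 0 for squares and circles, and
$1-\tfrac13$ for three collinear tangent disks.

### A geometric identity worth recording

For two tangent equal circles of radius $r$, the convex hull is the $2r
\times 2r$ rectangle spanning the two centers plus two half-disks, so hull
area is $(4+\pi)r^2$ and the union's solidity is

$$\frac{2\pi r^2}{(4+\pi)r^2} \;=\; \frac{2\pi}{4+\pi} \;\approx\; 0.880 .$$

The test suite asserts this closed form against an independent brute-force
hull; digital renders at $r = 40$ px give ≈ 0.874. The dumbbell's HS
circularity (analytically $1/2$, measured ≈ 0.55) and solidity both sit far
below the 0.920 / 0.970 classification boundaries, while its convexity
(≈ 0.82) stays above the 0.750 QC floor — exactly the regime that keeps true
agglomerates in the analysis but out of the individual class.

## QC filtering and classification

A particle is excluded iff convexity < 0.750, or solidity < 0.700, or pixel
area < 100, or intensity SD < 10 (all strict, so records sitting exactly at a
threshold are kept), or its CE diameter leaves the 1.5–130 µm window.
Excluded records carry *every* failed criterion, not just the first.
Survivors are classified:

* **individual** — HS circularity ≥ 0.920 and CE diameter < 25 µm;
* **agglomerate** — HS circularity < 0.920 and solidity < 0.970;
* **unclassified** — everything else (large circular particles, or
  low-circularity but high-solidity ones).

The two rules share the 0.920 boundary, so the three labels partition every
QC-passing record. The unclassified bucket is retained inside "total" because
the study's own count table contains a sample whose two class counts fall
short of its total — a third bucket reproduces that structure without
guessing which reading (typo vs. unclassified remainder) is correct. Manual
exclusion of visually identified debris is supported as an explicit
particle-id list rather than an algorithm.

## Size-distribution metrics

All metrics operate on raw per-particle CE-diameter lists — no histogram
binning. Number-weighted: $D[1,0]$ is the arithmetic mean; volume-weighted:
$D[4,3] = \sum d_i^4 / \sum d_i^3$, with each particle treated as a sphere of
its CE diameter. Treating agglomerates as spheres is a knowing 2D-projection
approximation — the alternative (excluding them) would make volume metrics
incomparable with laser diffraction, which cannot exclude them either.

Percentiles use one shared convention for both weightings: sort the
diameters, form cumulative weight fractions $c_i$ (weights 1 for Pn, $d_i^3$
for Pv), and interpolate linearly on the $(c_i, d_i)$ pairs, returning the
smallest diameter for targets at or below $c_1$. Because the cumulative
volume fraction never exceeds the cumulative number fraction at any diameter,
this single rule *guarantees* $Pv_p \ge Pn_p$; mixing conventions (e.g. a
textbook type-7 quantile for Pn with a cumulative-volume rule for Pv) can
invert that ordering on small samples — for diameters $\{1,2\}$, type-7 gives
$Pn_{50} = 1.5$ while the volume rule gives $Pv_{50} = 1.44$.

## Method agreement

For paired per-sample values of two methods (differences fixed as method A −
method B), the agreement ledger comprises: Pearson $r$; Lin's concordance
correlation coefficient

$$r_c \;=\; \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}$$

with population ($1/n$) moments — Lin's original convention; the $1/(n-1)$
variant differs by $O(1/n)$ and the choice is fixed and tested; the paired
$t$-test for systematic bias; Bland–Altman mean bias with 95% limits of
agreement $\bar d \pm 1.96\,\mathrm{SD}(d)$ (sample SD); and the
proportional-bias regression of $x - y$ on $(x+y)/2$. The proportional-bias
slope is computed as $\operatorname{cov}/\operatorname{var}$ rather than via
a QR fit so that exactly constant differences yield an exact zero — a QR fit
returns $O(10^{-16})$ noise that a bootstrap interval would confidently
"detect".

Confidence intervals use the bias-corrected and accelerated (BCa) bootstrap
with 3000 resamples by default: bias constant
$z_0 = \Phi^{-1}\!\big(\#\{\theta^*_b < \hat\theta\}/B\big)$, acceleration
$a$ from jackknife skewness, endpoints taken as order statistics of the
bootstrap distribution (index $\lfloor (B+1)p \rfloor$, clamped, never
extrapolated). Paired rows are resampled jointly; two-group contrasts
resample within groups. Proportional bias is declared when the BCa interval
of the slope excludes zero — the bootstrap-CI criterion, not the OLS
$t$-test, for consistency with the rest of the ledger. Statistics that are
undefined on degenerate resamples (a correlation when a resample repeats one
row) are dropped from the bootstrap distribution; a fully degenerate
distribution yields a point interval with a warning. p-values are reported
unadjusted, and both the classical $t$-transform p-value and the bootstrap
interval are available for correlations, since either reading of
"significance" is defensible.

Calibration: on the mean of Normal(0,1) samples of size 30, 1000 replications
at $B = 1000$ give empirical 95%-interval coverage of about 93–94% — the
well-known slight small-sample undercoverage of BCa — which the test suite
accepts within 95% ± 2%. The implementation is cross-checked against
`boot::boot.ci(type = "bca")` on identical data.

## The synthetic scene generator

Scenes emulate a bright-field smear: a light background (default level 230)
carrying dark near-circular globules whose diameters follow a lognormal law,
with defaults `meanlog = log(4.5)`, `sdlog = 0.3` — median 4.5 µm, 95% range
roughly 2.5–8 µm, the mature human-milk globule scale and consistent with the
packaged study's per-sample means (4.0–6.0 µm). Agglomerates are chains of
`k ∈ {2,3,4}` disks, each placed at distance
$(1-\text{overlap}) (r_{i-1}+r_i)$ from its predecessor along a random
direction (default overlap 0.25); the chain model reliably produces
silhouettes with HS circularity below 0.920 — at the boundary condition
(overlap 0.3) over 95% of generated clusters classify as agglomerates on
their noise-free masks.

Rendering is by pixel-center inclusion (hard mask), so analytic area oracles
hold: a noise-free disk of diameter ≥ 20 px measures within 2% of
$\pi d^2/4$. Intensity follows a radial linear ramp from `particle_level`
(default 60) at the center to `rim_level` (default 140) at the edge, with
overlapping disks taking the darker value. The ramp matters for a subtle
reason: a flat profile would give every noise-free particle an intensity SD
of 0, and the QC filter would then exclude *all* synthetic particles via the
intensity-SD < 10 rule. The ramp yields SD ≈ 19 while staying below the
163.2 threshold so the full silhouette is still segmented. Optional additive
Gaussian noise is applied before 8-bit quantisation. Particles are placed by
rejection sampling with a cap of 10 000 attempts and a guaranteed one-pixel
separation between silhouettes — overcrowding is an error naming the frame
and occupancy, never a silent overlap.

Ground truth records each particle's class, component diameters, centroid,
and the CE diameter of its rendered union mask. What the generator does *not*
emulate — point-spread blur, vignetting, debris, casein micelles, focus
drift, 3D stacking — bounds what green tests mean: they validate the
geometry, the estimators and the decision rules, not robustness to real
optical artefacts.

### Problem sizes

The default pixel size is 0.0625 µm (a 1.25 µm camera pixel behind a 20×
objective). The package's own demonstration, test and acceptance scenes use
0.2 µm pixels on 512–768 px frames with 30–80 particles: at 4.5 µm median
diameter that is a 22-px globule — comfortably above the detection floor —
while keeping every suite fast; the estimators themselves are
scale-equivariant, which the tests assert directly. The distribution-metric
recovery checks use $10^5$ lognormal draws; bootstrap calibration uses 1000
replications of $B = 1000$.

## The packaged study tables

Three CSVs transcribe, verbatim, a 12-donor study's per-sample covariates,
class counts, and number-weighted size/shape metrics; a fourth holds the
printed summary rows and correlations. `reproduce_study_summaries()`
recomputes each printed value and compares at the printed precision, to one
unit in the last printed digit — the printed summaries were evidently
computed from unrounded per-sample values, so means of the rounded printed
columns can differ from them by up to one ulp. Four rows are flagged as not
reproducible and are excluded from regression targets:

* the two Pn50-vs-storage correlations, whose printed class labels cannot be
  reconciled with recomputation from the tables themselves (recomputation
  attributes −0.554 to agglomerates, not individuals);
* the individual-percentage mean and SD, which were printed as the complement
  of the agglomerate percentage (100 − 15.25) and the agglomerate column's
  SD — an identity that fails here because one sample's two class counts sum
  below its printed total (preserved verbatim; the unclassified bucket covers
  either reading of that discrepancy).

## Known limitations

* Perimeter, and hence circularity, carries a thin-structure bias of order
  one pixel for 1-px-wide objects; irrelevant above the 25-px floor.
* The convex hull is built on boundary pixel centers, biasing hull
  quantities by up to one pixel — acceptable at the detection floor, and
  corrected to first order by the half-pixel terms.
* Volume metrics treat every silhouette as a sphere of its CE diameter; for
  flat or chain-like agglomerates this overstates volume in a way 2D imaging
  cannot resolve.
* The BCa bootstrap undercovers by 1–2 points at n ≈ 30 and is reported as
  such, not corrected.
* Single-image scope: particles are never merged across adjacent fields of
  view.
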