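---
title: "Outline-based morphometrics of spore silhouettes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline-based morphometrics of spore silhouettes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporemorph)
```

# The problem

Basidiospores carry much of the taxonomic signal in many fungal groups, but
their shape is traditionally recorded either as a qualitative term
("cylindric", "fusiform") or as the single length-to-width ratio Q. Both
discard most of the geometric information in the silhouette. This package
quantifies the full 2D outline of a spore in lateral projection and asks a
concrete comparative question: how well do outline-derived shape
descriptors, classical linear measurements, and their combinations identify
species under repeated cross-validation?

The analysis chain is: binary micrograph → Freeman chain code per spore →
closed outline polygon → elliptic Fourier descriptors, normalized by the
first harmonic (NEFDs) → three principal-component shape spaces
(symmetric, asymmetric, global) → per-image trait table (shape PC scores +
length, width, Q, integrated size) → Spearman correlation structure and
flexible discriminant analysis with repeated stratified 70/30 splits.

# Elliptic Fourier descriptors

A closed outline is parameterized by arc length $t \in [0, T)$ and each
coordinate is expanded as a truncated Fourier series,

$$x(t) = A_0 + \sum_{n=1}^{H} a_n \cos\frac{2\pi n t}{T} + b_n \sin\frac{2\pi n t}{T},$$

and likewise $y(t)$ with coefficients $c_n, d_n$. For a polygon the
coordinate functions are piecewise linear, so all integrals have closed
forms (the chord-length formulas); no quadrature is involved. The suite
verifies the closed forms against brute-force Simpson integration of the
defining integrals to $10^{-8}$ relative error.

We use $H = 20$ harmonics throughout. That depth is established practice
for smooth biological outlines (common choices run from 15 to 30) and, on
the synthetic spores used here, the 20-harmonic reconstruction error is
well under 1 % of spore length. Each spore is then described by
$4H = 80$ coefficients.

## First-harmonic normalization

Size, position, rotation and the arbitrary start point of boundary tracing
are nuisance parameters. They are removed with the classical
first-harmonic procedure: drop the DC terms, rotate the start point onto
the semi-major axis of the first-harmonic ellipse, rotate the plane so
that axis lies along $+x$, and divide by the semi-major axis length. The
result satisfies $a_1 = 1$, $b_1 = c_1 = 0$, so 77 of the 80 stored
coefficients remain free shape variables. The removed scale is kept as
`size_scalar` (micrometres), so size and shape separate cleanly.

Two conventions had to be fixed where the classical procedure is silent:

* **The residual 180° ambiguity.** The first-harmonic frame is defined
  only up to a half-turn. Workflows built on interactive tools resolve
  this by eye; an automated and *pose-invariant* rule is needed here,
  because the package promises that descriptors are identical for
  arbitrarily rotated, scaled and resampled copies of the same outline
  (tested at $10^{-6}$). The rule is intrinsic to the shape: the proximal
  (hilar-appendix) end is the sharper end — the end of the major axis with
  the larger integrated absolute boundary turning over its outer 15 % of
  axial extent — and it is mapped to negative $x$. Detection runs on the
  full-resolution source polygon when `normalize_efd(efd, poly = ...)` is
  given one (recommended; truncation to 20 harmonics visibly blunts a
  small appendix), with a smoothing window (`flip_smooth`) for
  raster-traced outlines whose staircase noise would otherwise dominate
  the turning integral. On a sharpness tie the flip is fixed by the sign
  convention $d_2 \ge 0$: a half-turn negates exactly the even harmonics,
  and genuinely end-symmetric outlines have vanishing even harmonics, so
  the tie choice is immaterial precisely when it triggers.
* **Near-circular first harmonic.** If the first-harmonic ellipse has axis
  ratio above 0.999 its orientation is numerically meaningless; the
  spatial rotation is then taken from the second harmonic, with a warning.
  Elongate spores never reach this branch; it exists so the function is
  total.

Reflection is deliberately *not* normalized: mirroring is treated as data
curation (images are mirrored before analysis so all spores face the same
way), not as shape mathematics.

## Symmetric and asymmetric blocks

For an outline mirror-symmetric about the normalized major axis the sine
cross-terms vanish: $b_n = c_n = 0$. The coefficient vector therefore
splits into a symmetric block $\{a_n, d_n\}$ (39 entries at 20 harmonics)
and an asymmetric block $\{b_n, c_n\}$ (38 entries), with the global
vector their concatenation in per-harmonic order (77 entries). Reflecting
an outline negates the asymmetric block and preserves the symmetric block,
which the suite asserts at $10^{-6}$.

# Shape spaces

Each block is summarized by PCA on the covariance matrix — not the
correlation matrix, because normalized coefficients already share one
dimensionless scale and standardizing would inflate the high-harmonic
noise floor. Eigenvector signs are fixed (largest-magnitude loading
positive) so scores are reproducible across platforms.

"Effective" components are selected by eigenvalue magnitude. A literal
eigenvalue > 1 rule cannot apply to covariance eigenvalues of NEFDs, which
are far below 1; the package's default (`gt_mean`) retains eigenvalues
strictly greater than the mean eigenvalue, the covariance-PCA analogue of
the Kaiser rule, and `kaiser_scaled` exposes the same selection phrased as
mean-scaled eigenvalues > 1. A variance-share criterion is also available.
Whatever the selection, the feature sets used in the discriminant
comparison fix the component counts (symmetric PC1; asymmetric PC1–PC3;
global PC1–PC2) so that models are comparable across panels.

What a component encodes is visualized by reconstructing the mean shape
and the mean ± 2 SD shapes along the component (`pc_shape_range`); on
synthetic panels the suite confirms that a width-varying panel puts
relative thickness on symmetric PC1 (|Spearman| ≥ 0.9 against true
width/length) and a bow-varying panel puts the long-axis curvature on
asymmetric PC1.

# Size traits and the observation unit

Length is the maximum Feret diameter of the outline; width is the maximal
caliper extent perpendicular to the length axis. The mycological
convention says only "longest" and "broadest" dimension; measuring width
across the length axis (rather than as an independent minimal caliper)
matches how a mycologist places the second measurement and is documented
as this package's choice. Derived traits are $Q = L/W$ and the integrated
size $\sqrt{LW}$, a size measure less entangled with shape than either
linear measurement.

All comparative statistics run on **average-per-image** values: when an
image contains several spores, shape and size records extracted by
different tools can only be aligned at the image level, so spore-level
traits (including PC scores — the PCA itself is fit per spore) are
averaged per image first. Trait similarity is summarized by Spearman rank
correlations with two-sided p-values from the t-approximation, unadjusted
at $\alpha = 0.05$ by default (a Holm option exists because the default
makes no multiplicity correction).

# Discriminant analysis

Species identification uses flexible discriminant analysis in its
optimal-scoring form: regress the class-indicator matrix on the features,
eigen-decompose the fitted class scores, and classify by nearest class
centroid in the eigenvalue-weighted discriminant space with priors
proportional to training frequencies. With the default linear basis this
is *exactly* classical LDA — the distance weights are
$\frac{n-K}{n} \cdot \frac{1}{\theta_l^2(1-\theta_l^2)}$, where the
$(n-K)/n$ factor matches the unbiased within-class variance convention so
that the $-2\log(\text{prior})$ penalty is commensurate with the
distances. The suite asserts prediction-level identity with an
independent classical LDA implementation on 20+ random datasets.
Polynomial bases and a ridge penalty are available for non-linear or
rank-deficient problems but are not defaults. Exact distance ties go to
the first class in label order.

Cross-validation repeats a species-stratified 70/30 split (default 1000
replicates), fits on the training portion, and records the fraction of
correct test assignments; the mean over replicates is the identification
success rate. Replicate $r$ seeds its partition stream with
$\text{seed} + r$, which gives two properties: results are reproducible
from the root seed, and every feature set sees the *identical* partition
sequence, so per-replicate accuracies are paired across feature sets and
mean differences are free of partition noise. Pairing is a design choice
of this package (whether the original workflow shared splits across
models is unknowable); it only reduces comparison variance.

A note on chance-level checks: with labels permuted once and fixed, CV can
legitimately exploit the fixed permutation's chance alignment with the
features, so the mean success rate on a finite panel sits slightly above
$1/K$ no matter how clean the machinery is. The calibration test therefore
re-permutes labels afresh in every replicate, which makes the replicate
mean an unbiased estimate of $1/K$ and the 3-standard-error band a
coherent criterion.

# The synthetic spore generator

Real spore image collections are external; validation therefore rests on
a generative model whose free axes map one-to-one onto the shape features
the PCs are expected to capture. A spore silhouette is a bent capsule: a
centerline $x \in [0, L]$ with vertical offset
$y_c(t) = \kappa_1 L \sin(\pi t) + \kappa_2 L \sin(2\pi t)$
(single bow; S-curvature differentiating the two ends), half-width
$w(t) = \frac{W}{2}\,(4t(1-t))^{p}$ (end-taper exponent $p$), and a
Gaussian hilar-appendix bump of height $h$ and width $\sigma L$ added to
the adaxial profile at the proximal end.

The hierarchy mirrors a balanced collection design: species means are
drawn uniformly from configurable ranges, specimens within species and
spores within specimens add Gaussian effects — log-scale for length and
width (spore dimensions are positive and right-skewed), additive for the
curvature, taper and appendix terms — and draws are clipped to the
parameter invariants. Default ranges (lengths 8–18 µm, widths 2–4.5 µm,
bow up to 0.12, taper 0.4–1.0, appendix 0.15–0.4 µm) emulate
needle-shaped to short-cylindric basidiospores of a few to ~20 µm with
specimen-level CVs of ~4 % and spore-level CVs of ~5–6 % on the linear
dimensions; these are fixed study conditions, not tuning knobs. The
default design is 10 species × 3 specimens with 10–37 spores per specimen
and 1–4 spores per image, matching the uneven yields of herbarium squash
preparations.

What the generator does *not* emulate: illumination gradients, optical
blur, overlapping or touching spores, hyphal and crystal clutter, focus
variation, and ornamented walls. Passing tests therefore demonstrate the
correctness of the measurement and comparison machinery on clean
silhouettes with known truth — not robustness to difficult micrographs,
which the upstream filters (border, minimum area, morphological cleaning)
only partially address.

# Numerical and design details

* Pixel convention: 0-based pixel indices in files, polygon coordinates at
  pixel centers, image row axis flipped so y increases upward before any
  shape mathematics; all polygons counterclockwise (positive signed area).
* Boundary tracing is Moore neighbor tracing over 8-connected components
  with Jacob's stopping criterion, starting at the topmost-then-leftmost
  pixel. Components touching the image border and components below a
  minimum area are rejected, not repaired. The labelling primitive merges
  diagonally-touching 4-connected labels to obtain exact 8-connectivity.
* The structuring element for erosion–dilation cleaning is a disc of
  radius 1 by default; the radius is a configuration knob since no
  standard value exists.
* `standardize_orientation` applies only 0°/180° rotations (as in
  chain-code workflows); arbitrary rotation is later removed by the
  Fourier normalization. Its appendix auto-detection uses the same
  integrated-turning rule as the normalization flip, with raster-robust
  smoothing and a conservative tie threshold: an ambiguous outline is left
  unrotated with a warning rather than risk a wrong half-turn.
* Degenerate inputs error early and informatively: blank images, zero-
  perimeter polygons, species with a single observation, singular
  regressions without a ridge penalty, conflicting labels within an image.
* Pipeline determinism: the generator uses the root seed itself and
  cross-validation uses root + 10000, so extending the replicate count
  never perturbs the simulated data.

# Problem sizes used by the validation suite

The test suite and the acceptance script exercise: full default panels
(10 × 3 species × specimens, 10–37 spores per specimen, ~700 spores in
~290 images) for the feature-set comparison at 200–1000 CV replicates;
single-axis panels of 150 spores for parameter recovery; 20 random
polygons for the integration oracle; and eight random spores for the
raster round trip (1.5-pixel Hausdorff bound). These sizes were chosen so
the entire suite documents the method's behavior at the study's own
design scale while remaining quick to re-run.

# Known limitations

* The appendix-side rule needs a detectable appendix; on panels of
  near-end-symmetric spores the even-harmonic tie convention takes over,
  which is consistent but arbitrary in sign.
* Width-perpendicular-to-length is one reading of "broadest dimension";
  outlines with strongly curved axes can make this differ from a minimal
  caliper width.
* Spore-level (rather than average-per-image) discriminant analysis would
  use more information but is deliberately not the default observation
  unit, for comparability with image-level workflows.
* The raster path assigns new spore identifiers during extraction;
  spore-level ground-truth joins across that path must go through the
  image identifier.
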