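---
title: "herbleaf: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{herbleaf: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

herbleaf classifies pressed herbarium leaves to species from specimen
images. Herbarium material is awkward for morphometrics: leaves overlap,
fold, tear and bend during pressing, and most species are represented by
only a handful of sheets. The pipeline therefore (1) segments a single
leaf semi-automatically from user scribbles, (2) normalizes pressing
distortion by straightening the main vein, (3) extracts three
complementary feature sets describing outline and venation, and (4)
classifies with a linear one-against-one SVM evaluated leave-one-out,
which is the appropriate protocol when a class has ~10 samples.

This vignette records the model, its tunable parameters, and every place
where the design was genuinely open and a choice had to be made. It
states no empirical result that the package's tests and
`scripts/acceptance.R` do not themselves compute.

## Segmentation

A leaf is cut out of the sheet by minimising the scribble-seeded binary
energy

$$E(L) = \sum_i D_i(L_i) \;+\; \lambda \sum_{(i,j)\in N_4}
\frac{[L_i \ne L_j]}{1 + \lVert c_i - c_j \rVert},$$

where the data term $D_i(\mathrm{fg}) = d_\mathrm{fg}/(d_\mathrm{fg} +
d_\mathrm{bg})$ uses distances to k-means colour clusters fitted to the
foreground and background scribbles, and scribbled pixels carry hard
labels. The energy is submodular, so a single s-t min cut
(`igraph::max_flow`) returns the exact global optimum; the test suite
verifies equality with exhaustive enumeration on random small instances.

Choices: $K = 8$ clusters per side (stable with few scribble pixels),
$\lambda = 10$ on colours scaled to $[0,1]$, Euclidean RGB distances
(grayscale treated as three equal channels), 4-connected neighbourhood
(submodular, exact). k-means is Lloyd's algorithm with deterministic
farthest-first seeding, so segmentations are bit-reproducible — the
interactive feedback loop of the original scribble-based tool is
deliberately replaced by file-based scribbles plus IoU assertions in
tests, for reproducibility. `cleanup_mask()` keeps the largest
4-connected component and fills interior holes below 0.1% of its area.

## Vein maps: the oriented line operator

For each pixel, the mean intensity of a length-15 line template (15
sample points spaced 1 px along the rotated direction, bilinearly
interpolated to avoid angle-dependent discretisation bias) is compared
with the mean of the 15 x 15 square neighbourhood, over 24 evenly spaced
orientations in $[0^\circ, 180^\circ)$ (bin width 7.5°). The best match
gives the per-pixel orientation $O(x,y)$ and strength $S(x,y)$; ties go
to the smallest angle. Veins press as *dark* ridges, so strength is
neighbourhood mean minus line mean. Angles are measured counterclockwise
from the image x-axis (columns), modulo 180°, so a vertical vein has
orientation 90°; the same convention feeds $\Delta\alpha$ and FS3.

The operator family includes variants that subtract flanking strips
instead of the square neighbourhood; the square-neighbourhood variant is
used here and is substitutable behind the same interface.

Scale: responses are computed on a Gaussian pyramid ($\sigma = 1$,
2x subsampling, 3 levels including the original), upsampled to full
resolution, and combined per pixel by maximal strength, the winning
scale also supplying the orientation — "best match" extended across
scales. Adding a constant to the image leaves $S$ and $O$ unchanged;
scaling intensities by $c > 0$ scales $S$ by $c$.

## Normalization: tracing and straightening the main vein

The leaf tip is the outermost 2% of the segmented area along the ray
from the petiole through the mask centroid (the returned tip pixel is
the one of maximal projection; ties toward smallest row, then column).
The petiole is user-marked in the manifest; when absent, the lowest-row
mask pixel is used so batch runs stay unattended.

The main vein is the minimal-cost 8-connected path from petiole to tip
inside the mask. The underlying cost combines line strength and the
angle $\Delta\alpha \in [0^\circ, 90^\circ]$ between the local
orientation and the fixed base-tip axis $g$. The raw form
$-S + \Delta\alpha$ adds arbitrary strength units to degrees; as the
minimal repair that preserves intent and admits exact search, both terms
are normalised to $[0,1]$:

$$\tilde\varepsilon = (1 - \tilde S) + \Delta\alpha / 90^\circ,
\qquad \tilde S = \text{min-max normalised } S \text{ over mask pixels},$$

a step from $u$ to $v$ costing $\ell \cdot
(\tilde\varepsilon(u) + \tilde\varepsilon(v))/2$ with $\ell = 1$ axial
and $\sqrt 2$ diagonal (the trapezoidal geodesic-time discretisation).
Costs are nonnegative, so Dijkstra is exact; tests compare against an
independent Bellman-Ford relaxation. $\Delta\alpha$ is measured against
the *fixed* direction of $g$, not a locally updated heading, and the
path must end at the single detected tip pixel (determinism).

The leaf is then rotated so $g$ is vertical with the tip up. Because
the detected tip pixel can sit a few pixels off the true axis on blunt
apices, the rotation is refined once with the chord of the cubic fitted
to the traced path: any residual axis error left for the row shear
would distort left- and right-hand vein angles asymmetrically (a shear,
unlike a rotation, is not angle-preserving), degrading the mirrored
orientation histograms. After refinement a cubic
$\mathrm{col} = a_0 + a_1 r + a_2 r^2 + a_3 r^3$ is least-squares fitted
to the rotated path (fitting *after* rotation makes the per-row shift
well defined even for strongly curved veins), and every row is shifted
horizontally so the cubic lands on a straight vein column. The rotation
and the per-row shear are composed into a *single* inverse map, so the
image is resampled exactly once (bilinear for the image,
nearest-neighbour for the mask, background filled with the median
off-mask intensity to avoid dark-border artifacts in downstream line
maps): resampling twice measurably blurs 1-2 px veins and degrades the
orientation histograms computed downstream. The canvas is padded so no leaf pixel is lost;
shifts outside the leaf's row range are clamped to the boundary values
so cubic extrapolation cannot blow up the canvas. Nearest-neighbour
warping can strand single pixels off 1-px-wide structures (the very tip
of the outline), so the warped mask is passed through `cleanup_mask()`.

The vein column is the rounded median of the fitted cubic over the
leaf's rows. This per-row shear is area-preserving up to resampling
(the tests bound the area change at 2%) and idempotent to IoU >= 0.99.

## Features

**FS1 — Fourier contour descriptors (20).** The outer contour is
extracted by marching squares at level 0.5 on a Gaussian-smoothed
($\sigma = 1$) copy of the binary mask — without smoothing, the pixel
staircase inflates perimeters by ~4% and aliases into the low-frequency
coefficients. The contour is resampled to 256 equal arc-length points
$z_k = \mathrm{col}_k + i\,\mathrm{row}_k$ and Fourier transformed.
Descriptors are $|F_m|/|F_1|$ at $m \in \{-10..-1\} \cup \{2..11\}$:
dropping $F_0$ gives translation invariance, magnitudes give rotation
and starting-point invariance, division by the fundamental gives scale
invariance. The frequency window (symmetric low frequencies, normalised
by the fundamental) is a package decision; only the count (20) and the
invariances are externally fixed.

A measured limitation worth recording: the invariances are exact at the
contour level (the test suite verifies $10^{-3}$ relative and better),
but *re-rasterising* a rotated or rescaled shape injects
pixel-sampling noise of order $10^{-3}$ per descriptor for leaf-sized
shapes — binary pixel-center sampling carries Moire-structured boundary
error that no contour estimator can remove and that decays only like
$1/\sqrt{\text{size}}$. Mask-level robustness is therefore tested at
$10^{-2}$.

**FS2 — nine shape descriptors.** The names are standard but no formulas
are canonical, so the package fixes one per name: compactness
$4\pi A/P^2$; convexity $P_\mathrm{hull}/P$; solidity
$A/A_\mathrm{hull}$; rectangularity $A/A_\mathrm{minrect}$ (minimum-area
rectangle via rotating calipers); circularity $\mu_R/\sigma_R$ over
boundary-to-centroid radial distances (the Haralick form, deliberately
distinct from compactness); perimeter-area ratio $P/A$; slimness
(bounding-box width/height in the tip-up frame); position of maximum
thickness (distance of the widest row from the base as a fraction of
leaf height; ties resolved toward the base); dispersion $\max_R/\mu_R$.
$P$ is measured on the resampled sub-pixel contour, $A$ in pixels. All
are unit-tested against closed forms (circle, square, L-shape,
triangle). A circle's $\sigma_R$ approaches zero, making circularity
large but finite for rasters; an exactly zero $\sigma_R$ is rejected as
degenerate.

**FS3 — weighted vein-orientation histograms (2 x 24).** On the line map
of the *normalized* image (computing maps after warping keeps the
histograms in the upright frame; computing before and warping the maps
would be the substitutable alternative), the leaf is split into upper
and lower halves at the row midway between tip and base, and into left
and right of the vein column (pixels exactly on the column are excluded
so mirroring is an exact symmetry). Accumulation is restricted to pixels
whose winning template support lies entirely inside the leaf: a response
won at pyramid scale $s$ has an effective support radius of
$7 \cdot 2^{s-1}$ px at full resolution, and where that support reaches
past the margin the template saw the background — its response
describes the outline edge (whose orientations converge toward tip and
base and would fake a venation signature) or, at coarse scales on a
narrow lamina, the whole leaf acting as a "line". Each remaining pixel
accumulates
$\max(S, 0)$ into its orientation bin; the right side is mirrored
($\theta \to 180^\circ - \theta$) and averaged with the left; the upper
and lower histograms are each normalised to unit sum. Unit-sum
normalisation is a package decision — raw cumulative weights would make
the feature depend on leaf size in pixels, breaking comparability
across scans; strength is not thresholded before accumulation. An empty
or zero-strength half stays all-zero with a warning.

One behaviour of the unthresholded histogram is worth knowing: pixels
*flanking* a vein also collect positive responses, at oblique
orientations, because their best-matching template is the one that
crosses the dark line. Flank responses are several times weaker than
on-vein responses but more numerous, so even a leaf whose quadrants
contain only vertical veins puts roughly half to two-thirds — not
nearly all — of its histogram mass into the 90-degree bin. The peak
location and the upper/lower peak *separation*, which is what the
classifier exploits, are unaffected.

## Classification

One linear soft-margin SVM per unordered class pair; prediction by
majority vote, ties broken by the largest sum of signed decision values
among the tied labels, then label order. Features are standardised to
zero mean and unit deviation *from the training samples only*
(zero-deviation dimensions pass through unscaled); inside leave-one-out,
standardisation is refit on every fold's training set — the only
leakage-free choice. The runtime ships no SVM library, so the binary
subproblem is solved by deterministic dual coordinate descent on the L1
hinge loss (cyclic sweeps, fixed order, tolerance $10^{-6}$, bias as an
augmented regularised feature); every accuracy and confusion matrix is
bit-reproducible. $C = 1$ by default ("linear kernel" is the only
externally fixed choice); a permutation-null test guards the whole
pipeline against information leakage.

## The synthetic-leaf generator

The original ~260 specimen scans are not deposited, so the package
ships a parametric generator that emulates the statistical structure
the pipeline assumes — it is first-class, tested code, not a fixture.

A species is a `leaf_spec()`: an outline half-width profile $w(t)$,
$t \in [0,1]$ base to tip (elliptic / obovate / cordate / lobed with
lobe count and depth), leaf length (default 150 px, so a canvas of
roughly 220 x 150 — scans are scaled down so a 26 x 10 benchmark fits a
single CPU budget), secondary-vein angles for the lower and upper leaf
half, vein spacing, a cubic midvein bend (zero shift at the base keeps
the petiole fixed; the bend is applied with exactly the per-row shift
warp that `straighten()` inverts), additive Gaussian intensity noise
(sd 0.02 easy / 0.03 hard on a $[0,1]$ scale), optional bite damage
(disks removed off the midvein corridor so the leaf stays traceable)
and optional leaf overlap. Intensities: background 0.85, lamina 0.58,
veins ~0.2 darker, 1-2 px wide, anti-aliased.

Benchmarks draw species from a coarse parameter grid. "Easy" species
are well separated relative to the within-species jitter (width x
(1 + N(0, 0.03)), angles +- 1.5°, random bend of up to ~15 px). "Hard"
species come in look-alike pairs offset by less than or about the
jitter (width +0.012, angles +1°), mimicking congeneric species whose
morphological similarity drives misclassification; the pair structure
is recorded so tests can check that errors concentrate within pairs.
These values were fixed from the stated design before the acceptance
outcomes were measured.

What a green benchmark test does establish: the full chain — rendering,
cleanup, tip detection, tracing, straightening, all three feature
blocks, fold-safe LOO SVM — separates species whose differences are of
the kind the features target. What it does not establish: performance
on real scans, which add overlapping laminae on the sheet, petiole and
stem clutter, handwriting and labels, non-uniform illumination, browning
and texture the generator does not model.

## Numerical and policy details

* Coordinates are (row, col), 1-based, origin top-left, in every type
  and every file. A single convention end to end was the goal; 1-based
  was chosen over 0-based because the implementation language indexes
  matrices from 1 and a mixed convention is the classic off-by-one trap.
* On-disk rasters are NetPBM PGM/PPM (8/16-bit, ASCII or binary),
  implemented in-package: the runtime ships no PNG/TIFF codec, and
  NetPBM keeps all test fixtures plain text.
* Manifest CSV: UTF-8, comma-separated, header required; records sorted
  by species then path so ordering is identical across platforms.
* Degenerate inputs: images smaller than the template are an error at
  single scale and drop levels with a warning at multi-scale; an empty
  mask, a single-class training set, a path spanning < 4 rows, a
  zero-variance radial profile are errors; a fold that loses a class is
  allowed and simply cannot predict that class.
* `run_pipeline()` isolates per-leaf failures (they are reported, not
  fatal), caches per-leaf features as full-precision JSON keyed by the
  resolved configuration, and echoes that configuration into the run
  report for auditability.

## Known limitations

* Segmentation quality depends on scribble coverage; there is no
  boundary-editing phase and no automatic scribble proposal.
* The straightening model is a per-row horizontal shear along one cubic;
  folded or torn laminae, or leaves whose midvein is not a function of
  the row after rotation, are outside its scope.
* FS1's mask-level stability is bounded by rasterisation noise (see
  above); shapes much smaller than ~50 px of diameter lose descriptor
  precision quickly.
* The SVM is linear only, by design; no kernels, probabilities, or
  cross-validation schemes other than leave-one-out.
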