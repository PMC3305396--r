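---
title: "Quantifying radiation-induced foci in 3D: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radiation-induced foci in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifquant)
```

## The problem

DNA double-strand breaks recruit repair factors (53BP1, γ-H2AX, MDC1, ...)
into micron-scale foci visible by immunofluorescence. Their number per
nucleus tracks dose and repair kinetics; their sizes and mutual 3D distances
carry mechanistic information. Scoring them by eye is slow and subjective,
and becomes unreliable when foci spread across several focal planes.
`rifquant` automates the full chain from TIFF z-series to per-focus tables.
This vignette records the models used at each stage, the parameters that
matter, and the design decisions taken where more than one reasonable choice
existed.

## Input model and calibration

A field of view is a folder of single-plane grayscale TIFFs, one file per
z-slice and channel, z-order given by the trailing integer in the file name,
channels told apart by a file-name substring (`dapi` / `rif` by default —
plain TIFF series carry no channel metadata, so some naming convention is
unavoidable; it is configurable). Physical calibration cannot be read from
plain TIFFs either, so it is supplied by the user: defaults are 0.07 µm/pixel
laterally and 0.5 µm between slices, typical of a 100×/NA 1.3 widefield
system imaging 22–25 slices per nucleus with a 14-bit camera. Pixels are kept
as unsigned integers at native depth for I/O; filtering is done in floating
point. Coordinates are 0-based `(x, y) = (column, row)`, and micrometre
conversions happen only in reporting and 3D geometry.

## Nucleus segmentation

Nuclei are segmented once per field on the maximum-intensity projection of
the DAPI stack. Segmenting the composite rather than individual slices avoids
false positives on slices that contain mostly noise. The threshold is Otsu's:
the gray level maximising the between-class variance of the histogram split,
with pixels strictly above the threshold as foreground and ties resolved to
the lowest maximising level (a fixed tie-break keeps runs reproducible).
Connected components are labelled 8-connected — diagonal contact does not
split a nucleus — by a two-pass run-based sequential labelling with
union-find merging. Two exclusion rules remove unusable nuclei: area below
`min_nucleus_px` (default 1000 px; an area of exactly 1000 px is retained,
reading "smaller than one thousand" literally) and masks containing a pixel
in the first/last row or column ("touching the boundary" is judged on the
mask, not the bounding box). Touching nuclei are *not* split: declumping by
watershed is out of scope, and closely bounding nuclei are a known failure
mode that should be screened out before analysis.

The single 2D nuclear mask is applied to every slice of the focus channel:
the crop keeps the bounding box and zeroes everything outside the mask.

## The focus-detection chain

Per slice, in order:

1. **Pre-smoothing** — `pre_iterations` (default 3) applications of a 3×3
   uniform mean, reflective borders. This removes the high-frequency noise
   spikes that the Laplacian would amplify. The smoothing kernel itself is a
   documented choice: any small symmetric low-pass kernel serves the same
   role, and the mean kernel is the simplest member of that family.
2. **Laplacian** — a discrete Laplacian turns intensity peaks into troughs.
   `laplacian_sensitivity` selects the kernel: `low` the 4-neighbour kernel,
   `medium` (default) the 8-neighbour kernel, `high` a 5×5
   Laplacian-of-Gaussian; the increasing neighbourhood responds to
   increasingly broad structures. A normalisation offset (default 1500) is
   added so focus troughs do not fall below zero; anything still negative is
   clamped to 0 with a warning. The offset's scale is meaningful: at proper
   exposure, focus Laplacian magnitudes reach the order of 10³ counts.
3. **Crimmins speckle removal** — `post_iterations` (default 3) of the
   classic geometric filter, which raises pixels significantly darker than
   their neighbours and lowers those lighter, in ±1 steps over four
   directions. It removes residual noise amplified by the Laplacian while
   barely moving extended structures.
4. **Polarity inversion** — the trough image is negated so that foci are
   peaks and "above threshold" uniformly means "focus"; this is pure
   bookkeeping to keep a single code path.
5. **Global maximum-entropy threshold** — one Kapur threshold per nucleus
   stack (or per folder, `histogram_scope = "folder"`), computed on the
   pooled integer-binned histogram of all in-mask pixels of all slices, with
   one bin per integer level over the observed range (exact, no bin-width
   tuning; fractional values are binned by round-half-away-from-zero).
   Pooling all slices makes the noise and signal classes more distinct and,
   crucially, slices without foci are cut at the same level as slices with
   foci, so their noise is not promoted to signal.
6. **Closing** — a fixed 3×3 binary closing fills one-pixel gaps inside
   foci.

The chain is fully deterministic; identical inputs give bit-identical masks.

### Guards around the threshold

Three additional mechanisms, all package design choices, make the chain
robust on two inputs the five filter stages alone handle badly:

* **Mask guard rim** (`mask_guard_px`, default `pre_iterations + 1`).
  Zeroing pixels outside the nucleus creates an artificial intensity step at
  the mask edge to which the smoothing and Laplacian kernels respond within
  roughly their own reach. A rim of that width is eroded off the mask before
  histogramming and thresholding, so the chain never scores its own masking
  artefact as a focus ring.
* **Peak-side threshold selection.** Foci only ever add response *above* the
  background level, while bright peaks also produce Laplacian side lobes of
  the opposite sign. The entropy split is therefore searched only over
  levels at or above the median of the response distribution; otherwise the
  side-lobe population can win the entropy competition outright and the
  "foreground" degenerates to nearly the whole nucleus. The full signed
  histogram is still accumulated and reported.
* **Signal-presence gates.** A focus is by definition a peak *distinct from*
  background. If the selected threshold lies fewer than `min_threshold_snr`
  robust standard deviations (1.4826·MAD) above the response median
  (default 10), or if it marks more than `max_foreground_fraction` (default
  20%) of in-mask pixels as foreground, the stack has no separable signal
  class — the Kapur criterion is then merely splitting noise into strong and
  weak, which is exactly what happens on sham (unirradiated, focus-free)
  stacks — and the nucleus is reported focus-free with a logged warning. The
  gate value of 10 was calibrated on synthetic sham stacks, which is the
  same role sham slides play in the batch-optimisation workflow; on stacks
  with genuine foci the margin is an order of magnitude larger (tens to
  hundreds of robust SD), so the gate is far from the operating point.

Finally, reconstructed 3D foci whose largest slice region is smaller than
`min_focus_px` (default 5 px) are discarded: a diffraction-limited focus
(≈ 0.25 µm across) covers ≈ 10 px at 0.07 µm/pixel, so anything smaller than
half that is speckle residue, not a focus.

## Moment geometry

Each per-slice binary region R is described by image moments
(`raw_moment()`, `centroid()`, `central_moments()`, `ellipse_params()`):
m₀₀ is the area, (m₁₀/m₀₀, m₀₁/m₀₀) the centroid, and the second central
moments define the best-fit ellipse via the eigenvalues λ₁ ≥ λ₂ of
[[μ₂₀, μ₁₁], [μ₁₁, μ₀₂]]. Orientation uses the two-argument arctangent
θ = ½·atan2(2μ₁₁, μ₂₀−μ₀₂) so the quadrant is correct when μ₂₀ < μ₀₂, with
θ = 0 as tie-break for symmetric regions. Radii are r\_a = 2√(λ₁/m₀₀) and
r\_b = 2√(λ₂/m₀₀), which a rendered filled ellipse of semi-axes (a, b)
recovers to within rasterisation error (≈ 3% for semi-axes ≥ 8 px; the
orientation of near-circular regions, axis ratio ≲ 1.3, is dominated by
rasterisation noise and not meaningful). Eccentricity is reported as the
eigenvalue ratio λ₁/λ₂ (≥ 1; column `ecc_ratio`), which equals the *squared*
axis ratio — the plain axis ratio r\_a/r\_b is emitted alongside as
`axis_ratio` to avoid confusion with the conic eccentricity in [0, 1).
Moments are computed on binary membership; intensity statistics are taken
from the raw focus channel inside R. Degenerate regions (λ₂ = 0) report
`ecc_ratio = Inf` and r\_b = 0 rather than erroring.

## 3D reconstruction

Two foci on adjacent slices belong together iff the centroid of either,
rounded to the nearest pixel (half away from zero), lies inside the other's
pixel set — the literal binary region, not the fitted ellipse. Footprint
overlap alone does not link. Foci separated by an empty slice are never
bridged. The partition of slice foci is the transitive closure of the link
relation (union-find); the Y-junction case — one region linked to two
mutually unlinked regions above — is merged by the closure and flagged
`junction = TRUE` for auditing, since either reading ("one branching focus"
vs "two foci sharing a base") is defensible.

Per 3D focus: the centroid is the area-weighted mean of member centroids
(weights m₀₀; equivalently the binary centroid of the union of member
voxels), converted to µm. The primary volume is the voxel sum
Σᵢ Aᵢ·s²·Δz; an ellipsoid-model volume (4/3)·π·r\_a·r\_b·(z\_extent·Δz/2)
from the largest member is written as a secondary column, since an
"elliptical approximation of the true boundary" admits more than one
formula and the voxel sum is assumption-free. The size category mirrors the
manual scoring convention of judging the most in-focus plane: the
equivalent-circle diameter d = 2√(A\_max·s²/π) of the largest member is
binned small (d < 0.5 µm), medium (0.5 ≤ d ≤ 1.0 µm, boundaries inclusive)
or large (d > 1.0 µm). The nuclear centre for distance tables is the (x̄, ȳ)
of the MIP mask with z at the midpoint of the acquired range (stacks are
acquired about the central focal plane; there is no 3D nuclear
segmentation).

## The synthetic-stack generator

`render_field()` renders what the pipeline consumes: a nuclear channel of
filled ellipses (constant across z) and a focus channel of 3D Gaussian
blobs, over a flat or linearly ramped background, with Poisson shot noise on
the signal and additive Gaussian read noise, quantised to the container bit
depth, all deterministic in the seed. Defaults emulate the acquisition
conditions above: 22 slices, 14-bit, 0.07 µm/pixel, 0.5 µm z-step,
background 500 counts, read noise SD 20. Focus peak amplitude defaults to
10 000 counts (≈ 60% of the 14-bit range): exposures in foci assays are set
so the brightest foci approach but do not reach saturation, and 53BP1 in
particular is a high signal-to-noise marker. Nuclei default to semi-axes
95–120 px (13–17 µm across, typical of spread epithelial nuclei).
`sample_ground_truth()` draws focus lateral FWHMs from {0.3, 0.7, 1.5} µm
with weights 0.25/0.55/0.20 — a small/medium/large mix of the kind seen a
few hours after a ~2 Gy low-LET exposure — and enforces a lateral
separation of at least three focus radii (which also guarantees 3σ), so
that ground-truth counts are unambiguous. Ground truth serialises to a JSON
sidecar next to the rendered TIFFs.

What the generator does *not* emulate: a realistic optical PSF (blobs are
separable Gaussians, not Gibson–Lanni widefield PSFs with their axial
asymmetry and out-of-focus haze), spectral bleed-through, photobleaching,
intra-nuclear background texture (nucleoli, heterochromatin), clustered
sub-resolution foci from high-LET tracks, or touching/overlapping nuclei.
Passing the synthetic-recovery tests therefore demonstrates that the chain
is implemented correctly and is well-behaved under calibrated noise — it
does not certify performance on real stacks, where the batch-optimisation
step and visual review of previews remain essential.

## Batch optimisation

`optimise_batch()` operationalises the settings-testing step that precedes
every experiment: a seeded sample of nuclei (default 10%, at least one per
field) is run under every grid point of pre/post iterations and sensitivity;
each setting is scored by the mean count of single-pixel binary components
per nucleus (the salt-and-pepper signature of under-filtering) and by the
mean change in focus count against the lightest setting (a proxy for
morphology distortion from over-filtering). The recommendation is the
setting with the fewest total iterations whose salt-and-pepper score is
under the cap — i.e. the minimum filtering that does not admit artefacts —
and binary preview images are written so the operator can confirm by eye.
"Artefact" has no operational definition in manual practice, so the two
scores plus previews deliberately keep the human in the loop rather than
fully automating the judgement.

## Numerical and degenerate-input choices

* Histograms are exact (one bin per integer level); thresholds are integer
  gray levels; fractional filter output is binned by
  round-half-away-from-zero (documented because base R rounds half to even).
* All convolutions use reflective (symmetric) padding so frame edges do not
  generate gradient artefacts; binary dilation pads with background and
  erosion with foreground, so closing is idempotent and never erodes at the
  frame edge.
* Both threshold selectors break ties toward the lowest maximising level;
  selector correctness is tested against exhaustive search.
* Degenerate histograms (a single populated level) yield "no nuclei" / "no
  foci" with a warning rather than an error; an all-excluded field produces
  empty result rows, not a failure.
* The pipeline contains no randomness; the only seeded operation is batch
  sampling in `optimise_batch()` (and the synthetic generator). Reruns are
  byte-identical.

## Problem sizes used in the test-suite and acceptance runs

Unit tests run on 9-slice 192² fields with ~50–62 px nuclei to keep the
suite fast; the acceptance checks render full 22-slice 384² fields at the
default calibration with 0/5/15/40 foci per nucleus, five seeds each, and
score exact-count recovery, localisation RMSE and size-category accuracy
against ground truth. These sizes are the package's own validation choices;
both suites use the same code paths as full-frame (1300×1030) processing.

## Known limitations

* No declumping of touching nuclei; such fields should be screened out.
* The 2D nuclear mask is shared across slices; nuclei strongly tilted in z
  are cropped suboptimally.
* Size categories inherit the threshold dependence of binary areas; foci
  near a bin edge can flip category between stacks with very different
  signal composition.
* The Y-junction merge rule can undercount genuinely distinct foci stacked
  obliquely; the `junction` flag marks affected foci.
* Folder-scope histograms assume comparable staining across the folder's
  nuclei; a single very bright nucleus raises the threshold for all.
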