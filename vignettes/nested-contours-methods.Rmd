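---
title: "Detecting mammographic masses with nested iso-contours: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mammographic masses with nested iso-contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NestedContours)
```

## The model

A mass on a mammogram is radiopaque: a bright, roughly compact region
superimposed on textured parenchyma. If the image is viewed as a surface,
a mass is a hill whose horizontal cross-sections — iso-intensity contours —
shrink gradually and stay concentric as the cutting level rises. Parenchyma
texture, Cooper-ligament crossings and vascular structure also produce
contours, but their cross-sections change erratically from one level to the
next: they flood into neighbouring structure, jump in area, or drift
sideways.

The nested contours algorithm (NCA) operationalizes this contrast:

1. **Level sets.** Contours are traced (marching squares with sub-pixel
   linear interpolation) at every threshold `min + i*k` strictly below the
   image maximum, where `min`/`max` are the image's own extremes and `k` is
   the constant gradation step. Placing levels relative to the image's own
   brightness range makes the detector invariant to affine intensity
   rescaling, which matters across exposure settings. Contours touching the
   image border are closed along it, so a mass only partly inside the field
   of view still produces closed, linkable contours.
2. **Nesting.** Chains are grown from the lowest level upward: a contour at
   level `l + k` extends the chain whose level-`l` contour contains it.
   Because the iso-regions at `l + k` are strictly nested in those at `l`,
   each contour has exactly one such parent region. When one contour
   contains several next-level contours (a hill splitting into sub-peaks),
   the chain follows the largest-area one and the siblings start chains of
   their own; ties go to the smallest centroid shift, keeping the procedure
   deterministic.
3. **The discard rule.** For each consecutive pair the dissimilarity is the
   larger of the area-ratio deviation `|1 - A(next)/A(prev)|` and the
   centroid shift normalized by the equivalent radius
   `sqrt(A(prev)/pi)`. A step exceeding its component threshold
   (`tauArea`, `tauShift`) concludes that the outer contour of that step
   does not represent the mass: the chain is cut there, and the maximal
   runs of sequentially similar contours are kept. Cutting — rather than
   keeping only the portion below the first dissimilar step — is what
   separates a mass from the parenchyma contour it floods into: the flooded
   outer contours are discarded while the mass's own similar run survives.
   This reading is also the only one under which two well-separated masses
   yield two disjoint candidates rather than one merged box.
4. **Candidates.** Runs at least `minDepth` deep whose outermost contour
   area lies in `[minArea, maxArea]` become candidates. The representative
   contour is the run's outermost retained one; the box is its axis-aligned
   bounding box; the score is depth-weighted circularity
   `depth * 4 pi A / P^2`, ranking deep, compact nests first. Candidates
   whose boxes nest inside a *closely comparable* candidate box (inner box
   area at least half the outer) are duplicates of the same structure and
   are merged, keeping the outer; a small candidate inside a much larger
   one is a distinct structure — a mass within a broad density region — and
   is kept. An unconditional keep-the-outer merge was tried first and
   discarded: any surviving broad parenchyma run swallowed the lesion
   candidate it enclosed and halved localization accuracy.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k` | `(max - min)/32` | intensity | 32 gradation steps span any brightness range; scale-free and affine-invariant. |
| `minDepth` | 3 | steps | a mass must stay self-similar over at least 3 consecutive levels; 2 admits noise pairs. |
| `tauArea` | 0.35 | — | between consecutive levels a mass's contour area changes by well under 35%; the step where a contour dips into the background-texture band jumps by more. |
| `tauShift` | 0.2 | equivalent radii | concentric mass contours barely move; asymmetric texture attachment drags the centroid by 0.2 radii or more. |
| `minArea` | 25 | px² | below ~5 px across, a "mass" is indistinguishable from speckle. |
| `maxArea` | 25% of image | px² | larger candidates are breast-level structure, not focal lesions. |

The two thresholds were calibrated jointly on the phantom families below:
the area-step distribution of genuine mass chains at `k = range/32` stays
below ~0.3 even for smooth Gaussian-profile masses, while the
background-junction step shows area jumps above 0.35 and/or centroid shifts
above 0.2 equivalent radii. The generic 0.5/0.5 setting retains those
bloated junction contours and inflates the representative box by ~1.8x in
area, halving box-overlap accuracy; all four values remain configurable in
`NCAParams()`.

## Pre-processing (for detectors that want it)

The NCA itself runs on the raw image. The three-step enhancement offered
alongside it (for CNN-style consumers) is: truncation normalization
(effective min/max as the 1st/99th percentiles of the non-zero breast
pixels, clip and rescale to full range), CLAHE at two clip limits (1 and 2,
read literally as multiples of the uniform per-tile bin height; 8 x 8
tiles), and stacking the three results into one 3-channel image. The CLAHE
here is the classic tile-LUT construction with clipped histograms,
redistributed excess and bilinear blending between tile mappings; a single
unclipped tile reduces exactly to global histogram equalization, and a
constant image maps to itself (tiles whose pixels fall into a single
histogram bin use an identity mapping, which is what makes the flat-image
contract hold).

## Augmentation

`eightfoldAugment()` draws, per output, a rotation angle uniform in
[0, 360) degrees (clockwise about the image centre, in y-down pixel
coordinates), horizontal and vertical mirroring each with probability 1/2,
and a translation uniform within ±10% of each dimension. One affine matrix
drives both the raster warp (inverse-mapped nearest neighbour, exposed
corners filled with 0 — mammography background is black) and the box
transform (map the four corners, re-axis-align, clip), so image and
annotations cannot drift apart. `mosaicAugment()` scales each of four
inputs to the output shape (nearest neighbour, so every output pixel
originates from exactly one input), crops each centrally to one quadrant of
a mosaic centre drawn uniformly within the central half, and drops boxes
that lose more than 80% of their area. Rotation-angle distribution, shift
range and the drop threshold are not dictated by the method's description;
the defaults above are stated once here and exposed as arguments.

## The synthetic phantoms

The phantom generator exists so the detector and the evaluation stack can
be exercised end to end, with exact ground truth, in a repository that
carries no clinical images. It is stylized, not photorealistic.

* **Backgrounds.** A half-elliptical breast support against the left
  (chest-wall) edge; base intensity and band-limited texture amplitude grow
  with ACR density class (means 60/90/120/150; texture amplitudes
  4/10/16/24 at 8 bit). Texture is white noise smoothed at a correlation
  length of 6 px — fibroglandular grain is fine relative to a 1–2 cm mass —
  and the dense classes C/D add a broader structural component (sigma 20 px
  at half amplitude). Additive Gaussian read noise (sigma 2 by default)
  rather than Poisson: simpler, and sufficient for contour-stability
  testing.
* **Lesions.** Six appearance families: a spiculated star (Gaussian core,
  8 thin radial ridges with a defined length — a sharp sigmoid cut-off at
  one lesion radius), a wide Gaussian for unclear borders, a flat ellipse
  with a sharp sigmoid edge for clear borders, an anisotropic two-lobed
  blob for asymmetric density, the unclear-border shape at an amplitude of
  20% of the background texture amplitude for lesions invisible on the
  dense background, and the clear-border shape placed at the chest-wall
  edge for partly visualized masses. Peak amplitude is
  `contrast * (255 - local background median)`; default contrasts are 0.8
  for the clearly visible families (spiculated masses of BIRADS 4–5 are
  distinctly brighter than parenchyma texture), 0.5 for unclear borders and
  0.4 for asymmetric densities.
* **Ground truth.** The truth mask is the lesion patch at or above 10% of
  its peak — the visible extent, down to where the lesion fades into the
  background. This matches how a reader annotates (out to the edge of
  visibility) and makes truth and detection extents commensurate: the
  detector's outermost contour sits about one gradation step above
  background, i.e. also near 10% of a typical lesion amplitude. Truth boxes
  are the minimal axis-aligned boxes of the clipped masks.
* **The default test set** is 100 single-lesion phantoms with lesion-type
  counts 16/30/8/28/16/2 (star-like / unclear border / clear border /
  asymmetric / invisible / partly visualized) and ACR density counts
  27/33/31/9, paired at random under the master seed, plus 100 lesion-free
  phantoms with the same density proportions; 512 x 512 at 8 bit, a desk
  scale at which the geometry of the method is fully exercised without
  full-resolution mammography sizes.

What passing tests on these phantoms shows — and what it does not: the
nesting logic discriminates stable bright hills from erratic texture across
the stated difficulty spectrum, localization is tight enough for the 0.5
IoU rule on clearly visible lesion families, and invisible-on-dense-background
lesions are (by construction) at the detection floor. It does not show
clinical sensitivity: real parenchyma is not band-limited Gaussian texture,
real spicula are not eight cosine ridges, and no claim about reproducing
sensitivity on clinical images is made.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, half-open, x = column, y = row, everywhere.
* A constant image has no level crossings: contour extraction returns an
  empty list and detection returns no candidates, while truncation
  normalization raises an error (there is no dynamic range to normalize).
* Border-touching contours are closed along the border by clamping the
  padded-trace vertices; consecutive duplicate vertices are removed.
* Containment uses a strict-interior point-in-polygon test with a
  point-to-segment fallback so vertices lying exactly on the outer polygon
  still count as contained.
* Chain linking exploits the nesting structure of iso-regions: one interior
  point decides each contour's parent, and on speckle-heavy levels parents
  are resolved through a connected-component labelling of the thresholded
  image, with polygon tests retained for the ambiguous cases (hole
  boundaries, fully border-clamped contours).
* Two-decimal truncation guards against binary floating point
  (`floor(x * 100 + 1e-9)`), so an exact 0.60 truncates to 0.60, not 0.59.
* Undefined precision (no detections) is reported as `NA`, never silently 0.
* Ties in candidate ordering are broken by box coordinates; ties in chain
  extension by centroid shift. Two runs of any pipeline stage on identical
  input produce byte-identical output.

## Known limitations

* The dissimilarity thresholds are calibrated for `k = range/32`; a much
  finer gradation step shrinks per-step area ratios and would warrant
  rescaling `tauArea`.
* The NCA is sensitivity-oriented and emits many false-positive markings on
  dense parenchyma (by design; its clinical role pairs it with reader
  review). Candidate counts on dense-background phantoms reflect that.
* A mass bridged to an equally bright neighbouring structure over many
  levels is reported as the joint structure (the discard rule only cuts
  where the joint contour stops being self-similar). On textured
  backgrounds this makes per-lesion localization at the 0.5 IoU rule a
  near-threshold event for a small fraction of lesions, so recall
  estimates over a few dozen lesions carry binomial uncertainty of several
  percentage points across generator seeds.
* DICOM input is out of scope here; PNG and TIFF (8/16 bit) are supported.
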