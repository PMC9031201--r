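# NestedContours

Suspicious-lesion detection on 2-D mammography images with the **nested
contours algorithm (NCA)**, plus the surrounding machinery a detection study
needs: truncation-normalization/CLAHE pre-processing, annotation-consistent
training-set augmentation, detection evaluation (IoU matching,
precision/recall, F1 and F-beta, 11-point average precision, per-lesion-type
tallies, two-proportion comparison), and a seeded synthetic phantom
generator so the whole pipeline is testable without clinical data.

## Who it is for

Researchers in mammography CAD who want a transparent, non-learning
reference detector and a reproducible evaluation stack. Masses are
radiopaque: they appear as bright, roughly compact regions whose
iso-intensity contours shrink gradually and stay concentric as the
brightness level rises. The NCA turns that observation into a detector and
needs no training data and no pre-processing.

## The algorithm

For an image with intensity range `[min, max]`, level sets are traced at
thresholds `min + k, min + 2k, ...` with a constant gradation step `k`
(default `(max - min)/32`). Contours at consecutive levels that nest
geometrically are linked into chains. A chain step whose contour differs too
much from the nested one of the previous step — area-ratio deviation
`|1 - A(next)/A(prev)|` above `tauArea`, or centroid shift above `tauShift`
equivalent radii — concludes that the outer contour does not represent a
mass, and the chain is cut there. Maximal runs of sequentially similar
contours that are at least `minDepth` deep and of plausible area become
lesion candidates, each reported with its representative (outermost
retained) contour, bounding box, nest depth, and a depth-weighted
circularity score `depth * 4 pi A / P^2`.

Evaluation follows the standard detection conventions: a predicted box is
correct when `IoU = S(A ∩ B) / S(A ∪ B) >= 0.5`; precision `TP/(TP+FP)`,
recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and the recall-weighted score
`F_beta = (1 + beta^2) P R / (beta P + R)`; average precision is the
11-point interpolated form. Printed two-decimal table values use truncation
(`0.857 -> 0.85`), and F1/F-beta are derived from the two-decimal
precision/recall, the form in which such tables are conventionally printed.

## Worked example

```r
library(NestedContours)

# a 512x512 phantom: ACR density C background with one spiculated mass
ph <- composePhantom(PhantomSpec(
  densityClass = "C",
  lesions = list(list(lesion_type = "star_like", center = c(200, 250),
                      size_px = 55, contrast = 0.8, n_spicula = 8L)),
  seed = 42L))
ph$annotations
#>   x_min y_min x_max y_max lesion_type density_class
#> 1   172   222   229   279   star_like             C

dets <- detectionTable(detectLesions(ph$image, NCAParams()))
m <- matchDetections(dets, ph$annotations)
m$matches
#>   det gt      iou
#> 1   5  1 0.569406
dets[m$matches$det, ]
#>   x_min y_min x_max y_max    score depth
#> 5   177   225   214   275 2.497307     8
m$counts
#> ConfusionCounts: TP=1 FP=9 FN=0
```

The detector marks the mass with a box overlapping the truth box at
IoU 0.57 (a hit at the 0.5 rule) and, characteristically for the NCA, adds
false-positive markings on dense-parenchyma structure; sensitivity is its
design goal, and downstream review or filtering handles the rest.

Evaluating a two-detector comparison from per-type outcome counts:

```r
counts <- data.frame(lesion_type = LESION_TYPES,
                     tp = c(16, 24, 8, 27, 16, 2),
                     fp = c(9, 14, 4, 18, 16, 2),
                     fn = c(0, 6, 0, 1, 0, 0))
rep <- aggregateByType(counts, betas = c(10, 50, 100))
rep
#> MetricReport (truncate_2dp): TP=93 FP=63 FN=7
#>   precision 0.59  recall 0.93  F1 0.72
#>   F-beta: beta=10:  8.11, beta=50: 45.09, beta=100: 91.56
```

## Command line

A thin CLI over the same functions lives at `inst/cli/nca.R`
(`Rscript <library>/NestedContours/cli/nca.R <subcommand> ...`) with
subcommands `preprocess | detect | augment | synth | evaluate | run`.

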