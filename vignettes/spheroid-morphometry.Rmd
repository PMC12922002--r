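---
title: "Brightfield spheroid morphometry with spheromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brightfield spheroid morphometry with spheromorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Tumor spheroids embedded in a hydrogel and imaged by transmitted-light
(brightfield) microscopy appear as dark, roughly compact objects on a bright,
unevenly illuminated background. As cells undergo an epithelial-to-mesenchymal
transition (EMT) the spheroid outline changes character: a compact,
near-circular ball grows irregular and sprouts thin projections ("spikes").
spheromorph quantifies that change from single-plane TIFF images, with no
fluorescent label, by segmenting each spheroid and reducing its outline to
three descriptors:

* **Form factor** $FF = 4\pi A / P^2$, equal to 1 for a perfect circle and
  strictly below 1 for every other shape.
* **Solidity** $S = A / A_{hull}$, the fraction of the convex hull the object
  fills; spikes and indentations pull it below 1.
* **Mesenchymal morphology score** $MS = 1 / (FF \cdot S)$, the working
  EMT proxy: 1 for an ideal circle and increasing as the outline grows
  irregular and spiky.

Scores are averaged per treatment condition and imaging day, normalized to a
control condition at the baseline day, and compared by Student's *t*-test.

## The processing chain

Each image passes through a fixed sequence; every stage maps a $[0,1]$
intensity image to a $[0,1]$ image.

1. **Load and normalize.** TIFFs (8/16-bit, grayscale or RGB) are divided by
   the dtype maximum, because every threshold below is defined on the $[0,1]$
   scale. Only the first page of a multi-page file is read: the protocol
   exports one focal plane per file. Metadata (experiment, spheroid id,
   channel, optionally day/condition) is parsed from the filename by a
   named-group regular expression anchored to the whole name; a sidecar
   `metadata.csv` (`spheroid_id,day,condition`) covers schemes that do not
   encode day or condition. Note that with the default pattern
   `(?P<Experiment>.*)_(?P<SpheroidID>.*(_\d+)?)_(?P<Channel>TRANS).tiff` the
   leading group is greedy, so an id containing underscores is split in favor
   of the experiment field (`OA50_sph_03_TRANS.tiff` parses as experiment
   `OA50_sph`, id `03`). This follows the reference regular-expression engine;
   write unambiguous ids (or a stricter pattern) if the distinction matters.
2. **Grayscale** by equal channel weights (1/3, 1/3, 1/3) — brightfield
   channels carry no perceptual meaning, so the conversion equalizes them
   rather than applying luma weights.
3. **Sharpen** by unsharp masking, $I + \alpha (I - G_{\sigma_s} I)$, with
   $\alpha = 1$ and $\sigma_s = 1$ px by default. This is a standard
   contour-emphasis operator; the amount and blur are configurable.
4. **Smooth** with a Gaussian, $\sigma = 2$ px by default (the useful range
   is 1.5–2; the default sits at the top for stronger noise suppression
   before differentiation). Blurring after sharpening quiets background
   noise while the boosted object contours survive.
5. **Sobel edge magnitude**, rescaled by its per-image maximum so the result
   is a $[0,1]$ edge mask — bright rims on a dark background. All
   convolutions use reflective boundary padding, so the image frame itself
   never generates edges.

Segmentation then works on the edge mask:

6. **Threshold** by minimum cross-entropy (Li's criterion), evaluated on a
   256-bin histogram with every interior bin edge as a candidate, which makes
   the result deterministic and independent of the input bit depth. Ties take
   the smallest candidate, which favors keeping thin projections. The raw
   threshold is multiplied by a correction factor (0.7) and clamped to
   bounds (default $[0.02, 1.0]$; a lower bound of 0.015 is the documented
   setting for capturing very thin spikes). The threshold smoothing scale is
   0: nothing is smoothed between edge enhancement and thresholding.
7. **Solidify.** The thresholded edge band is closed (disc structuring
   element, radius `min_diameter/50`) and hole-filled. Because the gradient
   band straddles the true boundary roughly symmetrically, filling to its
   outer edge would inflate every object by half the band thickness; the
   filled mask is therefore eroded by half the estimated band thickness
   (band area / outline length / 2). The correction is skipped when the
   input mask is already mostly solid, so solid inputs pass through
   unchanged apart from hole filling.
8. **Declump.** Seeds are local minima of a surface blending the smoothed
   intensity (spheroid interiors are dark) with the negated normalized
   distance transform, thinned to a minimum separation of `min_diameter/2`.
   A seed must also sit at distance-transform depth of at least
   `min_diameter/4`: a genuine spheroid center in a clump lies at depth
   comparable to its radius, whereas a spike arm is shallow and must not
   trigger a split. Pixels are then assigned to the geodesically nearest
   seed within the mask, which divides touching equal discs exactly along
   the perpendicular bisector of their centers. Pure intensity seeding is
   intentionally regularized here: on a flat-interior object (and on the
   synthetic renderer's objects in particular) the interior intensity
   carries no structure at all, and the distance-transform term supplies
   the missing shape cue.
9. **Filter.** Objects are kept if their equivalent-circle diameter
   $2\sqrt{A/\pi}$ lies within $[250, 3000]$ px and (by default) they do not
   touch the image border; survivors are relabeled contiguously. Labeling is
   8-connected; hole filling is 4-connected.

## Measurement conventions

* **Area** is the pixel count.
* **Perimeter** uses a smoothed boundary polygon: the 8-connected contour of
  pixel centers is smoothed by a circular moving average (window 5) to remove
  rasterization staircase jitter, and $\pi$ is added to account for the
  half-pixel outward offset of a pixel-center contour (offsetting a simple
  closed curve by $d$ adds $2\pi d$ to its length). On exact test geometry
  this estimator lands within about 1% of truth for discs with radii from 50
  to 600 px and within about 2.5% for squares and stars; a naive chain-code
  length would bias the form factor low by roughly 20%, and that bias would
  propagate directly into the mesenchymal score. A 4-direction Crofton
  estimator is available via `perimeter_method = "crofton"`.
* **Convex hull area** is the lattice-point count of the hull of boundary
  pixel centers (shoelace area + boundary points/2 + 1, by Pick's theorem).
  This equals the pixel-rasterized hull area and guarantees
  $A_{hull} \ge A$, so solidity can never exceed 1; a plain shoelace area on
  pixel centers would violate that for convex objects (a $100\times100$
  square has shoelace hull 9801 but area 10000).
* **Major axis length** comes from ellipse-equivalent second central moments
  ($4\sqrt{\lambda_{max}}$, with the 1/12 per-pixel variance term).
* Discretization can push the form factor of small discs marginally above 1;
  values are reported as computed, without clamping, so estimator bugs stay
  visible. Objects under 5 px are skipped with a warning.
* All coordinates in outputs are 0-based pixel centers, row-major, origin at
  the top-left.

## Aggregation

Objects are first averaged within a spheroid, making the spheroid the
replication unit; summaries then report n, mean, and sample SD of the
per-spheroid scores for each (condition, day) cell. Normalization divides
every cell mean by the control condition's mean at the baseline day (the
control baseline maps to exactly 1). The default test is the classical
pooled-variance two-sided Student's *t*-test on per-spheroid scores, run per
day against the control (the natural reading of per-day significance stars);
Welch's form and Benjamini–Hochberg adjustment are available but off by
default, since raw per-test significance is the reporting convention being
mirrored. Zero-variance degenerate groups are handled explicitly
($t = 0, p = 1$ for equal means).

## The synthetic study generator

Because the original microscope images are not redistributable, the package
ships a generator whose outputs stand in for them in every test:

* **Geometry.** Epithelial morphology is a disc; mesenchymal morphology is a
  star polygon with $2k$ vertices alternating between an outer and an inner
  radius. Both have closed-form area, perimeter, and convex hull, so every
  descriptor has an exact continuous-geometry truth value computed from the
  vertices — never from the rasterized mask. (For shallow stars with
  inner/outer ratio above $\cos(\pi/k)$ the inner vertices protrude past the
  outer polygon's hull; the hull is therefore always computed from all
  vertices.)
* **Rendering.** `image = background + linear gradient − contrast × blurred
  mask + Gaussian noise`, clipped to $[0,1]$: a bright field (0.85) with a
  mild illumination ramp (amplitude 0.08), a dark object (0.25), an optical
  softness blur (σ = 3 px), and additive noise (SD 0.02). All randomness is
  seeded; a global seed fans out to per-image streams by a stable hash of the
  spheroid id, so regeneration is byte-identical.
* **Longitudinal design.** The default simulated study mirrors the design it
  emulates: 15 spheroids per condition, four conditions (a BSA control and
  three oleic-acid doses), imaged on days 1, 3, 5, 7 and 10 — 300 frames of
  600×600 px. The control stays a disc (exact MS = 1, radius 160 px). Treated
  conditions are 8-spike stars (outer radius 230 px) whose inner/outer ratio
  declines linearly with day: from 0.90 at 0.0056/day (low dose, mild
  progression), from 0.87 at 0.0167/day, and from 0.84 at 0.030/day (high
  dose, rapid progression), spanning exact scores from ≈1.1 to ≈5 — the
  biologically plausible range of a strong EMT response. Per-spheroid jitter
  (±4% radius, ±0.015 ratio, random rotation and small center shifts) keeps
  frames from being clones while preserving the ordering of condition means.
  Filenames follow `{Experiment}_{condition}-s{nn}-d{dd}_TRANS.tiff` so the
  default metadata pattern parses them, with day and condition supplied by
  the sidecar CSV (the canonical filename scheme carries no day field).

What the generator does *not* emulate: real point-spread optics and z-blur,
hydrogel texture, debris, contrast drift, overlapping or out-of-frame
spheroids, and intensity heterogeneity inside the spheroid. Passing the
end-to-end suites therefore demonstrates that the chain is internally
consistent and recovers known geometry under realistic noise — not that it
matches any particular microscope's output. On real data the practical
failure modes remain poor focus and low rim contrast.

## Numerical choices and verified tolerances

The test suite pins these properties, at these tolerances, on synthetic
geometry:

* Exact circle form factor is 1 to machine precision; rasterized discs
  (radius 50–600) stay within 3% of 1 and never exceed 1.03.
* The minimum cross-entropy threshold equals an exhaustive scan of all 256
  histogram-edge candidates on hundreds of seeded bimodal histograms.
* Full-pipeline recovery of discs (radius 150/300/600, noise SD 0.03):
  exactly one object, area within 5%, MS within 10% of 1. Star recovery is
  harder — spike tips are thin structures at the smoothing scale — and holds
  within 20%.
* Two equal discs overlapping by 20% of a radius split along the
  perpendicular bisector within 5 px.
* Descriptors vary under rotation and 2×/4× rescaling by under 2%.
* Empirical type-I error of the t-test at α = 0.05 stays within 0.05 ± 0.02
  over 1000 null simulations.

Problem sizes in the routine suite (image sizes of 400–1300 px, a 300-frame
simulated study) were chosen as the smallest scales that still exercise the
250 px minimum-diameter gate and the full longitudinal design.

## Known limitations

* The sharpening macro used by the original acquisition workflow is not
  published; unsharp masking reproduces its described effect, so functional
  — not numerical — equivalence with that workflow is the claim.
* Perimeter estimation conventions differ across tools; absolute form-factor
  values from other software will differ by a few percent, though rankings
  and trends are robust to this.
* Declumping is tuned for objects near the configured diameter range;
  heavily fused clusters of many spheroids are out of scope.
* Objects are tracked across days only through filename identity — there is
  no positional tracking.

## A worked example

```{r example}
library(spheromorph)

# simulate a small study: 2 conditions, 2 days, 3 spheroids each
dir <- tempfile("study")
generate_timecourse(dir, schedules = default_schedules(c("BSA", "OA150")),
                    days = c(1L, 10L), n_spheroids = 3L, seed = 1L)

cfg <- pipeline_config(aggregate.control_condition = "BSA")
experiment <- run_pipeline(dir, cfg, out_dir = file.path(dir, "out"))
experiment$summaries     # mean MS per condition/day, normalized to BSA day 1
experiment$ttests        # per-day comparisons against the control
```
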