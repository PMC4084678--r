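---
title: "Fractal morphometry and the two-stage diagnosis cascade: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal morphometry and the two-stage diagnosis cascade: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepfract)
```

## The problem

Distinguishing hepatocellular carcinoma (HCC) from liver metastases (LM)
and from normal parenchyma on histology is ordinarily a job for an
experienced pathologist. Two tissue features carry much of the signal:
malignant nuclei are large and pleomorphic, with irregular chromatin
contours (hematoxylin stains them blue), and the microvasculature differs
sharply -- HCC is richly vascularised with tortuous, sprouting vessels
(CD31/CD34 immunolabeling renders them brown), while metastases show a
relative paucity of labelled vessels. `hepfract` operationalises both
observations with a single morphometric quantity, the box-counting
fractal dimension (FD) of each segmented element, and feeds FD summaries
to a cascade of two small feed-forward neural networks: the first labels
every image *malignant* or *benign*; the second labels each case with at
least one malignant image *HCC* or *LM*.

No public image set accompanies this problem, so the package ships a
synthetic-cohort generator that emulates the relevant structure of the
data (colours, element geometry, class-dependent contour complexity,
case/slide/image hierarchy) and provides exact ground truth. Everything
below is computable from a fresh install with no external data.

## Segmentation in HSV space

RGB is the wrong space for stain thresholds: stain identity is chromatic,
and a blue-ish and a brown-ish pixel can have overlapping channel values.
After the hexcone transform to hue-saturation-value, stain identity lives
almost entirely in hue. The pipeline:

1. `rgb_to_hsv()` -- pixelwise transform (hue in degrees, saturation and
   value as fractions);
2. `flatten_value()` -- the value (brightness) plane is set to a constant
   (default 1), collapsing the space to the hue-saturation plane so that
   section thickness and illumination do not influence the thresholds;
3. `segment_channel()` -- a pixel belongs to a channel when its circular
   hue distance to the channel's reference hue is at most the tolerance
   and its saturation reaches the floor;
4. `extract_elements()` -- connected components (8-connectivity by
   default, 4 available), dropping components under `min_pixels = 10`
   (sub-resolution debris) and, for nuclei, components touching the
   image border: an incomplete nucleus has a truncated contour, which is
   exactly the feature being measured. Vessels keep border components --
   vessels legitimately cross the field.
5. `manual_override()` -- a pure set-edit on the mask (add/remove pixel
   sets), the scripted equivalent of an operator correcting a threshold
   failure before FDs are computed.

Shipped thresholds (`default_channel_specs()`): nuclei 240 deg +/- 35,
vessels 25 deg +/- 35, saturation floor 0.25 for both. Real slides need
per-batch tuning (that is what `manual_override` and the config file are
for); these defaults are matched to the generator's palette, which was
chosen so that the two channels and the near-achromatic background are
linearly separable in hue-saturation -- sharp tests, not a claim about
real stain spectra.

## The box-counting estimator

For a binary raster, pad to the smallest power-of-two square
(`pad_to_pow2()`), count the occupied cells $N(e)$ of grids of box size
$e =$ side, side/2, ..., 1, and fit least squares to the points
$(\log 1/e, \log N(e))$. Under the power law $N(e) = C\,e^{-D}$ the slope
is the dimension $D$:

$$\widehat{D} \;=\; \mathrm{slope}\bigl(\log N(e) \sim \log 1/e\bigr).$$

Numerical choices, each visible in `box_counting_fd()`:

* **Sign convention.** Regressing on $\log(1/e)$ rather than $\log e$
  makes the slope positive, matching the convention that a filled region
  measures 2 and a point 0.
* **Scale range.** The fit includes every dyadic scale down to $e = 1$
  and up to the full padded side (where $N = 1$ for any non-empty mask).
  A single grid anchored at the origin is scanned -- no multi-offset
  averaging.
* **Bounds.** Because $N$ can at most quadruple and never decrease when
  $e$ halves, every pairwise slope lies in $[0, 2]$, and a least-squares
  slope over equally spaced abscissae is a convex combination of pairwise
  slopes -- the estimate is mathematically confined to $[0, 2]$ with no
  clamping.
* **Degenerate input.** A 1x1 mask offers one scale; its FD is defined
  as 0. An empty mask is an error: callers must skip empty elements.
* **Determinism.** The estimator is a pure function; identical masks give
  bit-identical results.

The estimator is validated against closed forms (filled square exactly 2,
line exactly 1, point exactly 0 -- these are exact because the counts lie
exactly on the fitted line) and against self-similar sets with known
limiting dimension: the Sierpinski triangle ($\log 3/\log 2 \approx
1.585$, exact at every dyadic scale by construction), the Sierpinski
carpet ($\log 8/\log 3 \approx 1.893$, approximate because the dyadic
grid is incommensurate with the triadic recursion), and a von Koch curve
($\log 4/\log 3 \approx 1.262$). A brute-force nested-loop cell scan
serves as an independent oracle for the counts on random masks.

### What is measured per element

`element_fd()` rasterises an element onto its tight bounding box (making
the estimate position-independent) and, by default, measures the
element's **boundary contour** -- the pixels with a 4-neighbour outside
the set. The package's FD is a roughness measure of the perimeter line of
a nucleus or vessel outline. This choice is forced by geometry: the
box-count dimension of a *filled* blob a few tens of pixels across is
dominated by area scaling -- it is maximised by the smooth disk and
*decreases* under any boundary perturbation -- so filled measurement
cannot distinguish a smooth nucleus from a crenellated one, and it cannot
produce values near 1 for small smooth elements, which is where normal
tissue sits. Contour measurement does both: a smooth outline measures
near 1 and rises toward 2 with convolutedness. `contour = FALSE` is
available for the filled measurement (a filled power-of-two square then
measures exactly 2).

## Feature construction

A feed-forward network has a fixed input width, so the variable-length
multiset of element FDs in an image is reduced to order statistics --
median, minimum, maximum FD plus the element count, per channel
(`summarize_image()`, 8 features). Median/min/max are the summaries by
which the class-conditional FD distributions separate; the counts encode
vascular density, which the FDs alone do not (metastases: few vessels).
A channel with no surviving elements contributes the sentinel (0, 0, 0,
count 0) -- "no detected vessels" is diagnostic information, not missing
data, and discarding such images would bias the cohort.

Stage 2 sees two numbers per case (`summarize_case()`): the means of the
malignant-flagged images' median FDs, nuclei and vessels. During cascade
*training* the truly tumour-labelled images define the aggregation; at
*prediction* time the stage-1 flags do. A case with no malignant-flagged
image is reported benign and never reaches stage 2.

## The network and its training protocol

`fdnn()` fits input -> one logistic-sigmoid hidden layer (default width
10; the published architecture fixes one hidden layer but not its width)
-> softmax output, minimising cross-entropy by plain mini-batch gradient
descent (no momentum or adaptive optimisers -- the problem is
low-dimensional and nearly separable, and plain descent keeps the
arithmetic transparent and exactly reproducible). Defaults: learning
rate 0.05, batch 32, at most 500 epochs, early-stopping patience 25.

Two evaluation protocols coexist, as both are standard for this kind of
model:

* a stratified 50/25/25 split into training / validation / testing: the
  validation loss drives early stopping (the kept weights are the
  best-validation-epoch snapshot) and the test quarter, untouched by
  fitting, yields the reported accuracy;
* `cross_validate()`: stratified 10-fold cross-validation in which every
  sample is predicted exactly once by a model that never saw it, pooled
  into one confusion matrix.

Features are z-scored with constants estimated **from the training
portion only** and stored in the model; raw FDs span a narrow range and
standardisation stabilises the descent. All randomness (split, weight
initialisation, per-epoch shuffles) derives from one seed through named
substreams, so a fit is bit-reproducible; the analytic gradients are
verified against central finite differences at relative error below
1e-6. The per-sample output is the softmax vector; the reported
probability score is 100 times the winning activation -- the percentage
of the ideal score.

## Agreement statistics

`class_metrics()` gives per-class recall (column-normalised diagonal),
overall accuracy, and -- once a positive class or superclass (e.g.
malignant = {HCC, LM}) is designated -- sensitivity and specificity.
`cohen_kappa()` computes chance-corrected agreement
$\kappa = (p_o - p_e)/(1 - p_e)$ with the large-sample (Fleiss--Cohen--
Everitt) standard error, a 1.96-multiplier Wald interval clipped to
$[-1, 1]$, and a qualitative band: negligible / slight / moderate /
great / excellent. The conventional band edges leave gaps (0.20 vs
0.21); they are implemented as half-open intervals split at the rounding
midpoints 0.205, 0.405, 0.605, 0.805, which is monotone, total, and
reproduces every banded example. Categories are nominal here, so the
default is unweighted kappa; linear weights are available for ordered
scales. The kappa point estimate is cross-checked against an independent
implementation (`e1071::classAgreement`) in the test suite; the standard
error has no installed reference implementation and is verified against
a hand-computed closed form.

## The synthetic cohort

`cohort_spec()` describes the study structure: 20 cases by default (10
HCC, 10 LM, alternating), 10 slides per case -- 5 tumour, 5 normal
parenchyma -- and 10 images per slide of 512 x 512 pixels: 100 images
per case, 2000 in all. Tumour-slide images are drawn with the case
class's parameters, normal slides with the normal-tissue parameters.
Every image is generated from a named substream of the root seed
(`image_fn(case, slide, image)`), so any single image can be regenerated
independently and a cohort never needs to reside in memory or on disk.

**Nuclei** are disks with a randomly perturbed radial boundary
$r(\theta) = R\,(1 + \sum_k a_k \cos(k\theta + \varphi_k))$. The wave
numbers are octave-spaced ($k = 2, 4, 8, \dots$ up to about $\pi R$,
i.e. wiggles down to roughly two pixels' wavelength) and the amplitudes
grow proportionally to $k$, normalised so $\sum_k |a_k|$ equals the
roughness amplitude. The spectrum matters: perturbation concentrated at
low frequencies deforms the shape without convoluting its contour, and
the measured contour dimension stays flat (or falls); the
fine-scale-weighted octave spectrum gives a strictly monotone roughness
-> FD map, which is the knob the classes are built on. Roughness is
capped at 0.6 so the radius stays positive.

**Vessels** are constant-speed random walks whose heading receives a
Gaussian increment (s.d. = tortuosity, radians) per step, reflected at
the field bounds, dilated to the target calibre, with optional daughter
branches -- sprouting microvessels. Tortuosity zero with no branching is
a straight segment.

Class parameters (`cohort_spec()$class_params`) encode the histology:
HCC -- few large rough nuclei (radius 22-40 px, roughness 0.35) and many
thick tortuous branching vessels; LM -- intermediate nuclei (14-26 px,
0.16) and sparse vessels; normal -- small smooth nuclei (8-14 px, 0.04)
and occasional thin straight vessels. Roughness and tortuosity are
ordered HCC > LM > normal by construction (the constructor enforces it),
which makes the class-conditional FD distributions stochastically
ordered the same way -- the qualitative ordering reported for real
tissue. The magnitudes were anchored once with
`calibrate_roughness()`, which bisects the roughness amplitude against a
target median contour FD; with the published HCC median nuclear FD as
target the procedure lands near the 0.35 default. Exact real-tissue
medians are not reproduced and are not asserted anywhere: real chromatin
texture, stain variability and optics are outside the generator's scope.

Rendering order is vessels first, then nuclei, with rejection-sampled
nucleus centres that avoid vessels: a crossing would otherwise fragment
one of the structures and corrupt its contour statistics. Ground-truth
masks record final pixel ownership, so they are exactly consistent with
the rendered pixels; with the shipped thresholds, segmentation recovers
them with pixel recall and precision of 1.0 on the default cohort. That
is by construction (disjoint hue bands, no noise, no anti-aliasing): it
validates the wiring of the segmentation chain, and says nothing about
real stained tissue, where thresholds overlap and manual correction is
expected.

### What passing tests do and do not show

The synthetic cohort demonstrates that the pipeline recovers known
structure: perfect segmentation of a separable palette, FD orderings
that follow the built-in complexity ordering, a cascade that reaches
high image-level accuracy and correct case labels when classes are
separated by construction. It does not demonstrate clinical performance:
real nuclei overlap and vary in stain uptake, vessels and nuclei
interleave, and class distributions overlap far more than the generator's.

## Problem sizes and runtime

The shipped tests and the acceptance script use the default cohort (20
cases, 2000 images at 512 x 512), which processes in a few minutes on a
single core; unit tests use miniature cohorts (2 cases, 96 px images)
and masks up to 64 x 64 for the brute-force oracle comparisons. Training
runs at most 500 epochs with patience 25 and usually stops far earlier.

## Known limitations

* Thresholds are global per channel; no adaptive or learned segmentation,
  no stain deconvolution, no whole-slide pyramids.
* FD is the only shape feature; no texture, intensity or size features
  beyond the element count.
* The cascade's stage 2 sees only two numbers per case; with 20 cases
  its training set is small, which the synthetic separation tolerates
  but real data might not.
* Kappa is two-rater only (no Fleiss multi-rater extension, no bootstrap
  intervals).
* The BMP reader covers the uncompressed 24-bit flavour only.
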