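---
title: "Methods: ROI detection, trace normalisation, clustering and laminar mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI detection, trace normalisation, clustering and laminar mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roiscope)
```

This vignette documents the models and numerical choices behind
`roiscope`, in the spirit of a methods section: what each stage assumes,
which parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The analysis problem

Functional fluorescence imaging of intact neural tissue (multi-photon
calcium imaging of labelled synapses or somata, but equally wide-field,
confocal or TIRF recordings) produces movies in which many structures of
interest must be found, their time courses measured and normalised, their
responses grouped, and — in layered tissue such as the retina — their
depth within the layer recorded. The package implements this chain as
composable stages over simple containers: an `image_stack` (array
`[y, x, t]`), an `roi_mask` (signed label matrix), a `trace_matrix`
(ROI × time), an isocontour family, and a flat CSV results store.
Coordinates are 1-based with x = column and y = row, the native R
convention.

## Registration

Motion correction is deliberately modest: rigid translation per frame,
estimated by FFT cross-correlation against a reference frame, with
out-of-frame pixels filled by the frame median (neutral for later
averaging). Integer displacements are recovered exactly; a parabolic
subpixel refinement is available (`subpixel = TRUE`). The estimator is
pluggable (`engine` argument) because richer schemes (affine, B-spline)
are preprocessing choices orthogonal to the rest of the pipeline.
Registration runs *before* background subtraction in the file pipeline;
nothing downstream depends on that order for translation-only motion, but
fixing it makes runs reproducible.

A featureless (constant) frame carries no registration signal; the shift
is reported as (0, 0) with a warning rather than an error, since blank
frames occur in real recordings.

## ROI detection on the Laplace operator

Thresholding raw intensity fails when brightness spans an order of
magnitude: a threshold high enough to separate bright terminals loses dim
ones, and one low enough for dim terminals merges bright ones with the
background. The package instead thresholds the discrete Laplacian — the
sum of unmixed second spatial derivatives — which is negative at local
brightness *peaks* regardless of their absolute level.

Numerical choices:

* **Kernel.** The 4-neighbour stencil (centre −4, N/S/E/W +1), the
  simplest discretisation consistent with the operator's definition; an
  8-neighbour variant is available behind a flag. Exact pixel-level
  agreement with other implementations' Laplacian kernels is not claimed.
* **Edges.** Replicate padding, so borders of a uniform field produce no
  spurious response (zero padding would ring at all four edges).
* **Threshold.** A pixel is included iff ∇²I ≤ k·SD, with SD taken over
  *all* pixels of the Laplacian image and k < 0. Default k = −2.2, a
  mid-range value that balances dim-terminal recall against noise; values
  between −1.5 and −4 are typical, and the CLI `preview` subcommand emits
  masks at several k for visual choice (replacing an interactive panel).
  k is clamped to [−10, 0). In the degenerate case SD = 0 (constant
  image) the mask is empty. Because both ∇² and SD scale linearly,
  detection is exactly invariant to affine intensity rescaling
  aI + b (a > 0) of the source.
* **Components.** Connected components at 8-connectivity by default
  (diagonal-touching pixels of one terminal belong together), minimum
  size 4 px by default (rejects noise specks and reporter-free debris),
  numbered 1…n in raster order of their first pixel — the ordering is
  arbitrary but must be deterministic for reproducibility. The mask
  encoding (background 1, ROI n = −n) makes a single integer matrix carry
  the whole segmentation and reusable across any stack of the same frame
  size.
* **Source image.** Detection usually runs on the temporal average (best
  signal-to-noise, least bias); the SD image highlights active units and
  the stimulus-triggered response image highlights responsive ones, at
  the cost of biasing detection toward the chosen stimulus.

For high-resolution images whose terminals have flat-topped profiles the
Laplacian responds only at edges. `detect_rois_highres()` first smooths
with a Gaussian (own separable convolution with replicate padding, for
consistency with the Laplacian's boundary rule), block-averages down by an
integer factor, detects, and replicates the label mask back up —
labels are never interpolated, so no new label values can appear.
Morphological closing was deliberately not implemented: it risks merging
closely spaced terminals.

## Background, traces and ΔF/F

The background region is always user-specified (a rectangle, point list or
logical mask chosen to be devoid of reporter); automatic background
detection is out of scope because instrument offsets and non-specific
fluorescence are setup-specific. The per-frame mean over that region is
subtracted from the whole frame and the subtracted scalars are kept for
audit.

The baseline F₀ of each trace is the centre of the modal histogram bin,
with ⌈1 + log₂N⌉ bins spanning the trace's own range. The ceiling is used
because 1 + log₂N is rarely integral and more bins localise the mode more
finely; ties between equally tall bins break toward the lower-valued bin,
biasing toward baseline rather than response plateaus. The estimator is
robust to spontaneous transients while they occupy less than half the
recording; above ~50% duty cycle the mode migrates into the response and
F₀ is overestimated — a documented limitation, asserted as a directional
test. Traces whose F₀ is exactly zero cannot be normalised and are flagged
NaN with a warning rather than failing the batch.

Stages are explicit (`raw → background_corrected → dff`) and enforced:
`dff()` refuses raw traces so a missing background correction cannot pass
silently. ΔF/F is invariant to multiplicative gain of the corrected
signal, which the tests assert.

## Clustering

Pairwise distances support the metrics conventional in expression-profile
analysis. The Pearson distance is 1 − r, so 0 means perfect correlation
and 2 perfect anticorrelation. "Normalised Euclidean" is defined here as
the Euclidean distance between traces individually standardised to zero
mean and unit variance — the source literature for these metrics leaves
the exact formula open, so the definition is isolated in one place and
can be swapped. Constant traces have undefined correlation; they are
flagged NA with a warning and excluded from clustering rather than
poisoning the matrix.

The cutoff is a percentage of the largest pairwise distance (default 25%,
of the typical 25–30% range). Clusters are the connected components of
the graph whose edges join pairs with distance *strictly below* the
cutoff ("less than"; ties at exactly the cutoff do not link), which is
equivalent to cutting a single-linkage dendrogram at that height — an
equivalence the test suite verifies against `hclust` on random instances.
Components of size 1 are reported as unclustered: one trace is not a
grouping. Raising the cutoff can only merge components, never split them
(asserted as a monotonicity property).

## Laminar mapping

Both layer borders are resampled to the same number of points, uniform in
arc length; the default density of 8 points per image-width pixel makes
vertex spacing ≪ 1 px, which is why point-to-contour distances use
vertices only — segment projection would change assignments by far less
than a depth percent. Each coordinate is then LOWESS-smoothed against arc
length (local linear fits; default span 0.1 of the contour — the
algorithm's originator gives no canonical span, and 0.1 suppresses
pixel-scale drawing jitter while following the layer's curvature). If the
two borders were drawn in opposite directions, index-wise interpolation
would cross; the second border is reversed iff that reduces the summed
endpoint-pair distance.

Isocontours are interpolated point-wise, with i = −1 and 101 produced by
the same linear formula (extrapolation), so units slightly outside the
drawn borders are binned into the marginal groups instead of being lost.
Centres of mass weight each ROI pixel by its brightness in the same
source image used for detection; negative weights (possible in response
images) are clipped to zero with a warning, and a zero total mass falls
back to the unweighted centroid. Nearest-isocontour ties break toward
the lower index — deterministic and symmetric: swapping the two border
roles maps every depth d to exactly 100 − d.

ON/OFF classification is by windowed z-scores of ΔF/F in units of the
pre-stimulus SD: ON if the stimulus-window score exceeds +z, OFF if it
falls below −z or the post-stimulus score exceeds +z (rebound). The sign
rule alone would flicker on noisy traces, so the z-gate (default 3,
configurable) makes calls deterministic; it is an addition of this
implementation. The mapping assumes the optical section cuts the layer
orthogonally; the package computes positions regardless and leaves that
judgement to the experimenter — tilted sections bias depths
systematically.

## The synthetic-data generator

All tests run against generated data with planted ground truth, because
no public recordings accompany the method. The generator emulates:

* **Scenes** — isotropic Gaussian blobs (σ 1.5 px by default, the scale
  of diffraction-limited terminals at ~1–2.6 µm/px sampling) with peak
  amplitudes spanning a tenfold range (30–300 intensity units) on a
  linear-gradient background (0–60), with additive Gaussian noise.
  The default scene noise (sd 0.5) is that of a *temporal-average* image:
  detection in practice runs on averages of hundreds of frames, so the
  scene generator models that input directly. Sampled terminals sit on
  pixel centres so that the 1σ ground-truth disc has a consistent
  pixelisation; analytically placed terminals (layered scenes) keep
  sub-pixel positions. 20 blobs on 256×256 keeps the field sparse enough
  that the Laplacian's SD is set by background and noise rather than by
  the blobs themselves.
* **Movies** — per-blob amplitude modulation with phenomenological
  templates (sustained step; transient with exponential decay, τ = 5
  frames; OFF dip with rebound; Poisson-timed spontaneous spikes; silent)
  at per-frame noise sd 4 (≈ SNR 7 per frame on the dimmest terminal).
  Spontaneous spikers share spike times within a group, emulating
  synchronously spiking terminals so that planted clusters are
  recoverable. Indicator kinetics are phenomenological, not biophysical;
  no photobleaching, no optical PSF, single channel only.
* **Layered scenes** — terminals placed at prescribed relative depths
  between two concentric arcs (the roughly hemispheric curvature of the
  retina) or parallel lines, with the border polylines exported exactly.

Passing tests on these fixtures demonstrates correctness of the
algorithms under the stated model — blob-like structures, additive noise,
rigid motion — not performance on pathologies the model excludes
(overlapping sources, strong bleaching, non-rigid motion, anisotropic
PSFs).

Problem sizes used by the test-suite and acceptance checks (256×256
scenes, 64×64×50 movies, 100-seed repetition loops, 120–200-frame demo
pipelines) were chosen as the smallest at which the statistical claims
are stable; everything is regenerated from seeds at run time.

## Degenerate inputs and determinism

Deliberate behaviours worth knowing: empty frame ranges, overlapping
rest/stimulus windows, out-of-range thresholds and malformed masks raise
errors before computation; an all-zero distance matrix yields one cluster
of all members; an empty ROI mask yields an empty trace matrix, not an
error; store appends are atomic per batch and reject duplicate
(experiment, ROI) keys listing the offenders. Every generator and every
pipeline step is deterministic given the configured seed; each pipeline
step writes the fully resolved configuration it actually used beside its
outputs, and reruns with identical configuration produce byte-identical
tabular artifacts.

## Known limitations

* Translation-only registration; tissue deformation is out of scope.
* The Laplacian detector needs peaked cross-sections; the
  blur-and-downsample path coarsens ROI outlines at high resolution.
* F₀ overestimation above ~50% activity duty cycle.
* The clustering cutoff, as a fraction of the *maximum* distance, is
  sensitive to a single outlier pair; inspect the distance matrix when a
  run yields no or one giant cluster.
* Depth mapping presumes an orthogonal optical section and a single
  layer bounded by two contours; 3-D laminar geometry is not modelled.
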