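# roiscope

Semi-automated analysis of dynamic fluorescence imaging of neural circuits
in R: detect structures of interest, extract and normalise their activity
traces, group similar responses, and map each unit's position within a
layered network.

The package targets experiments such as multi-photon calcium imaging of
genetically labelled synaptic terminals (e.g. bipolar-cell terminals in the
retinal inner plexiform layer, IPL), where tens to hundreds of structures
of very different brightness respond to stimuli in a single field of view.

## What it computes

**ROI detection by Laplacian thresholding.** Structures are segmented on
the Laplace operator of a source image,

∇²I = ∂²I/∂x² + ∂²I/∂y²,

rather than on raw intensity: as a second derivative, ∇²I responds to
*relative* brightness, so a terminal ten times dimmer than its neighbour
still produces a comparable local minimum. Pixels with
∇²I ≤ k·SD(∇²I) (k negative, default −2.2; useful range about −1.5 to −4)
are segmented into connected components, small components are rejected, and
the result is stored as a signed label mask (background = 1, ROI *n* = −*n*).
A blur-and-downsample variant handles high-resolution images whose ROI
cross-sections are flat-topped.

**Trace extraction and ΔF/F.** Per-frame means over a user-chosen
background region are subtracted, per-ROI traces are extracted, and each
trace F is normalised as ΔF/F = (F − F₀)/F₀. The baseline F₀ is the centre
of the modal bin of a histogram of the trace with ⌈1 + log₂ N⌉ bins — a
mode-based estimate that tolerates spontaneous activity (it overestimates
F₀ only when the activity duty cycle exceeds ~50%).

**Response clustering.** Traces are compared pairwise under one of five
metrics (Pearson distance 1 − r, Euclidean, normalised Euclidean,
Manhattan, Chebychev); a cutoff is set as a percentage of the largest
distance (default 25%) and clusters are grown by single linkage —
equivalently, connected components of the sub-cutoff graph. Singletons are
reported as unclustered.

**Laminar positions.** Two user-drawn border contours (0% and 100%) are
resampled to uniform arc length (8 points per image-width pixel), LOWESS-
smoothed and oriented; 99 intermediate isocontours are interpolated
point-wise, Cᵢ = (i·C₁₀₀ + (100 − i)·C₀)/100, plus extrapolated −1% and
101% contours for units just outside the layer. Each ROI's
brightness-weighted centre of mass, R = Σ(rᵢ·mᵢ)/Σmᵢ, is assigned the index
of the nearest isocontour as its relative depth, and units are classified
ON/OFF/nonresponsive from windowed z-scores of their ΔF/F traces.

**Infrastructure.** A synthetic-data generator plants blob scenes, movies
with ON/OFF/transient/spontaneous responses, and curved layered geometries
with full ground truth; a flat-file CSV store collects per-terminal records
across experiments with conjunctive queries; a synopsis report (markdown +
PNG) summarises each experiment; and a file-based pipeline driver exposes
everything as composable subcommands (`inst/scripts/roiscope`).

## Worked example

```r
library(roiscope)

# a synthetic recording: 9 terminals, 3 response classes, 200 frames @ 5 Hz
sim <- make_movie(
  scene_spec(width = 128, height = 100, n_blobs = 9, brightness = c(60, 300),
             background = "constant", background_range = c(10, 10), seed = 1),
  response_spec(rep(c("ON_sustained", "OFF", "spontaneous_spiker"), each = 3),
                amplitudes = 0.8, stim_window = 80:120, seed = 1),
  n_frames = 200, frame_interval = 0.2)

avg  <- average_image(sim$stack)
mask <- detect_rois(avg, detection_params(k = -2.2, min_size = 4))
mask
#> <roi_mask> 128 x 100 px, 9 ROI(s), areas 9-10 px

corrected <- subtract_background(sim$stack, c(2, 20, 2, 12))
traces <- dff(extract_traces(corrected, mask))
traces
#> <trace_matrix> 9 ROI(s) x 200 frames, stage: dff, 0.2 s/frame

cl <- cluster_traces(pairwise_distance(traces, "pearson"),
                     cutoff_fraction = 25)
cl
#> <cluster_assignment> 3 cluster(s) at 25% of max distance (cutoff 0.4689)
#>   cluster 1: ROIs 1, 2, 6
#>   cluster 2: ROIs 3, 7, 8
#>   cluster 3: ROIs 4, 5, 9
#>   unclustered: 0
```

All 9 planted terminals are detected from the temporal average despite the
5-fold brightness range, and the three planted response groups are
recovered exactly: the cutoff (25% of the maximum Pearson distance, here
0.469) is far above the within-group distances (~0.05) and far below the
between-group ones (~1). Depth mapping works the same way from two border
contours; see `?isocontour_family` and `?assign_positions`, or run the
whole chain on files:

```sh
Rscript inst/scripts/roiscope all --out-dir demo --seed 1
```

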