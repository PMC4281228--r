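---
title: "colonymap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{colonymap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(colonymap)
```

## The problem

Human pluripotent stem cells grow as colonies, and a cell's phenotype
covaries with its position in that structure: loosely attached cells at the
colony periphery are biased toward G1 and low pluripotency-marker
expression, cells in the outermost colony layer are biased toward G2, and
dense differentiated patches lose marker expression and respond differently
to DNA damage. Quantifying this requires imaging whole colonies at
single-cell resolution, which in practice means a rectangular grid of
overlapping microscope fields, each segmented separately, whose per-field
results must then be reconciled into one seamless map. `colonymap`
implements that reconciliation (the *virtual slide*), the spatial-context
measures built on it, subpopulation gating with bootstrap uncertainty, and
single-molecule RNA FISH (smFISH) spot counting in 3-D stacks with
detection thresholds equalized across fields. A synthetic ground-truth
generator makes every stage testable without microscope data.

## The virtual slide: consensus relabeling instead of stitching

Raw pixels are never stitched for analysis. Each field's segmentation label
matrix is loaded into region coordinates (stage positions are assumed
accurate to well under a pixel), and duplicate objects are resolved at the
label level: two instances are the same physical object when their
region-coordinate footprints share at least one pixel *and* their centroids
are within one maximum cell diameter; of corresponding instances the larger
(by pixel area) is kept. The centroid guard prevents chained merges of
touching neighbours; ties go to the field with the smaller grid index so
the result is deterministic. Objects touching the outermost one-pixel frame
of the region are discarded, since region-boundary cells are clipped.

The heuristic is seamless when every cell fits entirely inside at least one
field. An overlap of at least twice the maximum cell diameter guarantees
this, and the property suite verifies that guarantee on randomized layouts.
The guarantee is sufficient but not tight: along one axis a cell of
diameter $c$ has a valid centre interval of length $W - c$ per field of
width $W$, and consecutive intervals leave no gap whenever the overlap is
at least $c$. The containment sweep in the acceptance suite measures the
empirically smallest safe overlap on random layouts and finds one cell
diameter, confirming that the factor-two condition carries a 2x safety
margin rather than being the critical value. We keep the factor-two
recommendation as the operating condition (it also gives the
duplicate-matching step complete instances to compare) and report the
sweep's measurement as-is.

Coordinates are 0-based pixels, `x` along columns and `y` along rows;
physical micrometres are pixels times `pixel_size`. These conventions are
fixed so that tests can be bit-exact.

## Segmentation and features

Colonies are found on the mosaicked DNA channel: Gaussian blur
(`sigma = 8` px at 1 um/px), a global Otsu threshold on the blurred image,
hole filling, and a minimum-area filter (2000 um^2). Nuclei are segmented
per field: light smoothing (`sigma = 1` px), thresholding against a
large-scale local background (blur at 25 px plus an offset of 12 a.u.,
which separates touching nuclei better than a global Otsu when a diffuse
within-colony stain is present), hole filling, then a watershed on the
Euclidean distance transform (tolerance 0.2 px) to split clumps, and an
area gate of 20-400 um^2 that discards poorly segmented objects. These
defaults were fixed once against the synthetic generator, where they
recover at least 95% of nuclei with at least 95% precision at the
generator's default packing (about 25% footprint density); they are all
exposed in `nuclei_params()` because real stains will need retuning.

Per-cell features are area, perimeter, eccentricity, equivalent diameter,
and per channel the integrated intensity, mean intensity and within-object
intensity SD (a deliberately simple texture score). The perimeter is the
crack-boundary count scaled by $\pi/4$, removing the ~1.27x taxicab bias a
raw boundary-pixel count has on smooth shapes. Eccentricity comes from the
second central moments. Colony records additionally carry the maximum edge
distance — the maximum over the colony mask of the Euclidean distance to
the nearest background pixel — which is the size measure used for the
small (< 150 um), medium (150-300 um) and large (> 300 um) classes; the
boundaries are closed on the medium side, a measure-zero choice.

## Spatial context

The distance from the colony edge is the Euclidean distance transform of
the colony mask evaluated at the cell centroid: 0 outside every colony
(the periphery), up to the colony's maximum edge distance inside.
Peripheral cells keep colony id 0 plus a nearest-colony id for context.
Cell layers divide distance into bands of one cell diameter: layer $k$ is
$((k-1)d, kd]$; the diameter defaults to the per-sample median nuclear
equivalent diameter. Equal-count distance bins use sort-and-split
quantiles, so bin counts differ only by ties; duplicate edges from massive
ties are collapsed with a warning. Density windows tile each colony's
bounding box (not the whole region — windows are a colony-level construct)
with 250 x 192 um tiles, partial edge tiles kept; window counts are
classified low/mixed/high at the tertiles of the observed counts unless
explicit edges are supplied, since no canonical cutoffs exist.

## Gating and bootstrap statistics

Integrated DNA intensity is bimodal on the log scale (2N and 4N). Because
S-phase cells carry intermediate DNA content, the package first places the
S threshold at the antimode of a two-component Gaussian mixture on the log
S-phase-label (EdU) intensity, then fits the 2N/4N mixture on the
EdU-negative population only; fitting on all cells drags the 4N centre
several percent low. The M-phase (pH3) threshold is the analogous antimode.
Gates are $\pm 3$ mode-SDs on the log scale (configurable), and the 4N/2N
centre ratio is checked against 2 with a 20% warning band. Classification
precedence is S (EdU) over M (pH3) over DNA content: active replication
trumps DNA content, and pH3 resolves M within the 4N population. All
thresholds are scale-equivariant, so the classification is invariant under
global intensity rescaling when gates are refit.

Marker positivity uses the same mixture-antimode construction on log
intensity, with Otsu on the log values as fallback for weakly bimodal
channels.

Subpopulation frequencies per bin (distance bins, layers, windows) come
with percentile bootstrap confidence intervals: `B` multinomial resamples
of the bin's composition (equivalent to resampling cells with replacement),
interval endpoints at the empirical quantiles. Percentile, not BCa: the
interval is read directly from the central 95% of the resampled
frequencies. One seed governs all resampling. The acceptance suite
measures empirical coverage — 500 simulated bins of 1500 cells with known
phase probabilities — and requires 95% +/- 2.5%.

## smFISH detection and threshold equalization

Stacks are preprocessed by a per-plane grayscale top-hat (subtracting the
morphological opening with a disc of radius 4 px; the disc must be larger
than a spot, or the opening preserves the spot and the subtraction erases
it — the warning fires when `open_radius <= 2 * log_sigma`) followed by a
3-D Laplacian-of-Gaussian (lateral sigma 1.3 px, axial sigma scaled by the
z-step), signed so spots are positive peaks. Candidates are 26-connectivity
local maxima above a permissive floor; the recommended floor is twice the
filtered noise scale estimated from the negative filtered values, which
adapts to per-field gain. The outer one-voxel shell is excluded — it holds
filter boundary artifacts and spots there cannot be localized anyway.

Each candidate is scored by a statistic that combines point-source
curvature with brightness: the geometric mean magnitude of the rectified
negative principal curvatures of the smoothed background-subtracted stack
at the peak, times the peak's LoG response (its band-passed intensity
above local background). A true point source curves downward along all
three principal axes; ridge- and edge-like artifacts (for example the rim
the top-hat leaves along a colony-mask boundary) have one near-zero
curvature and score near zero under the geometric mean, which is why it is
used instead of the arithmetic mean. The statistic is increasing in every
curvature magnitude and in the peak intensity, and scales as $c^2$ when the
stack is scaled by $c$ — both properties are tested.

Detection thresholds are equalized across the field grid by minimizing

$$E(S) = \sum_{x,y} \left[f^r_{x,y}(s_{x,y}) - f^l_{x+1,y}(s_{x+1,y})\right]^p
       + \left[f^b_{x,y}(s_{x,y}) - f^t_{x,y+1}(s_{x,y+1})\right]^p$$

over the threshold matrix $S$, where the $f$ are spot counts above
threshold in the physically shared margins (margin width equals the grid
overlap — only shared content is compared) and $p$ is 2, or 1 for more
outlier robustness. Each pair of adjacent fields enters once
(right-to-left and bottom-to-top); counting both directions would double
$E$ without moving the minimizer. Every $f$ is a step function of its
threshold, so only candidate statistic values matter: cyclic coordinate
descent over each field's sorted unique margin statistics finds an exact
per-coordinate minimum, taking the smallest threshold among minimizers,
and stops when a sweep yields no improvement. The result never exceeds the
initial objective. Two caveats are deliberate: the objective has degenerate
global minima (all thresholds at infinity give $E = 0$), so the absolute
detection level is anchored entirely in the initial constant estimate
$S_0$ — by default Otsu's threshold on the pooled log statistics of all
fields — and the descent only adapts relative levels around it; and at
four-field corners the pairwise terms apply transitively, which is one of
several defensible choices.

Cell territories expand the nucleus outlines until they touch: each colony
pixel joins the nucleus with the nearest boundary (per-label distance
transforms), boundaries forming along equidistant loci or the colony edge,
ties to the lower label. The colony mask is Otsu on the maximum projection
of the diffuse RNA background staining. Spots in shared margins are merged
in 3-D (duplicates of one physical spot agree in x, y and z), keeping the
higher-statistic instance.

## The synthetic generator: what it does and does not emulate

`generate_colony_scene()` draws non-convex colony outlines (radius
modulated by low-order Fourier modes — smooth irregular blobs chosen over
thresholded filtered noise so colony count and placement are controllable),
places elliptical nuclei inside them with a minimum centroid separation,
adds a small loosely attached peripheral population, and assigns phases
conditional on spatial zone. The defaults are the study conditions: 12 um
nuclei (max 15 um), phase mix G1/S/G2/M = 0.45/0.30/0.20/0.05 in the bulk,
G1-enriched periphery (0.70), G2-enriched first layer (0.32), and
marker-negative fractions of 10% in G1, 1% otherwise and 63% at the
periphery. DNA content doubles from G1 to G2/M with S in between;
S- and M-markers are bimodal log-normals. Rendering paints nuclei as
anisotropic Gaussians clipped at two sigma (footprint diameter equals the
stated cell diameter), scales the DNA channel so the pixel sum over a
nucleus approximates its true integrated intensity, adds a diffuse
within-colony glow, and degrades field crops with per-field gain and
background, Poisson shot noise and Gaussian read noise — noise is applied
after gain, as on a CCD.

`generate_smfish_stack()` scatters log-normal-amplitude 3-D Gaussian point
sources around nuclei inside a colony. Three realism constraints matter
for interpretation: spots are placed inside their own cell's territory
(cytoplasm does not overlap), at a minimum PSF-normalized separation of 4
sigma (single-molecule counting presumes diffraction-separated molecules;
closer pairs fuse into one focus and are not generated), and in the
central z-planes (an acquisition covers the cell volume with a focus
margin; spots in the outermost planes have truncated PSFs). The
`min_snr` parameter pins the 1st percentile of the amplitude distribution
at a stated multiple of the background noise SD, so "every spot at SNR 4"
is a generator condition, not an average.

What the generator does *not* emulate: optical aberrations and a realistic
PSF (spots are ideal Gaussians), uneven illumination within a field,
chromatic shifts between channels, segmentation-relevant texture inside
nuclei, mitotic morphology, overlapping nuclei in z, autofluorescent
debris, and stage positioning error (the virtual slide assumes exact
stage coordinates). Passing tests therefore demonstrate the correctness
and internal consistency of the algorithms under controlled conditions,
not segmentation robustness on real stains.

## Problem sizes and numerical notes

The test suite runs desk-scale versions of each analysis: scenes of 2-10
colonies with 70-300 cells each, field grids up to 3 x 3 at 160 px fields,
smFISH regions of 2 x 3 100-px fields with about 400 true spots, 500
bootstrap coverage replicates at 1500 cells and 1000 resamples, and 20-seed
sweeps for the consensus properties. Grayscale morphology in EBImage
operates on [0, 1], so the top-hat rescales around the opening; Gaussian
blur kernels are capped at the image size. Degenerate inputs are defined:
blank images segment to zero objects without error, constant channels are
rejected by the gating fits with the channel named, an empty bootstrap bin
is an error, and equal-count binning collapses duplicate edges with a
warning. All RNG passes through explicit seed arguments; reruns of the
pipeline with one configuration are byte-identical.

## Known limitations

At the detection limit (all spots at SNR 4) the spot statistic's true- and
false-candidate distributions overlap, so no threshold reaches perfect
recall and precision, and per-cell count errors of a few percent of the
mean are irreducible; the acceptance suite runs exactly at that limit and
reports what it measures. The consensus step assumes stage accuracy —
there is no sub-pixel registration — and the density-window cutoffs are
sample-relative (tertiles) unless calibrated externally. Bootstrap
intervals are percentile intervals; for very small bins they undercover
slightly, which the coverage test makes visible.
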