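---
title: "Simulating and scoring filament instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring filament instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filamentsim)
```

## The problem

Microtubules imaged by interference reflection microscopy (IRM) appear as
thin, curved, dark lines on a gray background.  Benchmarking instance
segmentation on such data is hard for two reasons: real annotations are
scarce and expensive, and classical pixel-overlap metrics punish a
one-pixel lateral shift of a three-pixel-wide filament as severely as a
genuine tracing error.  `filamentsim` addresses both ends of the problem:
it simulates IRM-like images with exact per-instance ground truth, and it
scores arbitrary segmenter output with skeleton-based metrics that
emphasize centerline geometry over raw area overlap.

## The generative model

Image generation is a two-step stochastic process conditioned on a single
flat parameter vector $\theta$ (`default_theta()`).

**Geometry.**  Each filament is a correlated random walk in the plane.
The total arc length $L$ and the individual segment lengths $\ell_k$ are
drawn from positive-truncated Gaussians; segments are accumulated until
they reach $L$ and the last one is truncated so the arc length is exact.
The heading evolves as
$$\varphi_k = \varphi_{k-1} + B_k\,\eta_k, \qquad
  \eta_k \sim \mathrm{Gamma}(\alpha,\beta),$$
where $B_k \in \{-1,+1\}$ decides whether the filament bends left or
right.  The sign process starts uniformly, flips with probability
$p_\text{flip}$ at each step, and is frozen once `max_flips` sign changes
have occurred, so $\sum_k |B_k - B_{k-1}| \le 2\,n_\text{flips}$ always
holds.  The product $\alpha\beta$ sets the mean bend per segment and
thereby the persistence of the walk.  Filaments may leave the canvas;
clipping is deferred to rasterization, as in real fields of view.

**Rendering.**  The vertex chain is rasterized by exact supercover (a
pixel is set iff the continuous polyline intersects its closed unit
square), the union skeleton mask is convolved with an isotropic Gaussian
PSF truncated at $4\sigma$, and the ideal image is
$$I_\text{ideal} = A\,(M * \mathrm{psf}) + B$$
with signed contrast $A$ (negative for IRM's dark filaments — polarity is
deliberately tunable, not hard-coded) and background $B$.  The first
`seed_len` pixels of arc length of each filament are rendered into the
red channel as the stabilized nucleation seed.  Convolution is
zero-padded; borders therefore darken slightly unless vignetting and the
tuner compensate, which we accept as the simpler contract.

**Degradation.**  A stochastic operator applies, in a fixed documented
order: low-frequency multiplicative background field, distractor spots,
global blur, vignetting, multiplicative speckle, Poisson shot noise,
additive Gaussian noise, per-channel gain jitter, and a final clip to
$[0,1]$.  The order is a design choice (the ingredients, not the order,
are dictated by the physics): signal-dependent noise must see the
already-structured image, and a fixed order is what makes samples
reproducible from a seed.  Every stage at zero amplitude is skipped
outright, so the all-zero configuration is a bit-exact identity —
a property the test suite checks literally.  `photon_scale = 0` is the
sentinel for "Poisson off".  Distractor spots are blurred disks only;
they are never written into the ground truth.

**Ground truth.**  Each instance mask is the filament's rasterized
skeleton dilated by a 1-pixel Euclidean disk.  A skeleton-only ground
truth would make the SKIoU numerator degenerate under 1-pixel shifts;
the 1-px radius gives the mask roughly the apparent width the default
PSF produces.  Filaments whose in-canvas skeleton covers fewer than
2 pixels are dropped from both image and stack — sub-pixel fragments are
unlabelable.  Overlapping instances are preserved by storing one mask
per filament (multi-page TIFF on disk).

## Fitting $\theta$ to real data

`tune()` draws candidate vectors from an explicit `search_space` (bounds
and linear/log scale per tunable field — noise amplitudes span orders of
magnitude, hence the log option), generates one image per candidate,
embeds it and each of the reference frames, and scores the candidate by
the *maximum* cosine similarity across the references: the candidate
must be plausible for at least one representative frame, not for their
average.  The top $k = 10$ candidates of 1000 trials are retained by
default.  The shipped sampler is seeded random search behind a sampler
interface; an adaptive (TPE-style) sampler can be plugged in, but the
package's correctness never depends on the sampler.  The built-in
embedding is a deterministic handcrafted feature vector (intensity
histogram, gradient-magnitude statistics, radially averaged power
spectrum), so the package tests and runs without any model weights; a
deep backend (e.g. an intermediate vision-transformer layer) satisfies
the same `embedding_backend` contract.  One generated image per trial is
compared (configurable); the variance this adds is absorbed by the trial
budget.

`adapt_segmenter()` reuses the same machinery for few-shot adaptation of
an arbitrary segmenter: each trial draws hyperparameters, segments a
small tuning set (10 images in the standard protocol), and maximizes the
mean SKIoU against ground truth.  Crashing trials score 0 and the run
continues.

## Scoring

**SKIoU.**  For masks $M_\text{pred}, M_\text{gt}$ with skeleton
operator $S$,
$$\mathrm{SKIoU} = \frac{2\,|S(M_\text{pred}\cap M_\text{gt})|}
  {|S(M_\text{pred})| + |S(M_\text{gt})|},$$
with the intersection taken *before* skeletonization, so a small lateral
shift of a thick filament still yields a long intersection skeleton.
Thinning is the two-subiteration parallel algorithm of Guo & Hall
(1989), which preserves 8-connectivity and erodes line ends by at most
about one pixel.  Both masks empty is defined as 0 and such pairs are
excluded from means.

**Protocols.**  The per-image mean SKIoU takes, for every ground-truth
instance, its best-matching prediction (non-exclusively) and averages;
missed instances score 0; false positives are not penalized — exactly
the headline-metric convention.  AP and F1 use greedy one-to-one
matching by descending SKIoU (deterministic tie-break by instance index)
at thresholds $0.50, 0.55, \ldots, 0.95$; because predictions carry no
confidence scores, AP at a threshold is $TP/(TP+FP+FN)$, the
cell-segmentation-community convention, and AP is the mean over the ten
thresholds.  F1 is reported at 0.50 and 0.75.  Dataset scores are
macro-averages over images.

**Biological statistics.**  Instance length is the skeleton pixel count
(the field's proxy for mask outputs; anchor-chain outputs use summed
Euclidean distances).  Curvature of an instance is measured by ordering
the skeleton pixels by greedy nearest neighbor, fitting a parametric
curve $(x(u), y(u))$, and averaging
$$\kappa(u) = \frac{|x'y'' - y'x''|}{(x'^2+y'^2)^{3/2}}$$
over one sample per skeleton pixel.  Distribution agreement between
predicted and ground-truth lengths/curvatures is the KL divergence
$\sum_i P_i \log(P_i/Q_i)$ (natural log — the convention in the KL
literature) over shared linear bins spanning the pooled range; 50 bins
and additive smoothing $\varepsilon = 10^{-10}$ per bin are config
values, since empty bins would otherwise make the divergence infinite.
Micrometer-denominated outputs require an explicit `pixel_size_um`;
there is no default because the factor is setup-specific.

## Numerical choices in the curvature chain

An interpolating spline through raster-quantized skeleton pixels is the
wrong tool for curvature: rounding adds coordinate noise of variance
$1/12\,\mathrm{px}^2$, and the second derivative of an interpolant
through that noise is dominated by it (on a digital circle of radius 50
the mean unsigned curvature comes out around $1.4\,\mathrm{px}^{-1}$
instead of $0.02$).  `fit_curve()` therefore offers two methods:

* `"interpolating"` — the exact zero-smoothing fit, used for anchor-chain
  conversion and wherever the input coordinates are continuous;
* `"smoothing"` — a penalized regression spline per coordinate, used by
  `instance_curvature()` for raster paths.  The penalty is selected by
  generalized cross-validation, with one guard: when the GCV residual
  falls clearly below the quantization floor (which happens for
  near-axis-aligned staircases, where GCV happily interpolates the unit
  jumps), the penalty is re-selected by the discrepancy principle so the
  residual RMS matches the known quantization noise.

Two further details matter.  The smoothing spline's natural boundary
conditions force curvature to zero at the open ends of a path, biasing
the mean downward by roughly $c/R$ on a circle; the evaluation grid is
therefore trimmed 6 px of arc length from each end (capped at 20% per
end).  With both measures the chain recovers $1/R$ on digital circles of
radius 15–120 px to about 1% and reports below $10^{-3}\,\mathrm{px}^{-1}$
on straight filaments at arbitrary orientation — both properties are
enforced by the test suite.  Branched skeletons (merged predictions) are
ordered greedily like everything else; the resulting curvature can be
inflated, which is documented behavior rather than an error.  Skeleton
pixel *count* remains the length proxy for metrics (matching the
benchmark convention) even though it undercounts diagonal filaments by
up to $\sqrt{2}$; when a geometric length is needed (e.g. the simulator
consistency checks), the arc length of the fitted smoothing curve is the
right measure and recovers the specified filament length to about 1%.

## Default parameters

The default filament count law (11.28 ± 5.1 per image) matches the
ground-truth statistics of the benchmark this simulator emulates; canvas
size is fixed at 512×512.  The default total-length law (148 ± 74 px)
reproduces the benchmark's 2:1 length mean-to-SD ratio at a plausible
IRM pixel scale (~0.09 µm/px); the remaining defaults (PSF width 1.2 px,
background 0.55, contrast −0.35, the noise amplitudes) were chosen once
to give visually plausible dark filaments at realistic SNR and are
expected to be *tuned*, not trusted: the published benchmark never
prints its 660 optimized vectors nor its search bounds, so the shipped
`default_search_space()` is an explicit, editable engineering default.

## What the generator does and does not emulate

Emulated: dark curved filaments of controllable count, length and
persistence; red nucleation seeds; PSF-limited apparent width;
spatially correlated background; vignetting; shot, speckle and read
noise; circular distractors.  Not emulated: interference fringes and 3-D
PSF structure, filament–filament interactions, dynamic instability
(single-frame setting only), elongated or irregular distractors, and
camera fixed-pattern noise.  Tests passing on synthetic data therefore
demonstrate correctness of the pipeline and metrics, not segmenter
performance on real IRM data; for the latter the domain tuner plus a
small annotated real set remain necessary.

## Problem sizes used by the test suite

The suite verifies the ground-truth self-evaluation contract on 20
generated 512×512 images, the 66×10×10 dataset combinatorics on reduced
32×32 canvases, tuner recovery of a known background level with 200
random-search trials at 64×64, and few-shot adaptation of a toy
threshold segmenter on ten 192×192 noise-free images.  The toy
adaptation setting uses 3 filaments of ~50 px per image so that
connected-components segmentation is actually separable — crossing
filaments merge into one component and cap the achievable mean SKIoU,
which is a property of the toy segmenter, not of the harness.

## Known limitations

Rasterization marks every pixel whose closed unit square the curve
touches, so tangent segments can produce 2-px-wide runs before thinning.
The greedy nearest-neighbor ordering is quadratic in skeleton size and
can jump across gaps in fragmented skeletons.  Random search needs more
trials than an adaptive sampler for high-dimensional spaces; for the
full 22-parameter space, budget accordingly or plug in an adaptive
sampler.  The AP definition (no confidence ranking) means methods that
emit calibrated scores get no credit for them.
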