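---
title: "Methods: graph-cut contraction scoring and the mixed-effects screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-cut contraction scoring and the mixed-effects screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseroi)
```

## Overview

`pulseroi` quantifies the contraction behaviour of a pulsating region of
interest recorded on video — the motivating application is the boar scrotum
during semen collection, where the projected size of the scrotum in the
frame shrinks visibly at each contraction. The pipeline has four stages:

1. **Segmentation.** Each frame of interest is segmented into
   region/background by a scribble-seeded binary graph cut.
2. **Refinement.** The raw mask is cleaned by the fixed composition
   *fill holes → clear borders → erode*.
3. **Scoring.** The per-frame pixel fraction (mask pixels / frame pixels ×
   100) serves as a proxy of the organ size. Alternating size maxima
   (relaxation) and minima (contraction) define contraction events; each
   event's intensity is the percentage change in size, and events per
   minute give the contraction frequency.
4. **Screening.** Per-ejaculate contraction intensity is related to
   semen-quality variables with a linear mixed-effects model grouped by
   animal.

All pixel coordinates in this package are 1-based `(row, col)`, matching R
indexing; scribble JSON files record an `index_base` field so 0-based files
from other tools are converted on read.

## The segmentation energy

For a labeling $L$ of the pixels into foreground/background the package
minimizes

$$E(L) \;=\; \sum_p D_p(L_p) \;+\;
  \lambda \sum_{(p,q)\ \mathrm{adjacent}} w_{pq}\,[L_p \neq L_q],$$

where the data term $D_p(c) = -\log \hat{f}_c(I_p)$ is the negative
log-likelihood of pixel intensity $I_p$ under a histogram estimate
$\hat f_c$ built from the scribbled pixels of class $c$ (with a Laplace
pseudocount so empty bins stay finite), and the contrast weight is
$w_{pq} = \exp\!\big(-(I_p - I_q)^2 / 2\sigma^2\big)$. Scribbled pixels are
hard-constrained by terminal links whose weight exceeds the sum of all
finite edge weights, so no minimum cut can override a seed. The energy is
submodular, so the global minimum is found exactly as a minimum s–t cut.
The cut itself is computed by a compact Dinic max-flow solver implemented
in C++ (`src/maxflow.cpp`); general-purpose graph libraries solve the same
problem but were measured at two orders of magnitude slower on
frame-sized grids, which matters when every frame of a video is segmented.
A unit test cross-checks the cut value against `igraph::max_flow` on random
instances, and the acceptance suite verifies exact energy optimality
against brute-force enumeration of all labelings on small frames.

Histogram likelihoods were chosen over Gaussian mixtures because they are
deterministic, cheap, exactly reproducible in an independent oracle, and
entirely adequate for single-channel images with a bright region on a
darker background. Interactive tools built on superpixel aggregation can
segment faster but change the energy being minimized; the pixel-level
energy above is the contract here.

**Parameters.** `lambda_smooth` (default 2, dimensionless) trades data
fidelity for boundary smoothness; `sigma_edge` (intensity units) defaults
to the standard deviation of neighbouring-pixel intensity differences of
the frame being segmented, the usual self-calibration for
contrast-sensitive cuts; `hist_bins = 32` and `hist_pseudocount = 1`
define the data term; `connectivity` is 4 by default (matching the
brute-force oracle's energy definition; 8 is available). Ties between
equal-energy labelings are broken towards background by an infinitesimal
($10^{-9}$) bias on the foreground data term of unseeded pixels, making the
output deterministic.

## Mask refinement

`refine_mask()` applies, in a fixed order: `fill_holes()` (background
components not connected to the frame border become foreground),
`clear_borders()` (foreground components touching any frame edge are
removed), and `erode_mask()` (erosion by a Euclidean disk,
$dx^2 + dy^2 \le r^2$, default radius 1 px). Fill and clear are idempotent
and erosion is anti-extensive; these algebraic properties are asserted in
the tests. Connected components and erosion are delegated to *EBImage*;
the disk kernel is constructed explicitly because EBImage's small "disc"
brushes degenerate to boxes. EBImage replicates image values at the
border during erosion, so objects flush with the frame edge are not eroded
from that side; in this pipeline `clear_borders` runs first, so eroded
masks never touch the border. The erosion radius used by the original
interactive workflow is not documented anywhere we know of; radius 1 is
this package's default and is exposed as a parameter.

## From masks to contraction statistics

The size series is the per-frame pixel fraction in percent. Extremum
detection smooths the series with a centered moving average
(`smooth_window`, default 5 frames, odd) and finds local maxima/minima with
a topographic prominence of at least `min_prominence` (default 10% of the
series range). A side of a peak with no strictly higher rival imposes no
prominence constraint, so extrema tied with the global extremum measure
their height above the global minimum — without this, the last contraction
of a recording that ends mid-cycle would be silently dropped. Alternation
is enforced (the more extreme of consecutive same-type extrema wins), each
maximum is paired with the following minimum, and indices are snapped to
the most extreme raw value within half a window of the smoothed location.
Manual relaxation/contraction tags can be supplied instead
(`events_from_pairs()` accepts a list of frame pairs), mirroring workflows
where an operator tags frames by eye.

Intensity supports two readings of "percentage change in size":
`relative` (default), $100\,(S_\mathrm{relax} - S_\mathrm{contract}) /
S_\mathrm{relax}$, and `absolute`, the difference in percentage points of
frame area. Events whose contraction size exceeds their relaxation size
are rejected rather than swapped, surfacing annotation errors. The
per-ejaculate summary aggregates event intensities by `mean` (default;
`median` and `max` are available — published workflows do not always state
which aggregate they use, so it is configurable) and reports events per
minute of total ejaculation time.

## The synthetic phantom

`generate_pulsating_video()` renders a bright ellipse on a darker textured
background. Both semi-axes are scaled by
$s(t) = 1 + A\sin(2\pi\,\mathrm{cycles}\,t/n)$, so the projected area
scales as $s(t)^2$ and the relative size change between full relaxation
and full contraction has the closed form

$$100\,\frac{(1+A)^2 - (1-A)^2}{(1+A)^2} \;=\; \frac{400A}{(1+A)^2},$$

which is what `analytic_intensity()` returns and what the end-to-end tests
recover. Scaling both axes identically is what makes this closed form
exact. The texture is a smooth low-frequency field (coarse uniform noise,
bilinearly upsampled, amplitude 0.08) added to both regions so that global
thresholding fails and the graph cut is genuinely exercised; per-pixel
Gaussian noise is added on top and the result is clipped to $[0,1]$ for
stable 8-bit round trips.

Defaults: 160×160 px frames, 48 frames, 3 contraction cycles, semi-axes
55 px, amplitude $A = 0.10$, foreground 0.75 vs background 0.35,
noise SD 0.03, texture scale 16 px. The region fills a large part of the
frame, as the organ does in a zoomed recording; geometrically, the
55 px axes keep the one-pixel erosion of `refine_mask()` small relative to
the region (an erosion by 1 px changes the area of a disk of radius $r$ by
roughly $2/r$), so mask accuracy is dominated by the segmentation itself.
The number of contraction cycles per recording is a free parameter — real
recordings do not come with a fixed count.

What the phantom does **not** emulate: camera motion, perspective change,
specular highlights, occlusion by the animal, colour, and operator
variability in scribble placement (scribbles are sampled at a safe margin
inside/outside the true boundary). Passing the phantom tests therefore
demonstrates correctness of the algorithmic chain under known geometry,
not robustness to field-recording artefacts.

## The mixed-effects screen

Each (intensity, response) pair is fitted as

$$y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,x_{ij} +
  \varepsilon_{ij},$$

with animal $i$, ejaculate $j$, independent random intercept $b_{0i}$ and
random slope $b_{1i}$ (diagonal random-effect covariance), fitted by
maximum likelihood via *lme4*. The fixed slope $\beta_1$ is reported with
a Wald 95% CI and two-sided p-value. When the random-slope variance is
estimated at the zero boundary — common with two ejaculates per animal —
the model is refitted with a random intercept only and the row is marked
(`random_slope_dropped`).

Three R² flavours are reported. The headline `r_squared` is the ordinary
R² of the conditional fitted values (fixed + predicted random effects)
against the observations; this is the flavour that can be large even when
the fixed slope is non-significant, because between-animal variation is
absorbed by the random effects. `r2_marginal` and `r2_conditional` are
variance-decomposition pseudo-R² values (fixed; fixed + random) for
transparency.

The default screen applies **no** multiple-testing adjustment — a screen
of ~26 variables at raw $p < 0.05$ mirrors common practice in small
feasibility studies — and `format_screen(..., fdr = TRUE)` provides
Benjamini–Hochberg adjusted flagging. Responses with zero variance are
omitted from the screen with a notice (a variable observed at 0–1% in
every sample carries no information for a linear fit). Constant
predictors are errors, per-pair fit failures become marked non-converged
rows rather than aborting the screen.

**Calibration, measured.** With 40 animals × 2 ejaculates the Wald
machinery is honest at conventional levels: across seeded replicates the
95% CI covers the true slope ~93–95% of the time and the null
false-positive rate at $\alpha = 0.05$ is ~6–8% (tests and the acceptance
script recompute both). In the far tail, however — the region BH flagging
probes, $p \lesssim 0.004$ — null p-values of the random-slope model with
two observations per group occur at roughly twice their nominal rate, an
inflation that persists under REML and Satterthwaite approximations. The
consequence is documented honestly by the test suite: in a 26-variable
screen with exactly one injected association, BH flagging isolates that
single row in ~84% of replicates, not the ~91% that perfectly calibrated
p-values would give. With the study-scale design of 5 animals × 2
ejaculates ($n = 10$), small-sample liberality is substantially stronger;
results at that scale should be read as descriptive screening, not
confirmatory inference.

## Numerical choices and reproducibility

* All generator randomness flows from a single integer seed per spec
  object (`withr::with_seed`), so every generator is bit-reproducible.
* The pipeline writes every intermediate (masks, series, events, record,
  report) plus a manifest with the configuration, seed and MD5 hashes of
  all inputs and outputs; reruns with the same configuration are
  byte-identical.
* Problem sizes used by the validation suite: brute-force optimality on
  4×5 frames with 16 unseeded pixels (all $2^{16}$ labelings enumerated);
  phantom recovery on the 160×160 × 48-frame default; 200 replicates for
  CI coverage, 500 for the null error rate, 100 for screen specificity.
  These sizes give Monte-Carlo standard errors comfortably below the
  decision margins while keeping the whole suite to a few minutes.
* Degenerate inputs are rejected with named errors: phantom regions that
  would touch the frame border, empty scribble classes, swapped
  relaxation/contraction tags, constant predictors, single-group tables,
  non-increasing frame numbering, comma decimal separators.

## Known limitations

* The graph-cut energy is pixel-level and single-channel; colour inputs
  are reduced to luminance on load.
* The pixel fraction is a 2-D projection proxy of a 3-D size; no volume
  reconstruction is attempted.
* The screen fits each response separately; no multivariate modelling.
* Frame timestamps come from a user-supplied fps; variable-frame-rate
  video should be resampled upstream.
* At $n = 10$ grouped observations, mixed-model p-values are liberal in
  the tails (quantified above); the package reports them as mainstream
  fitters do and leaves small-sample correction to the analyst.
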