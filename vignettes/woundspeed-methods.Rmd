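---
title: "Concerted cell velocity: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concerted cell velocity: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A wound-healing assay watches a confluent monolayer close a cell-free gap.
If the cell front advances everywhere at the same normal speed $v$, the open
area $A$ and perimeter $P$ obey $\mathrm{d}A/\mathrm{d}t = -v\,P(t)$
(the area swept per unit time is the front length times its speed). The
concerted cell velocity

$$v(t) \;=\; -\,\frac{\mathrm{d}\hat w_\alpha(t)/\mathrm{d}t}{\hat w_\varphi(t)}$$

therefore recovers the front speed for *any* wound geometry, while the raw
area change scales with the (uncontrolled, time-varying) perimeter. This is
the package's central quantity; everything else supplies $\hat w_\alpha$
(area), $\hat w_\varphi$ (perimeter) and their uncertainties.

Assumptions worth keeping in mind: cells are brighter than the wound (for
phase-contrast images this is manufactured by the Scharr gradient transform,
since textured cells have high local gradients and the open wound is
optically flat); one wound per field of view; the front advances roughly
uniformly (strong local heterogeneity shows up as a time-varying $v(t)$, and
the profile's spread is diagnostic).

## Detection

Each frame is smoothed with a Gaussian kernel (`sigma`, truncated at
4 `sigma` — detection is insensitive to the truncation radius, which the test
suite checks at 4 vs 6), then binarized at the absolute threshold
$\beta I_c$ with

$$I_c = \frac{\sum_i p_i^2}{\sum_i p_i},$$

the intensity-weighted mean intensity. Because bright pixels dominate both
sums, $I_c$ tracks the confluent cell level rather than the global mean, so a
large dark wound barely moves the threshold — that is what makes a *relative*
factor $\beta$ transferable across frames and illumination levels. $I_c$ is
computed on the smoothed frame by default (`ic_on`), so the threshold and the
pixels it is compared against share one intensity scale.

The wound is the largest 4-connected (Von Neumann) below-threshold component;
ties in pixel count are broken by label order (first-scanned wins), which is
deterministic. Strict inequality $p_i < \beta I_c$ assigns threshold-exact
pixels to the cells. From the third frame on, candidate components must have
their **centroid** within `radius` of the reference point (the midpoint of
the first two frames' wound centers of mass); gating by centroid rather than
by any-pixel membership is the cheaper and stricter reading, and it is what
rejects dark debris at image corners. Interior holes — drifting cells inside
the wound — are filled so the region is simply connected and the perimeter
describes only the advancing front.

Detection runs at `n_thresholds = 5` values evenly spaced in
$\beta \pm \Delta\beta$ (odd count so $\beta$ itself is one of them). The
across-replicate mean and unbiased variance of area and perimeter are the
measurement and its detection variance: soft, noisy wound boundaries move
substantially as the threshold shifts, hard clean edges do not. A degenerate
`n_thresholds = 1` or `delta_beta = 0` yields zero variance by construction.

### The threshold-offset bias, and why it cancels

On an ideal step edge, thresholding the smoothed image at a fraction $f$ of
the step height places the contour at a normal offset
$\approx \sigma\,\Phi^{-1}(f)$ from the true boundary — with $\beta = 0.3$
and a dark wound, roughly half a smoothing length *into* the wound. Absolute
areas are therefore biased (at the screening default $\sigma = 18$ px this is
tens of percent for a 100 px wound; at fixture-matched $\sigma \le 3$ px a
few percent, the regime in which the suite's 3%-accuracy check runs). The
offset is constant in time, so the detected wound is the true wound eroded by
a constant depth — still a member of the same constant-speed erosion family —
and the velocity $-\dot A/P$ is unaffected to first order. The suite verifies
this directly: recovered velocity agrees between $\sigma = 2$ and
$\sigma = 6$ on the same sequence. The practical guidance is simply: choose
`sigma` to match the noise correlation length of your images (18 px suited
1.3 µm/px screening optics; white-noise synthetic fixtures need only 2–3 px),
and trust velocities, not absolute areas.

### Closure

A wound is considered closed from the first time point whose area drops
below `closure_fraction` (default 0.005, i.e. 5‰) of the image area; that
point and all later ones are excluded from model training. A sequence closed
at its first frame is rejected.

## Perimeter tracing

`marching_squares` (default): the region mask is zero-padded by one pixel
(guaranteeing a closed contour even when the wound touches the image border)
and the 0.5 iso-line extracted with linear interpolation. Contouring a raw
binary field overestimates smooth boundaries by several percent (staircase
steps with diagonal cuts), so the padded mask is first lightly smoothed
(`contour_sigma = 3` px) — the iso-line then bends at sub-pixel resolution
and disk circumferences are recovered to a fraction of a percent, with error
decreasing as the radius grows (curvature bias $\sim \sigma_c^2/2r$). Regions
too small to survive the pre-smoothing fall back to the raw binary contour
(a single pixel yields its $2\sqrt2$ diamond). Saddle configurations are
resolved by the interpolated field itself and are consistent with
4-connectivity of the below-threshold region after this smoothing.

`chain_code`: Moore boundary tracing with 8-direction whole-pixel moves,
length = axial moves + $\sqrt2\,\times$ diagonal moves. Faster and slightly
biased upward on convex shapes (it never undercuts corners), which the suite
asserts as `chain >= marching squares` on disks.

The wound perimeter subtracts contour segments running along the image
border, so a wound cut off by the field of view is measured by its
cell-facing front only. A segment is discounted when both endpoints lie
within `tol = 1.5` px of a border line; the band absorbs the sub-pixel
tracer's slight corner rounding where a border run turns into the interior
(a mask covering the whole frame correctly yields perimeter 0, with a
warning). The literal per-pixel reading of the border term is available as
`border_correction = "pixel_count"`; the geometric rule is the default
because it keeps both tracers and the subtraction in the same unit (px of
Euclidean length).

## Gaussian-process regression

Area and perimeter series are modeled independently as zero-mean GPs with

$$k(t, t') \;=\; C + (\sigma_k^2 + t\,t')^2,$$

a constant plus a homogeneous quadratic kernel. Its feature space is
$\{1, t, t^2\}$, so posteriors are Bayesian quadratic curves — exactly the
family traced by a constant-speed disk (area quadratic, perimeter linear in
time), yet with data-driven uncertainty and per-point noise weighting.
Consequences users should expect: series with genuine cubic or oscillatory
structure are smoothed toward the best quadratic, and the model will report
correspondingly inflated uncertainty rather than follow the wiggles.

Numerics: targets are centered and scaled to unit standard deviation (making
the zero prior mean consistent), times mapped to $[0,1]$, detection variances
divided by the squared target scale. The log marginal likelihood
$-\tfrac12 y^\top K^{-1} y - \tfrac12\log|K| - \tfrac n2\log 2\pi$ is
maximized over $(\log C, \log\sigma_k^2)$ by Nelder–Mead from 10 starts on a
fixed grid design spanning $[-6, 2] \times [-3, 2]$ in log space — fully
deterministic, so fits need no seed and byte-identical outputs follow from
identical inputs. The kernel matrix is rank-3 plus noise; a jitter starting
at $10^{-8}\,\mathrm{tr}(K)/n$ and escalating tenfold to $10^{-4}$ keeps the
Cholesky factorization positive definite (noise-free interpolation problems
need it). An optional learned homoscedastic noise term (`learn_noise`) exists
for data whose detection variances understate the scatter; it is off by
default because the threshold-replicate variances are normally the intended
noise model. Posterior predictions de-normalize back to original units and
flag extrapolation beyond the training range; held-out interior points are
imputed with calibrated uncertainty (the suite checks ~95% coverage at 2
predictive standard deviations over 50 seeded trials).

## Velocity and statistics

The prediction grid defaults to 101 uniform points over the retained time
range — denser than any hourly acquisition, so grid resolution never limits
the derivative. $\mathrm{d}\hat w_\alpha/\mathrm{d}t$ uses second-order
central differences (velocity is undefined at the two grid endpoints);
halving the grid step changes $v(t)$ by well under 1% on smooth fits.
Standard errors use first-order propagation with the area-derivative and
perimeter treated as independent:
$\sigma_{\dot A} = \sqrt{\sigma_A(t{+}h)^2 + \sigma_A(t{-}h)^2}/2h$, then
$\sigma_v^2 = (\sigma_{\dot A}/P)^2 + (\dot A\,\sigma_P/P^2)^2$. The
neglected GP cross-covariance between $t-h$ and $t+h$ is positive for a
smooth posterior, so ignoring it overstates $\sigma_{\dot A}$ —
a conservative choice, recorded here deliberately.

The per-sequence summary is the $\sigma_v^{-2}$-weighted mean of $v(t)$ over
interior grid points, with standard error $(\sum w_i)^{-1/2}$; weights are
capped at $10^6$ times the median weight so a single (near-)noise-free point
cannot dominate. All retained interior grid points contribute, regardless of
how early a series closed — shorter series simply contribute fewer, more
uncertain points. The conventional readout kept for comparison is the OLS
slope of measured area on time over retained points. Study-level statistics
are per-condition means/SDs of both readouts and the assay window
$\mathrm{SNR} = (\mu_\text{cond} - \mu_\text{baseline})/\sigma_\text{baseline}$
against a named non-migrating baseline; a zero-spread baseline leaves the
SNR undefined (reported as `NA` with a warning) rather than infinite.

Units are px and hours throughout; `pixel_scale` (µm/px; 1.3 in the
screening setting the defaults come from) converts velocities to µm/h and
areas by its square.

## The synthetic generator

`simulate_wound()` renders the erosion of an initial shape by a disk of
radius $v\,t$ — the exact geometric statement of "every front point advances
at normal speed $v$" — so ground truth stays closed-form: disks and
rectangles directly; ellipses by the inner Steiner formula
$A - P d + \pi d^2$, $P - 2\pi d$ (exact while $d$ is below the minimum
curvature radius $b^2/a$; beyond it the ground truth is `NA` but frames are
still rendered from the true eroded set via distance-to-boundary); convex
polygons by analytic inward edge shifts. Intensities are two levels plus
clipped i.i.d. Gaussian noise; optional bright blobs inside the wound mimic
drifting cells and must be absorbed by the hole fill. Defaults encode the
acquisition the method was designed around: 16 frames at 1 h, 512×512 px,
1% intensity noise, wound dark on bright cells.

`simulate_study()` adds the two ingredients that make condition comparisons
honest: replicate-level biological variability (each replicate's true
velocity drawn from a folded normal $|N(v, 0.25)|$ px/h — folded rather than
truncated so a slow condition keeps nonzero spread, and large enough that the
implied front displacement over a sequence exceeds the raster's resolution)
and shape heterogeneity (replicates cycle disk/larger disk/ellipse/rectangle
with ±10% size jitter). Under these conditions the area slope spreads with
geometry while the velocity does not — the package's reason to exist.

What the generator does *not* emulate: cell texture, proliferation pressure,
fluorescence point-spread and shading, front roughening, stage drift. Passing
tests therefore certify the measurement and inference chain on idealized
two-level images, not robustness to every optical artifact of a real
screen; the `scharr` path is exercised on textured synthetic frames as a
qualitative check only.

## Problem sizes

The test and acceptance runs use 512×512 px sequences of 16 frames for the
single-sequence and geometry properties, 256×256 px, 10–12 frames for
multi-condition studies, and 128–160 px fixtures for unit-level checks —
sizes chosen so the full suite exercises every stage, including four-figure
pixel wounds, in a few minutes on one CPU.

## Known limitations

* Absolute areas/perimeters carry the threshold-offset bias discussed above;
  compare conditions on velocity, or on areas measured at identical settings.
* One wound per field; multi-wound fields will gate to the largest candidate.
* The quadratic-kernel GP is a strong prior; velocity transients (delayed
  drug response) are smoothed. Refitting on windows, or a richer kernel,
  would be the extension point.
* $\sigma_v$ omits GP cross-covariances (conservative) and the detection
  variances estimate boundary fuzziness, not segmentation failure.
* The closure rule is an area threshold; a wound that fragments before
  closing is measured as its largest surviving piece.
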