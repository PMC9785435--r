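---
title: "Iris boundary localization with a compensated radial-gradient operator"
author: "irisloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iris boundary localization with a compensated radial-gradient operator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irisloc)
```

## The problem

Iris recognition and ocular diagnosis pipelines need the pupillary (inner)
and limbic (outer) boundary circles of the iris before any texture can be
unwrapped or compared. In cooperative, near-infrared close-up imagery both
boundaries are crisp, near-concentric circles and the classical
integro-differential search finds them reliably. In non-cooperative
acquisition — hand-held or stand-off cameras, visible light, subjects
wearing glasses — the image inside the eye region carries specular
reflection spots, eyelash strokes, partial eyelid occlusion and off-angle
(elliptical) distortion. Objectives that sum raw gradient evidence around a
candidate circle are easily captured by a few pixels of spurious contrast.

`irisloc` implements the full localization stage: denoising, two circle
objectives, a constrained two-stage search, a coarse initialization, a
synthetic scene generator with exact ground truth, and an evaluation
harness. An external object detector (which in a production system supplies
the eye bounding box) is out of scope; its output is modeled by annotation
files or by the built-in intensity-based pupil estimate.

## The two objectives

Both objectives score a candidate circle $(x_0, y_0, r)$ on a gray image
$I(x, y) \in [0, 1]$.

**Integro-differential operator.** The smoothed radial derivative of the
normalized contour integral,

$$\max_{(r, x_0, y_0)}\;\Bigl|\,G_\sigma(r) * \frac{\partial}{\partial r}
\oint_{r, x_0, y_0} \frac{I(x, y)}{2\pi r}\,ds\,\Bigr|,$$

computed here as: contour mean $m(r)$ at each candidate radius (bilinear
interpolation at $n$ uniform points along the integration path), central
differences in $r$, convolution with a 1-D Gaussian of standard deviation
$\sigma$, absolute value.

**Compensated radial-gradient operator.** For $n$ points uniformly spaced
along the path, the radial gradient of the $\theta$-th point is the
same-ray intensity difference one radial step outward,

$$g_{\theta,r} = I_{\theta, r+\Delta r} - I_{\theta, r},$$

and its compensation factor is half the sum of absolute differences to the
two angular neighbors,

$$C_{\theta,r} = \tfrac12\bigl(|g_{\theta+1,r} - g_{\theta,r}| +
|g_{\theta-1,r} - g_{\theta,r}|\bigr),$$

giving the objective $\sum_{\theta=1}^{n} (g_{\theta,r} - C_{\theta,r})$.
On a genuine circular boundary the gradient varies smoothly with $\theta$,
so $C \approx 0$ and the score approaches the plain gradient sum. An
isolated interference point — a reflection spot crossed by one or two rays —
produces a gradient spike that differs sharply from both neighbors; the
spike is cancelled (and slightly over-cancelled, since the neighbors also
pay) rather than dragging the argmax toward the interference. $C \ge 0$
always, so the compensated score never exceeds the uncompensated sum.

```{r compensation}
compensation(c(2, 10, 4))[2]   # 0.5 * (|4 - 10| + |2 - 10|)
```

## Two-stage search

The search is exhaustive over a restricted field, never gradient-based: the
objectives are non-convex and the restricted field is small enough that
enumeration is cheap and exactly reproducible.

1. **Inner boundary** (`locateInner`): full-circle path with `n_inner = 32`
   points (the contour is short), centers on an integer grid within
   ±10 px of the detector-box center, radii from 8 px to
   0.35 · min(box side).
2. **Outer boundary** (`locateOuter`): two lateral 90° arcs with
   `n_outer = 256` points, centers within ±3 px of the found inner center
   (the two boundaries are near-concentric but not exactly concentric),
   radii in the open interval $1.2\,r_p < r < 0.5\max(\text{rows, cols})$,
   discretized at 1 px.

Ties are broken toward the smaller radius, then lexicographically by
(cy, cx), so results are exactly deterministic. Candidates with fewer than
half their sample points inside the image are rejected; remaining scores are
rescaled by $n / n_\text{valid}$ so partially framed candidates stay
comparable.

The lateral-arc choice for the outer stage deserves a note: the outer
boundary is the one interfered with by eyelids and lashes, which enter from
the top (and bottom, for lower lids). Ninety degrees per side — the arcs
$[315°, 45°)$ and $[135°, 225°)$ — keeps the path on sclera-adjacent
horizontal flanks. An alternative reading (90° total, 45° per side) is
available by configuring `operators$outer_arcs`.

## Denoising

Two interference classes are removed inside the (10 %-padded) detector box
before searching; the rest of the image is untouched.

* **Reflections**: pixels at or above `reflection_threshold = 0.90`
  (specular points are near-saturated), dilated by 2 px to cover bloom
  halos, then filled by harmonic inward interpolation — masked pixels are
  iteratively replaced by their 4-neighbor mean until the largest per-sweep
  change is below $10^{-5}$ (cap 500 sweeps). Pixels outside the mask are
  bit-identical to the input.
* **Eyelashes**: grayscale morphological closing with a disk of radius 3 px
  at the 224-px reference scale (rescaled proportionally). Closing is
  extensive and idempotent; it lifts dark detail thinner than the element
  while leaving boundary steps wider than the element in place.

The order — reflections first, then closing — matters only weakly, but
inpainting first prevents the closing from smearing saturated spots. Both
search stages run on the same denoised image.

## Coarse initialization

When no detector box is available, `coarsePupilEstimate` thresholds the
(reflection-inpainted) image at its 5th intensity percentile plus a 0.05
margin and takes the centroid of the largest compact dark component — the
pupil is the darkest compact structure in an eye image. The returned square
box of side $6 r_\text{equiv}$ mimics a detector box: its center may miss
the true pupil center by a pixel or two but falls well within the pupil,
which is all the inner-stage center window needs. Components covering more
than a quarter of the frame are rejected (the threshold separated nothing).

## The synthetic scene generator

`renderScene` / `generateBatch` produce the study conditions: a dark pupil
disk inside a textured iris annulus inside a bright sclera, with optional
near-saturated reflection disks, dark anti-aliased eyelash strokes hanging
from the lid line, partial upper-eyelid occlusion, horizontal (off-angle)
axis scaling and Gaussian blur. Every scene carries exact ground truth
(post-distortion equal-area circles, tight iris bounding box, reflection
centers), so boundary recovery is measurable to the pixel.

Defaults, chosen once as plausible for 224-px eye crops: iris radius
48–66 px, pupil radius 16–28 px (capped at 0.45 of the iris radius),
pupil–iris center offset up to 2 px, intensities ≈ 0.10 / 0.45 / 0.85
(pupil / iris / sclera, the outward-brightening near-infrared convention),
radial-sinusoid iris texture of amplitude 0.04 plus low-amplitude noise
(so within-iris gradients are nonzero and the compensation has work to do),
2–4 reflection disks of radius 2–4 px at 0.99, 3–6 lashes, eyelid coverage
15–30 % of the iris vertical extent, axis ratio down to 0.92, blur
$\sigma = 0.5$ px. Boundaries are anti-aliased with a 1-px linear soft edge;
a `hardEdge` flag renders ideal step edges for exact analytic checks.

What the generator does *not* emulate: photometric camera effects (sensor
noise, vignetting, NIR illumination falloff), glasses-frame geometry and
refraction, hair, limbus softness gradients, and real iris texture
statistics. Passing benchmarks on these scenes therefore demonstrates the
operators' geometric robustness to the modeled interference classes — not
performance on any real-world dataset, which additionally depends on the
upstream detector.

## Numerical choices

* Coordinates are 1-based and continuous; x = column, y = row; pixel
  centers at integers; angles counter-clockwise from +x with "up" =
  decreasing row. Sampling is bilinear (the method is silent on
  interpolation; bilinear is the standard choice and keeps scores smooth in
  sub-pixel center shifts).
* $\Delta r = 1$ px and $\sigma = 1$ px by default.
* The radial step $\Delta r$ makes the compensated objective prefer the
  inside shoulder of an anti-aliased edge (the pair $(r, r+\Delta r)$ best
  straddles the ramp at $r \approx r_\text{true} - \Delta r/2$), a
  systematic half-pixel-to-one-pixel inward radius preference visible in the
  benchmarks; the integro-differential profile peaks at the ramp center.
  Both sit well within the 2-px recovery tolerance.
* The integro-differential radial profile is evaluated on support radii
  padded ~3σ beyond both ends of the candidate list, so the derivative is
  centered and the Gaussian has full support at the range boundaries; scores
  are reported for the candidate radii only. Without the padding, a true
  radius at the top of the admissible interval (common, because the
  detector box is tight: $0.5\max(\text{rows, cols}) \approx r_\text{iris}$)
  is systematically under-scored at the correct center.
* At the open end of a partial arc — and next to an out-of-bounds sample —
  the missing neighbor term of $C_\theta$ is replaced by the existing one;
  with no usable neighbor, $C_\theta = 0$. On a single full-circle arc,
  neighbors wrap cyclically.
* The compensated sum is left unnormalized in $r$ (no $1/2\pi r$ factor),
  matching its definition; only the out-of-bounds rescaling
  $n/n_\text{valid}$ is applied. A radius bias on very low-contrast images
  is conceivable but not observed on the synthetic conditions.
* Degenerate inputs are contracts, not crashes: an empty outer-radius
  interval or an all-invalid candidate set yields a `LocalizationResult`
  with status `outer_failed` / `inner_failed`; a uniform image fails the
  coarse estimate the same way.

## Benchmarks and problem sizes

`runBenchmark` denoises each scene once and evaluates all requested
objectives on the identical denoised image and identical inner search grid
— the outer grid follows each method's own inner result, as the two-stage
design dictates. The shipped acceptance computation uses 100 scenes per
stratum at 224×224; at these sizes the full three-stratum comparison runs
in a few minutes on one CPU. On clean scenes both objectives recover all
boundaries within 2 px and agree within one grid step; under combined
reflections + lashes + occlusion the compensated operator's recovery rate
is at least that of the uncompensated gradient sum, and at least that of
the integro-differential baseline under reflections — the directional
robustness claim, reproduced on synthetic conditions.

## Known limitations

* Boundaries are modeled as circles; strongly off-angle irises (axis ratio
  well below ~0.9) violate the model and degrade radius recovery first.
* The outer search inherits inner-stage failures: a wrong pupil fit shifts
  the admissible outer annulus. Status flags expose this; no joint
  refinement is attempted.
* The coarse pupil estimate assumes the pupil is the darkest compact
  region; heavy shadows or very dark frames of glasses can capture it. An
  external detector box is the intended input in such imagery.
* Search resolution is 1 px in center and radius; no sub-pixel refinement.
* Eye-disease imagery (distorted pupils) and video are out of scope.
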