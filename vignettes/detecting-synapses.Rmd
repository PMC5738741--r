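---
title: "Detecting boutons, spines and synapses in two-photon image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting boutons, spines and synapses in two-photon image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsedetect)
```

## The problem

In dual-colour in vivo two-photon imaging, one fluorescence channel
(Channel 1) collects both GFP and YFP signal and a second (Channel 2)
collects GFP only. Long-range projecting axons carry GFP; local neurons
carry YFP, so subtracting Channel 2 from Channel 1 isolates the local
dendrites (and local axons). A chemical synapse consists of a presynaptic
axonal bouton apposed to a postsynaptic dendritic spine. Light microscopy
cannot resolve the synaptic cleft, but a bouton and a spine lying within a
few hundred nanometres of each other is a reliable proxy: the package
detects boutons in the axon channel and spines in the YFP-only channel,
pairs them by lateral distance within each z-layer, and links the per-layer
pairs across layers to count three-dimensional synapses.

The geometry throughout assumes a lateral pitch of 137 nm/pixel and an
axial pitch of 700 nm/layer (configurable). All coordinates are 1-based
`(z, y, x)` with `y` down rows and `x` across columns; distances are
lateral pixels, because the ~5x axial anisotropy makes 3D Euclidean
distances misleading.

## Intensity models and Hessian enhancement

A bouton is modelled as a 2D Gaussian intensity surface

$$R(x,y) = C\,\exp\!\left(-\frac{(x-x_0)^2+(y-y_0)^2}{2\delta^2}\right),$$

and a dendrite as a ridge whose cross-section is a Gaussian curve of scale
$\sigma$. The model scale is tied to the structure radius $r$ by
$\delta = r/\sqrt{3}$: the third derivative of the Gaussian profile
changes sign at $x_0 + \sqrt{3}\delta$, which is where the edge of a
structure of radius $r$ should sit. With the default physical sizes
(boutons 1.0 µm across, spine-bearing dendrites 0.9 µm) and the 137 nm
pitch this gives $r = 4$ px and $w = 3$ px — `radius_from_physical()` and
`scale_from_radius()` compute both.

Both detectors work through the eigenvalues of the image Hessian. At a
blob centre both eigenvalues are strongly negative; on a ridge centreline
one eigenvalue is strongly negative and the other is ~0. Accordingly
`enhance_blobs()` returns the additive inverse of the eigenvalue of
*minimum* absolute value (large only where both curvatures are negative),
and `enhance_lines()` returns $-\sigma^2\lambda$ for the eigenvalue
$\lambda$ of *maximum* absolute value where $\lambda < 0$, and zero
elsewhere, so its output is non-negative.

### Numerical choices

The Hessian of a discrete image is computed by correlation with sampled
Gaussian-derivative kernels at the model scale, truncated at 4 standard
deviations, with reflective borders. Discrete moment conditions are
enforced on the kernels (zero sum and exact second moment for the
second-derivative kernel) so they are exact on quadratics.

Probing an ideal Gaussian structure of scale $t$ with kernels of scale $s$
yields the Hessian of the same model at effective scale
$\sqrt{t^2+s^2}$ with amplitude attenuated by $t^2/(t^2+s^2)$ (blob) or
$t/\sqrt{t^2+s^2}$ (ridge). The enhancers compensate for the
matched-scale case ($s = t$): a constant factor 4 for blobs and
$2\sqrt{2}$ for lines. With this compensation an ideal blob responds with
its own model curvature $C/\delta^2$ at its centre and an ideal ridge of
amplitude $C_\text{den}$ responds with $C_\text{den}$ on its centreline,
which is what the closed-form profiles predict; the test suite verifies
the discrete pipeline against those closed forms to within 5% at three
scales and three orientations (observed errors are below 0.5%). This is a
fixed matched-model normalization, not a scale-sweep
($\gamma$-)normalization — the pipeline deliberately runs at a single
scale per structure class.

One analytic subtlety: the enhanced-blob profile as a function of squared
distance $m$ to the centre switches expression at $m = 2\delta^2$. That
switch is a genuine sign flip — the two eigenvalue magnitudes cross
there — so the profile is discontinuous at the switch with one-sided
values $\mp\sqrt{3}/(\delta^3 e)$; the tests assert the crossing rather
than continuity. Independent differentiation of the ridge model gives a
mixed partial $I\,\sin\theta\cos\theta\,(1/\sigma^2 - u^2/\sigma^4)$ —
with a minus between the terms — which is what makes the eigenvalues
orientation-invariant; the implementation uses the derived form.

## Bouton detection

Per layer: normalize, enhance at $\delta = r/\sqrt3$, then

1. strict local maxima (plateaus excluded) above a noise floor of
   3 robust standard deviations of the enhanced image;
2. threshold segmentation of the enhanced image — Otsu's method on the
   strictly positive responses by default, overridable by a fixed value;
3. keep 8-connected regions that contain a maximum and look disk-like:
   eccentricity ≤ 0.95, major axis in [2, 6r], minor axis ≥ 2 px
   (second-moment definitions; a filled disk of radius $\rho$ has major
   axis $2\rho$);
4. require the region's peak in the *original* image to exceed 3x the
   local axon-shaft intensity, estimated as the median original intensity
   over above-background pixels in an annulus 1–4 px outside the region.
   The background level is the larger of median + 2 MAD and 5% of the
   layer maximum; if no annulus pixel qualifies the detection is kept and
   flagged rather than silently dropped.

Every rejected candidate is reported with its reason
(`eccentricity`, `major_axis`, `minor_axis`, `brightness_ratio`,
`shaft_unresolved`), so audits of false positives/negatives per layer are
possible on synthetic data.

When processing a stack, `run_full()` normalizes by the *stack* range and
computes *one* segmentation threshold per stack (Otsu over the pooled
positive responses of all layers). A per-layer adaptive threshold
over-adapts on layers containing no bouton — min-max normalization
stretches faint shaft remnants to full range and Otsu then segments them —
which is exactly the failure mode fixed thresholds avoid; one acquisition
has one intensity scale, so one threshold is also the physically coherent
choice. `detect_boutons()` on a single image retains per-image
normalization so the function remains self-contained.

## Spine detection

Per layer: normalize, ridge-enhance at $\sigma = w/\sqrt3$, Otsu-segment,
then reduce the dendrite mask to a one-pixel skeleton with the
two-subiteration parallel thinning operator. A pixel $p$ with neighbours
$x_1..x_8$ (east first, counter-clockwise) is deleted in sub-iteration 1
iff

- (a) the crossing number $X_H(p) = 1$,
- (b) $2 \le \min(n_1, n_2) \le 3$, and
- (c) $(x_2 \lor x_3 \lor \bar{x}_8) \land x_1 = 0$;

sub-iteration 2 replaces (c) with (d)
$(x_6 \lor x_7 \lor \bar{x}_4) \land x_5 = 0$. Deletions within a
sub-iteration are simultaneous; iterations repeat to a fixed point. Border
pixels read missing neighbours as 0. The suite checks idempotence, the
per-pixel fixed-point property, preservation of 8-connected components
and 4-connected holes on randomized masks, and pixel-exact agreement with
an independently coded lookup-table implementation of the same scheme.

Spine candidates come from skeleton geometry: spur pixels (endpoints,
deleted iteratively for up to `max_spur_length` rounds) are putative spine
locations, and a removed-spur component counts as a spine when it hangs
off the side of a surviving line. Concretely, some pruned-skeleton pixel
adjacent to the component must still have ≥ 2 skeleton neighbours (the
*attachment anchor*); components produced by eroding a line's free end
attach to an endpoint and are discarded. The candidate is placed at the
spur's distal end — the removed pixel farthest from the anchor. The anchor
rule is used instead of a lookup of explicit branch-point pixels because
parallel thinning frequently realizes a T-junction as a diagonal jog
spread over two pixels: the 4-neighbour cross kernel (`find_branch_points()`,
kernel `[[0,1,0],[1,1,1],[0,1,0]]`, threshold 4) misses diagonal
attachments, and the crossing-number variant (`find_bifurcations()`)
misses 4-connected T-junctions, so neither enumerates all attachment
sites; both are still exported for skeleton analysis.

Defaults: `max_spur_length = 7` and `search_radius = 8`. A spine
protruding ~0.5 µm beyond the shaft surface spans, at 137 nm/pixel, about
4 px of protrusion + 3 px of shaft half-width + ~1 px of skeleton-midline
slack ≈ 7 px of skeleton spur; the window radius is one more so a fully
pruned spur always fits. These were calibrated on the synthetic suite and
are logged in every report.

Because YFP labels axons as well as dendrites, candidates are screened:
the mask component supporting each candidate is cropped to a 15 px box
and judged by its area/perimeter ratio (perimeter = foreground pixels
with a background 4-neighbour inside the box, so a shaft crossing the box
is not charged for its cut ends) and its mean normalized intensity.
Defaults `ratio_min = 1.2`, `intensity_min = 0.2`: a 1-px line scores
exactly ratio 1, a 3-px-wide line ~1.4, a filled 7x7 square ~2, and
dendrite shafts ~2.5–3.5, so 1.2 separates axons from dendrites with
margin on both sides (calibrated on the synthetic suite). The intensity
criterion uses the normalized image, recorded in the output metadata.

## Synapse assembly

`pair_synapses_2d()` pairs accepted boutons and spines of one layer
greedily by ascending distance, one-to-one, within `d_max = 6` px (bouton
radius + spine-tip tolerance; "overlap" is not otherwise quantified).
`link_across_layers()` links detections in consecutive layers when each
is the other's nearest neighbour and their distance is ≤ `d_link = 4` px;
chains become 3D objects, and a detection missing in an intermediate layer
splits the chain (no z-gap tolerance — the report surfaces both fragments
so a proofreader can merge). Ties in nearest-neighbour distance are broken
by (y, x) order, making the linking invariant to detection order. The same
linker counts boutons in 3D.

## The synthetic generator

The generator emulates what the detectors need from real data: boutons as
Gaussian surfaces (peak 150, radius 4 px) riding on dim axon shafts
(amplitude 28, half-width 1.3 px) — a peak ≥ 5x shaft, comfortably above
the 3x acceptance criterion; dendrite tubes (amplitude 120, half-width
3 px) with spine stubs (length 6 px from the centreline, half-width
1.6 px, amplitude 110); a dim axon-like contaminant with a short side twig
in the dendrite channel to exercise the screening step; background 10;
and noise modelled as Poisson scaling with gain 0.1 plus Gaussian sd 3 —
shot-noise-limited detection with a small read-noise floor, resembling
averaged two-photon frames. Boutons persist over 3–6 layers with a cosine
axial taper floored at 0.6 of peak, so they satisfy the brightness
criterion throughout their axial extent; spines attach to the rasterized
tube centreline so the rendered geometry and the skeleton agree.

Channel 1 is rendered as axon scene + dendrite scene + background,
Channel 2 as axon scene + background, and noise is applied to both
channels independently, so channel subtraction behaves as it does on real
dual-colour data. Rendering is additive pre-noise and bit-reproducible
from the spec seed. Ground truth (per-layer coordinates and 3D
memberships) is emitted alongside and round-trips through CSV.

What the generator does *not* emulate: the optical PSF and its axial
elongation (structures are rendered in-plane; the out-of-scope external
deconvolution step would matter on real data), motion between layers,
depth-dependent background, crossing neurites in dense tissue, and
non-perpendicular spines. Passing the recovery tests therefore
demonstrates the correctness of the algorithmic chain under the stated
models, not performance on real tissue.

`default_benchmark_suite()` builds six stacks — noise-free sparse/dense,
noisy sparse/dense, an axon-contamination scene, and a noise-free
12-synapse stack (216 x 216 x 12) whose 3D synapse count is known exactly.
Stacks are 144 x 144 with 6–8 layers except the 12-synapse stack; these
sizes keep a full suite run under ten seconds while leaving tens of
structures per class.

## Degenerate inputs and edge rules

- Constant images normalize to all zeros instead of erroring, keeping
  batch runs alive on blank layers.
- Channel subtraction clamps negative differences to zero (negative
  fluorescence is noise, not signal).
- Plateau pixels are never local maxima (strict inequality), so constant
  regions yield no candidates.
- An isolated skeleton pixel survives thinning (condition (b) fails);
  closed loops survive spur pruning (no endpoints).
- A region whose shaft annulus contains no above-background pixel is
  accepted with a `shaft_unresolved` flag and a warning rather than
  silently classified.
- Evaluation matches detections to truths greedily by distance,
  one-to-one, within 3 px for boutons and spines and 4 px for synapses
  (sub-structure scale at the default geometry).

## Known limitations

- The pipeline is strictly per-layer 2D plus axial linking; there is no
  3D segmentation or 3D thinning.
- Multi-bouton and multi-spine synapses are out of scope: pairing is
  one-to-one.
- The segmentation threshold transfers across layers of one stack but not
  across instruments; new data requires re-deriving the two radii from
  the physical sizes and pixel pitch (the only dataset-specific
  parameters).
- Deconvolution is treated as an optional external preprocessing step; a
  pre-smoothing hook (`deriv_scale`) exists on the enhancers instead.
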