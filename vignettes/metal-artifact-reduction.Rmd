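---
title: "MV-prior metal artifact reduction: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MV-prior metal artifact reduction: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mvmar)
```

## The correction model

Metal artifacts in kV-CT are projection-domain defects: along rays that
cross metal, photon starvation (near-total absorption) and beam hardening
(preferential loss of low-energy photons) make the measured
log-transmission inconsistent with any attenuation image, and filtered
back-projection spreads that inconsistency into streaks and shading. The
defective cells are exactly the *metal trace* — the sinogram support of
the forward-projected metal mask — which suggests the correction family
this package implements: estimate what the trace *should* contain, and
remove the image-domain footprint of the deviation.

Where plain interpolation (LIMAR) discards the trace content and NMAR
normalizes it by a prior derived from the corrupted kV image itself, the
method implemented here builds its prior from a co-registered megavoltage
CBCT of the same anatomy. At MV energies attenuation is Compton-dominated
and metal is nearly transparent, so the MV image provides reliable
*anatomy* (which tissue is where) even though its gray values are not
planning-grade. The chain is:

1. `blockwise_segment()` — two-threshold Otsu per 8×8 block of the MV
   image yields masks M1 (bone + metal), M2 (soft tissue), M3
   (cavity/air).
2. `build_template()` — the template copies the kV values on M1 and fills
   M2/M3 with their kV regional means: piecewise-constant, artifact-poor,
   but with correct kV-scale values.
3. `metal_trace()`, `sinogram_difference()` — FP(kV) − FP(template)
   restricted to the trace isolates the metal-induced deviation plus
   whatever anatomy the template erased; outside the trace it is forced
   to zero, which is what protects the uncorrupted data.
4. `smooth_boundaries()` — linear ramps over Δ bins take the difference
   to zero at the trace edges, because a hard cut would itself
   back-project into fresh streaks.
5. `reconstruct_artifact()`, `correct_once()` — FBP of the smoothed
   difference, Gaussian high-frequency suppression, subtraction from the
   *original* kV image; metal pixels are restored from the input so the
   implant stays visible for delineation.
6. `iterate_mar()` — the template fill means are recomputed from the
   corrected image and the pass repeats. Only the means (and the M1 copy)
   can change: the masks come from the MV image, which the correction
   never touches, and the metal mask from the kV input, so both are held
   fixed.

Two identities pin the architecture down and are tested exactly: an empty
metal mask makes every method the identity (zero trace), and a template
equal to the input produces a zero difference and hence zero correction.

### Subtraction against the original image

Each iteration subtracts its artifact estimate from the original kV
image, not from the previous corrected image. The artifact estimate is a
function of the *current template*; re-deriving it against the original
image keeps the estimates from compounding reconstruction error, and
makes `corrected_i = kv − artifact_i` an invariant the tests assert. The
alternative reading (correcting the previous output) compounds FBP round
trips and has no advantage: the template is where iteration information
accumulates.

### What the method cannot recover

The template copies kV values on M1, including artifact-corrupted bone
near the metal. Deviations that are *shared* by the image and the
template cancel in the sinogram difference, so the first pass
under-corrects in and around bone; iteration recovers part of this as the
M1 copy improves. Similarly, the metal's own deficit (its reconstructed
value is far below its true attenuation) is deliberately not corrected —
both sinograms carry the same apparent metal — because restoring true
metal values is neither possible from starved data nor needed for
delineation. The practical consequence, visible in the benchmark, is that
the correction is strongest in soft tissue between and around the metals
and conservative inside M1.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `iterations` | 3 | — | lower end of the typical 3–4; the benchmark error is essentially flat after 3 |
| `delta_n1`, `delta_n2` | 4 | detector bins | ramp length; long enough to kill the cut discontinuity, short enough not to smear neighbouring anatomy |
| `hff_sigma_mm` | 1.5 | mm | high-frequency suppression width; physical units so the filter's effect does not change with grid resolution (see below) |
| `metal_threshold_hu` | 2500 | HU | above cortical bone, far below reconstructed metal |
| `block` | 8 | pixels | block edge of the prior segmentation |
| `trace_epsilon` | 1e-6 | relative | trace support cutoff; kills projector interpolation dust without narrowing real shadows |
| `min_metal_area` | 4 | pixels | speckle removal in the metal mask |

The high-frequency filter is specified in millimetres, not pixels: a
pixel-denominated blur changes meaning with resolution, and on a 2 mm
grid a 1.5-pixel blur (3 mm) removes most of the streak-frequency content
the subtraction needs — in calibration it made the correction worse than
no correction. At the reference 1 mm grid, 1.5 mm and 1.5 px coincide.

NMAR's self-prior thresholds are `air_hu = -700` and `bone_hu = 300`. An
air cut at the more usual −500 HU misclassifies dark streaks as air in
severely corrupted images, and NMAR then falls behind even the
uncorrected image; −700 keeps the prior usable while remaining a
plausible air boundary. This matters only for NMAR — the proposed method
does not use a kV-derived prior.

## The simulator

`simulate_scan_pair()` emulates the physics that causes the artifacts:
per detector bin, detected counts are
`N0 · Σ_E w(E) · exp(−Σ_m μ_m(E) · len_m)` with Poisson noise and a
count floor of 1 before the log (photon starvation), reconstructed by
FBP after the standard water beam-hardening precorrection, and calibrated
to HU through the spectrum's effective water/air attenuations. Material
μ(E) tables (air, water, soft tissue, lung-equivalent, cortical bone,
titanium, amalgam-like alloy) are shipped as an editable CSV populated
from standard published attenuation data; every test depends only on
their orderings and ratios, never on exact values. The kV spectrum is a
nine-bin 40–120 keV hump; the MV beam is two Compton-region bins. Ground
truth is the noiseless monochromatic reconstruction at each spectrum's
effective attenuation, so "artifact" is measured against an otherwise
identical reconstruction chain, not an unreachable analytic ideal.

The default *dental phantom* is a head-sized soft-tissue ellipse with a
bone skull shell, an oral air cavity, a jaw arc of bone and 2–4
amalgam-like inserts of 6 mm radius along the arc; its geometry is
specified in millimetres so the same anatomy renders at any grid size. A
second *QA fixture* (water body, bone shell, soft-tissue insert A,
air-cavity region B, removable amalgam rod) mirrors the two-region
phantom-evaluation layout with named ROIs.

What the simulator does **not** model: scatter, detector energy response
and cross-talk, fan/cone geometry (the projector is parallel-beam — the
method operates on sinogram supports and differences, which parallel
beam represents faithfully), 3-D effects, patient motion, and
registration error between kV and MV (pairs are co-registered by
construction; on scanner data registration quality directly limits the
method and is out of this package's scope). Passing tests therefore
demonstrate the correction logic under the stated artifact physics, not
clinical performance.

### Study conditions

The benchmark study conditions, chosen once during calibration and used
by the test suite and the acceptance script: 128×128 grid at 2 mm pixels
(256 mm field of view), 128 angles over the half circle, kV `N0 = 2e5`
photons per bin, MV `N0 = 5e5`, three amalgam inserts, seed 1. At these
conditions the method ordering (proposed < NMAR < original and
proposed < LIMAR < original on inter-metal NRMSD) is stable across seeds
and the per-iteration NRMSD is monotonically non-increasing. `N0` is
defined per detector bin and is not rescaled when the bin width changes
with grid size — dose realism across resolutions was not a goal. The
geometry module's own reference configuration (round-trip accuracy tests)
is 256×256 at 1 mm with 180 angles.

Severity calibration is deliberately one-dimensional: at mild severity
(small titanium inserts) the original image is good enough that trace
inpainting costs more than it repairs, and NMAR beats LIMAR as its
normalization intends; at the severe amalgam condition LIMAR's bulk
replacement wins over NMAR's corrupted self-prior while both trail the
MV-prior method. The test suite asserts the NMAR-over-LIMAR ordering on
the titanium variant and the full method ordering on the severe variant,
which is exactly the regime split the two baselines are known for.

## Numerical choices

* **Projector**: ray-driven line integrals with bilinear sampling at one
  pixel-spacing steps; linear, exact on zero images, nonnegative on
  nonnegative images. The FBP filter is a band-limited Ram-Lak kernel
  sampled in the spatial domain (avoids the DC bias of a frequency-domain
  ramp), with optional Shepp–Logan/Hann/cosine apodization; zero
  projections short-circuit so zero sinograms reconstruct to exactly
  zero. Round-trip interior RMSE is below 0.5% at the reference geometry;
  tests bound it by 5%.
* **Otsu**: 256-bin histogram over the sample range (64 bins in the
  oracle-equivalence tests), exhaustive maximization of between-class
  variance via cumulative moments; among ties the lexicographically
  smallest `(t_low, t_high)` wins, so output is deterministic. Fewer than
  3 distinct values raises a typed degenerate-input condition.
* **Blockwise splicing**: each block's local 3-class split is mapped to
  tissue labels by comparing the local class *means* against the global
  thresholds, rather than taking local rank order at face value — a block
  containing one noisy tissue then lands entirely in one class instead of
  sprinkling its noise tails into M1/M3. Near-constant blocks (range
  < 10 HU) fall back to global thresholds directly; a globally constant
  image is classified by fixed CT cut points (−500/300 HU) as a last
  resort. Metal-hint pixels are excluded from all threshold estimation
  (their extreme values would capture the high threshold and push bone
  into M2) and forced into M1 afterwards.
* **Boundary ramps**: the printed form of the interpolation rule ramps
  *away* from zero at the outer extension edge and references the wrong
  boundary index in its second branch; both contradict its stated
  purpose. The implementation realizes the stated intent — linear ramps
  reaching zero at `k1 − Δ` and `k2 + Δ` — and no strict-as-printed mode
  is provided. Overlapping extension zones of adjacent runs are summed
  and clipped to the larger boundary magnitude; ramps are truncated at
  the detector edge.
* **Baselines in difference form**: `kv − FBP(FP(kv + 1000) − inpainted)`
  instead of reconstructing the inpainted sinogram directly —
  algebraically identical (FBP is linear) but the FBP round-trip error
  cancels outside the trace. The +1000 HU offset keeps interpolation and
  normalization on nonnegative sinograms (neither is offset-invariant,
  unlike the proposed method's subtraction) and cancels in the
  difference.
* **Metrics**: noise is the population SD; MRE applies to ROI means;
  reports carry full precision plus a 2-decimal MRE column for
  table-style formatting. Zero reference means/energies raise a typed
  undefined-metric condition rather than returning infinities.
* **Determinism**: all randomness flows through one seed; simulation
  seeds are applied via a save/restore wrapper so the session RNG is
  untouched; provenance sidecars contain no timestamps or absolute
  paths, making same-seed outputs byte-identical.

## Known limitations

* Slice-wise 2-D only; parallel-beam geometry; no registration module —
  inputs must be co-registered, which the simulator guarantees and
  scanner data does not.
* The 3-class template cannot represent slices with four distinct density
  levels (e.g. a lung-density insert adjacent to air is filled with a
  blended mean); the correction then mis-fills that region. The same
  limitation applies to the method as described, not just this
  implementation.
* The whole-image diagnostic NRMSD can tick up marginally across
  iterations while the artifact-region NRMSD falls: iteration sharpens
  the correction near metal, where the halo dominates the whole-image
  metric. The iteration-improvement claim is therefore evaluated on the
  inter-metal ROI.
* DICOM and NPZ ingestion are not provided; NIfTI and CSV (with JSON
  sidecar) are the interchange formats, and a slope/intercept rescale
  helper covers values extracted from DICOM by other tools.
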