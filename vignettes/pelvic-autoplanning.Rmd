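---
title: "Automated pelvic planning: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated pelvic planning: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pelviplan` automates the two classic forward-planned external-beam
techniques for cervical cancer — the bony-landmark 4-field box and
PTV-conformal 3D-CRT — on binary structure masks, together with
field-in-field (FIF) hot-spot reduction, coverage normalization and
EMBRACE II-style evaluation. This vignette is the package's own account of
the science: what is modelled, what is deliberately simplified, and why
each numerical convention is the way it is.

## Coordinates and geometry

All volumes share one regular grid (`image_geometry`): x toward the
patient's left, y posterior, z superior; voxel centres at
`(index - 0.5) * spacing` mm. Gantry angles are restricted to the four
cardinal directions with **parallel (non-divergent)** beam geometry:
0&deg; enters anteriorly (travelling +y), 90&deg; from the patient's left
(-x), 180&deg; posteriorly, 270&deg; from the right. Beam's-eye-view (BEV)
images always map columns to z; rows map to the remaining transverse axis,
flipped for 180&deg;/270&deg; so opposed views mirror as seen from the
source. Parallel geometry admits exact oracles (projection is a ray-wise
`any`, back-projection its exact right inverse) at the cost of real
divergence effects; the consequences for the dose model are handled below.

## The synthetic phantom: a stated world

The phantom (`generate_phantom`) stands in for patient CTs and
auto-contours. It is schematic by design: only the geometric relations the
planning algorithms consume need to be faithful — bony landmark positions,
target-organ spacing, and the topology the landmark detectors rely on
(separate L4/L5 blocks with a detectable interspace, a pelvic ring with
obturator through-holes, femur shafts and heads, a tapering sacrum).

Defaults, chosen once: 360 mm lateral x 240 mm AP body, 300 mm
superior-inferior length, 2.5 mm isotropic grid (256 x 256 x 120). Soft
organs are ellipsoids/cylinders in anatomically plausible positions;
`organ_scale` grows or shrinks all of them together.

Three deliberate couplings give the phantom its clinically meaningful
failure modes:

* **Adiposity vs. skeleton.** Soft-organ *positions* scale linearly with
  the body diameters, but the bony frame scales with their square root:
  skeletal size varies far less than adiposity, so a slim phantom has
  near-normal bones close under the skin. Consequently the bony-landmark
  fields of a slim phantom stay near full size while the body (and the
  bowel cavity inside it) contracts — the bowel ends up more fully inside
  the fields, reproducing the known low-BMI weakness of the box technique.
* **Bowel clearance.** The exclusion gap between the bowel space and the
  targets is proportional to the AP diameter (9%): slim patients have
  less mesenteric fat between bowel and uterus. This is what makes the
  target-to-bowel distance shrink measurably when the diameters shrink.
* **Rectal gas.** `gas_filled_rectum` inserts a gas cylinder of the
  requested diameter (distending the rectum when it exceeds the default
  lumen), which the dose engine treats as non-attenuating, non-depositing
  space with rebuild-up beyond it.

The only randomness is a seeded, +/-2 mm anterior-posterior/
superior-inferior jitter of soft-organ positions. Lateral positions are
never jittered, so the default phantom stays exactly left-right symmetric
— which is also what makes the engine's symmetry property testable to
machine precision. What a green test on this phantom establishes is that
the *algorithms* behave as specified on anatomy with the right relations;
it does not establish performance on real, irregular, asymmetric patient
anatomy, auto-contouring errors excepted by construction.

## The dose surrogate

The engine replaces a clinical dose algorithm with the minimal model the
planning logic needs: per beam,
`dose = dose_per_mu_at_dmax * F(p) * PDD(d)`, where `F` is the aperture
indicator convolved with an isotropic Gaussian penumbra
(`penumbra_sigma = 3` mm) in the BEV plane, and
`PDD(d) = (d/d_max)^2` below the build-up depth, `exp(-mu_lin (d - d_max))`
beyond it, with `d` the water-equivalent depth accumulated through tissue
along the parallel ray. Dose is exactly linear in MU and additive over
beams — the two properties FIF's closed-form transfers rely on.

Two defaults deserve their rationale:

* `mu_lin = 0.003`/mm. A 6 MV *percent-depth-dose* falls about 5%/cm, but
  roughly a third of that is inverse-square divergence, which a parallel
  engine does not have. Using 5%/cm here would double-count divergence and
  make every opposed pair ~15-20% hot at the periphery relative to
  midline, which no transverse (field-in-field) modulation can repair —
  the depth profile of a beam is fixed. The attenuation-only (tissue-
  maximum-ratio-like) 6 MV value of ~3%/cm puts opposed-pair homogeneity
  in the clinically observed few-percent range.
* `d_max = 5` mm. The quadratic build-up shape rises much more slowly
  than real 6 MV build-up (quadratic with a 15 mm peak is at 44% of
  maximum at 10 mm depth, where a real 6 MV beam is already at ~95%).
  The synthetic PTV is the beam-path intersection shrunk by only 7 mm, so
  its surface-near corners sit at 7-17 mm depth: with a 15 mm quadratic
  peak those corners are half-built shells at 20-60% of the prescription,
  and the coverage percentile anchors there instead of in the cross-fire
  minimum, inflating the rest of the volume far above the prescription.
  With `d_max = 5` the quadratic curve matches real 6 MV build-up well in
  the exposed 7-17 mm range and the normalization behaves clinically.

**Gas cavities.** Along a ray, gas accumulates no depth and deposits no
dose; after the ray re-enters tissue, dose re-builds quadratically over
`d_max` (loss of electronic equilibrium beyond an air cavity). Depth
reduction alone would only *increase* dose distal to gas; the rebuild-up
term is what produces the clinically reported coverage loss next to a
gas-filled rectum, and it is the mechanism the gas-phantom test measures
(PTV coverage within 10 mm of the rectum drops by ~15-20 percentage
points).

## Plan construction and normalization

The 4-field box detects its borders on BEV projections of the bones:
superior at the midplane between the lowest L4 and highest L5 voxel
(tie-broken toward inferior — the boundary pixel is excluded); inferior
10 mm below the lowest obturator-foramen pixel, the foramina being the
interior holes of the projected pelvis; lateral at the widest projected
brim +18 mm; anterior 10 mm beyond the pubis; posterior covering the full
projected sacrum. All offsets are `fourfield_params`. A missing or
inverted L4/L5 is a hard, named error — the one failure mode that made a
plan unusable in clinical review.

Initial MU weights the AP/PA fields 3:2 over the laterals. Equal weighting
(the simplest default) leaves the laterals' attenuation across a 36 cm
body imprinted as an irreducible subcutaneous lateral excess of ~15%+;
3:2 is the textbook clinical weighting for pelvic boxes and brings the
intrinsic spread down to the few-percent regime in which a 107% hot-spot
criterion is meaningful. The weights are a configurable argument.

The **region of hot-spot detection (RHD)** is the intersection of the
back-projected beam paths, *clipped to the body*: without the clip, the
rectangular path intersection pokes through the elliptical body surface
into air, and the synthetic PTV (the RHD shrunk 7 mm, mirroring the 7 mm
the 3D-CRT aperture adds around the projected PTV) would contain zero-dose
voxels that make the coverage percentile degenerate. On patient CTs the
clip is implicit in computing paths through the patient.

**Normalization** solves for the scale `s = L*rx / D_p`, with `D_p` the
dose exceeded by exactly the coverage fraction of target voxels (linear
interpolation between sorted voxel doses, voxels counted by centre
inclusion). It is exact, not grid-quantized: after scaling, the fraction
of the target at or above `L*rx` equals the requested coverage to well
under half a percentage point, and renormalizing a normalized plan returns
`s = 1` to 1e-6. Presets: 100%/97% of the synthetic PTV (4-field box),
100%/95% of the PTV (3D-CRT default), 95%/99% (the cooler reviewer
preference). Prescriptions are accepted only in 43.2-50.4 Gy and PTV
margins only in 3-10 mm, enforced wherever a plan is built.

One property the synthetic-PTV construction does *not* reproduce here is
the claim that normalizing 100%/97% on it gives nearly the same
distribution as 100%/95% on the contoured PTV: on this phantom the PTV is
large and central, so it contains the cross-fire minimum that anchors the
synthetic-PTV percentile, and its own coverage under synthetic-PTV
normalization lands near 78% rather than 95%. The agreement reported on
patient anatomy evidently depends on dose shapes this phantom does not
imitate, and the package does not assert it.

## Field-in-field reduction

`fif_reduce` iterates: renormalize (analytically — the running scale is
tracked and folded into the MUs once at the end, so per-angle segment MU
is conserved up to that single factor); detect 26-connected components
above `hot_threshold * rx` larger than `min_hot_volume_cc` (inside the
RHD when the plan is normalized on the synthetic PTV, else inside the
body); take the largest; then place one subfield.

The donor is the parent field contributing the most dose at the spot's
hottest voxel (ties by beam order), with fallback down the ranking. The
subfield blocks the dilated BEV projection of the hot region **minus every
ray that crosses a coverage-critical target voxel** — the boundary layer
within -1%/+2% of the normalization isodose. This protection is what keeps
the loop stable: the percentile that pins the prescription only moves if
target voxels cross the coverage isodose from above, so those rays are
never shadowed, while voxels already well below it (e.g. build-up shells)
may sink freely. It also assigns each hot band automatically to the beams
that can resolve it transversely; a beam can never block its own
entrance/exit band without closing its field, and with this rule it never
tries.

The MU transfer is closed-form from linearity: the smallest amount that
clears the shadowed part of the hot spot, clipped so that (a) no shadowed
target voxel above the coverage isodose is pushed below it (it is parked
at the isodose and joins the protected layer), (b) every segment keeps
`min_segment_mu = 7` MU — new subfields are floored up to 7 MU, and a
transfer that cannot respect the floor falls through to an existing
identical subfield or the next donor. Non-convergence within the
iteration/subfield budgets is a recorded status plus a warning, never an
exception. Decisions on points the original description leaves open:
renormalization happens once at the end (tracked analytically during the
loop); the MU floor applies to parents and subfields alike; the
post-FIF normalization target is always the structure named in the plan's
normalization record.

`suppress_exterior_dose` reuses the same loop for regions above a given
isodose (no volume floor) outside the RHD. In parallel geometry the
opposed pair's own entrance/exit corridors cannot be suppressed — any
blocking pixel closes the field that produces them — so the operation
removes what is geometrically removable (e.g. aperture over-coverage
lobes) and otherwise terminates with a recorded reason.

## Evaluation conventions

`VxGy` counts voxels with dose **at or above** x (conventional DVH
semantics); `Dmax` is the maximum voxel dose, with `metric_dcc` available
for near-maximum quantities; femur metrics pool left and right femur; the
bowel constraint is evaluated on the whole bowel space (the contouring
convention the constraints were written against here), and loop-based
bowel limits are deliberately out of scope. The hard table applies
Dmax < 105% of prescription to bladder, rectum, femurs, spinal cord and
bowel; the soft table carries the EMBRACE II bladder/rectum V40/V30 limits
and the internal-protocol V45 and bowel/femur V40 limits as a separately
labelled rule set. Missing structures mark their rules not-evaluable
rather than silently passing.

## Known limitations

* Parallel geometry: no divergence, oblique angles, collimator or couch
  rotations; apertures are pixel masks, not MLC sequences.
* The dose surrogate has no scatter beyond the penumbra Gaussian, no
  heterogeneity beyond the gas flag, and arbitrary absolute calibration.
* The phantom is schematic and symmetric; results quantify algorithmic
  behaviour, not clinical dosimetry.
* The FIF optimizer is greedy (one subfield per iteration, largest spot
  first); it converges on the geometries tested here but carries no
  global optimality guarantee.
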