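# pelviplan

Automated external-beam treatment planning for cervical cancer, at desk
scale. `pelviplan` re-creates a fully automated planning chain for the two
classic forward-planned pelvic techniques:

* **4-field box** — anterior, posterior and two lateral fields shaped on
  bony landmarks detected in beam's-eye-view (BEV) projections: superior
  border at the L4/L5 interspace, inferior border below the obturator
  foramina, lateral borders at the pelvic brim, anterior border at the
  pubis, posterior border covering the sacrum.
* **3D-CRT** — fields shaped as the projected planning target volume (PTV)
  plus a uniform 7 mm margin, with the PTV built from the clinical target
  volumes by the EMBRACE II image-guided margins (10 mm
  anterior/posterior/superior/inferior, 5 mm lateral) plus a 5 mm setup
  margin.

Around these it implements the supporting machinery a planning system
needs, with every step exposed as an ordinary R function:

* a deterministic, parameterized **synthetic pelvic phantom** (binary
  structure masks on a regular voxel grid) standing in for patient CT
  contours, including a low-BMI mode and a gas-filled rectum flag;
* millimetre-true **mask morphology** (margin expansion/erosion via exact
  Euclidean distance transforms, BEV projection/back-projection,
  26-connected component analysis), with the heavy primitives in compiled
  code;
* a declared, simplified **6 MV photon dose surrogate** (MU-linear,
  additive, quadratic build-up, exponential depth falloff, Gaussian
  penumbra, gas-cavity rebuild-up) in place of a clinical dose algorithm;
* **coverage normalization**: plans are scaled so that the L% isodose of
  the prescription covers p% of a target volume — 100%/97% of the
  "synthetic PTV" (the intersection of all beam paths shrunk by 7 mm) for
  the 4-field box, 100%/95% or 95%/99% of the real PTV for 3D-CRT;
* automated **field-in-field (FIF) hot-spot reduction**: any contiguous
  volume larger than 2 cc above 107% (configurable, e.g. 105%) of the
  prescription is iteratively removed by subfields that block the hot
  region's projection, with a 7 MU floor for every segment and closed-form
  MU transfers;
* **plan evaluation** against EMBRACE II-style constraints (hard:
  Dmax < 105% of the prescription for bladder, rectum, femurs, spinal cord
  and bowel; soft: bladder V40Gy < 75%, V30Gy < 85%, V45Gy < 50%; rectum
  V40Gy < 85%, V30Gy < 95%, V45Gy < 80%; bowel space V40Gy < 30%; femurs
  V40Gy < 15%), plus DVH curves and dose metrics;
* NIfTI mask/dose I/O, JSON plan serialization with run-length-encoded
  apertures, a safety-gated configuration layer (prescription restricted
  to 43.2–50.4 Gy, PTV margin to 0.3–1.0 cm), and a one-call pipeline
  (`run_pipeline()`) with a thin CLI (`inst/cli/pelviplan`).

The methods vignette (`vignettes/pelvic-autoplanning.Rmd`) documents the
model, its assumptions, the phantom's stated world, and all numerical
conventions.

## Worked example

```r
library(pelviplan)

phantom <- generate_phantom(phantom_spec(voxel_spacing = 5))  # 5 mm grid
plan4 <- assemble_fourfield(phantom, rx = 45)
plan4 <- fif_reduce(plan4)
print(plan4)
```

```
<rt_plan> fourfield, rx = 45 Gy, 12 beam(s)
  g000     gantry   0 deg  1579.46 MU
  g090     gantry  90 deg  1100.60 MU
  g180     gantry 180 deg  1575.94 MU
  g270     gantry 270 deg  1020.07 MU
  g000.s1  gantry   0 deg   163.86 MU  (subfield of g000)
  g180.s1  gantry 180 deg   170.15 MU  (subfield of g180)
  ...
  normalized: 100% isodose covers 97% of synthetic_ptv (scale 13.5915)
  target V(45.0 Gy) = 97.1% of 7322.5 cc
  FIF: 8 iteration(s), converged
```

The four open fields (AP/PA weighted 3:2 over the laterals) were
normalized so the full prescription covers 97% of the synthetic PTV; FIF
then moved a few hundred MU per beam into subfields until no contiguous
region larger than 2 cc stayed above 107% of 45 Gy, and the coverage was
restored. Constraint evaluation:

```r
print(embrace_report(plan4$dose, phantom, rx = 45))
```

```
   structure metric  value comparator limit severity         ruleset status
     bladder   Dmax  47.62          < 47.25     hard EMBRACE II hard   FAIL
      rectum   Dmax  46.68          < 47.25     hard EMBRACE II hard   PASS
      femurs   Dmax  45.82          < 47.25     hard EMBRACE II hard   PASS
 spinal_cord   Dmax  46.31          < 47.25     hard EMBRACE II hard   PASS
 bowel_space   Dmax  47.82          < 47.25     hard EMBRACE II hard   FAIL
     bladder  V40Gy 100.00          < 75.00     soft EMBRACE II soft   FAIL
      rectum  V40Gy  76.19          < 85.00     soft EMBRACE II soft   PASS
     ...
```

This is the expected physics of a bony-landmark box technique: the bladder
sits entirely inside the fields, so the soft V40Gy limit (a constraint
written for modulated techniques) fails while the conformal-technique
metrics stay in the clinically reported range. A 3D-CRT plan of the same
phantom (`assemble_crt3d(phantom, rx = 45)`) covers 95% of the PTV with
the full prescription; `renormalize_plan(res, preset = "reviewer2")`
switches to the cooler 95%-isodose/99%-coverage preference.

## Acceptance script

`scripts/acceptance.R` regenerates the package's headline protocol
constants from scratch — it builds the default phantom, assembles and
normalizes both techniques, runs the FIF reduction on a weight-perturbed
plan, and measures the margin geometry on 1 mm grids — and writes the
results as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
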