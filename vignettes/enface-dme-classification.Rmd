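---
title: "Classifying diabetic macular edema from en face OCT slabs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying diabetic macular edema from en face OCT slabs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enfaceDME)
```

## The model

Diabetic macular edema (DME) is graded here by two things at once: *where*
the fluid sits in the retina and *how far* it extends laterally.  Fluid in
DME accumulates in a small number of compartments — the inner nuclear
layer (INL), the outer plexiform layer including Henle's fiber layer, the
outer nuclear layer (ONL), and the subretinal space — while the inner
plexiform layer (IPL) and the retinal pigment epithelium (RPE) are rarely
disrupted.  That makes the IPL/INL boundary and the RPE reliable reference
planes for flattening a 3D OCT volume, and two standard en face slabs
capture the compartments of interest:

* **Segment 1** — flatten along the IPL/INL boundary and project a 50 µm
  slab downward.  The INL is 33–40 µm thick, so 50 µm covers the INL plus
  the top of the OPL/Henle complex.
* **Segment 2** — flatten along the RPE, move the line 70 µm toward the
  vitreous (the RPE-to-ELM distance is 60–80 µm) to set the inferior
  boundary, and project the 50 µm above it.  This is essentially the ONL.

On these slabs fluid appears as well-demarcated low-intensity regions.
Segment-1 fluid is graded against the ETDRS circles centred at the fovea:
**FC** (foveal cystoid space) if every fluid pixel lies within the 1 mm
foveal circle, **PC** (parafoveal cystoid space) if it stays within the
3 mm parafoveal circle, **DF** (diffuse fluid) beyond that, **NF** for no
fluid.  Segment 2 is reduced to fluid presence/absence — whenever it has
fluid at all, the fluid exceeds the parafoveal circle — and subretinal
fluid (**SF**) is assessed separately.  Crossing 4 Segment-1 states with 4
Segment-2 states (NF, DF, SF, DF + SF) and removing the all-no-fluid cell
gives 15 combination labels (`taxonomy_labels()`), of which five occur in
practice (`observed_types()`): FC/NF, PC/NF, PC/DF, DF/DF, DF/DF + SF.
The cross-product count is our resolution of an ambiguity in how the
taxonomy is usually tabulated; the five observed types are unaffected by
it.

```{r taxonomy}
length(taxonomy_labels())
observed_types()
```

## The pipeline

`classify_eye()` runs: surface segmentation → flattening → standard slab
projection → fluid detection → ETDRS extent grading → taxonomy label.
Every stage is exported and usable on its own.

### Surface segmentation

`segment_surfaces()` is a transparent per-A-scan rule set adequate for
layered macular volumes (it deliberately does not attempt to be a clinical
segmenter, and vendor boundary algorithms are typically proprietary
anyway):

* ILM: first raw voxel above a reflectivity floor (default 0.045) —
  vitreous is far darker than every tissue structure, including the
  hyporeflective troughs of traction folds;
* RPE: start of the deepest bright run on a 3×3×3 box-smoothed channel
  (threshold 0.65);
* ellipsoid zone (EZ): centre of the bright run immediately above the RPE
  run; A-scans without one (true EZ loss) are interpolated from
  neighbours and counted in the `n_interpolated` attribute;
* IPL/INL: the earliest of several falling-edge candidates below the ILM.
  The laterally smoothed gradient is robust under speckle; an absolute
  mid-level crossing and (on low-noise volumes) a sharp axial-only
  gradient plus a strict local-minimum rule resolve the foveal pit, where
  the INL pinches to a single voxel between brighter bands.

Per-A-scan estimates are compared with their 7×7 median-smoothed
neighbourhood; an estimate that deviates by more than a veto distance
(50 µm on low-noise volumes, 10 µm under speckle, with the noise level
estimated from the axial high-pass residual of bright voxels) is replaced
by the neighbourhood value.  The loose/tight switch exists because the two
regimes fail differently: noise-free errors come from median lag at the
steeply bent pit (so trust the A-scan), speckle errors come from
early-triggering gradients (so trust the neighbourhood).  Two structural
safeguards matter on membrane-laden volumes: a falling edge only
qualifies as the IPL/INL if it lands in a hyporeflective band (the
membrane→inner-retina drop is steep but lands bright), and a final
wide-window (15×15) consistency pass removes the narrow column-streaks
that fold troughs can imprint on the map — genuine surface bends vary by
well under its 30 µm allowance across 15 A-scans.

### Slabs, projection and numerical conventions

All depths are carried in micrometres and converted to voxels only at
sampling time.  Voxel `z` spans `[(z-1)Δ, zΔ)`; a depth maps to the voxel
whose *centre* is nearest, with ties resolved toward the vitreous.  A
reported boundary is the centre of the first voxel of the deeper band,
which keeps `flatten()` + `make_enface()` sampling tissue rather than the
vitreous when a surface falls on a voxel boundary.  The slab
`[reference + offset, reference + offset + depth)` projects
`max(1, round(depth/Δ))` voxel planes; `depth = 0` selects the single
plane nearest the reference.  The projection operator is the mean over
in-range voxels (the vendor operator behind the published images is
unpublished; `min`/`max` are available in `slab_spec()` for sensitivity
checks).  Mean projection is linear and additive over voxel-aligned slab
partitions, and it is tested against a brute-force per-pixel loop.

### Fluid detection

`detect_fluid()` thresholds at half the slab median by default.  The rule
is scale-free and works because fluid (reflectivity ≈ 0.05 on the
phantoms) is far below any tissue mixture a 50 µm slab can produce; Otsu
thresholding is available as an alternative.  A one-pixel morphological
closing bridges quantization gaps, and components smaller than 0.01 mm²
(a ~110 µm spot) are discarded as speckle — the visual grading this
replaces had no explicit size floor, so the floor is a parameter.  The
median rule assumes fluid covers less than half the frame; on a 6×6 mm
scan even diffuse fluid beyond the parafovea covers ~40%, but pathologies
filling most of the frame would need the Otsu mode.

Subretinal fluid is decided volumetrically in a third slab, the 70 µm
band directly above the RPE (`standard_slabs()$subretinal`): that band is
normally filled by the bright photoreceptor complex, so any low-intensity
component of at least 0.05 mm² there is SF.  On the Segment-2 slab the
same blister instead produces the characteristic bright ring — an
appearance we treat as a consequence, not a detection rule, because ring
recognition is brittle.

### Biomarkers

* `central_subfield_thickness()`: mean ILM→RPE distance over A-scans
  within the foveal circle.  The outer boundary is the RPE (automated
  thickness maps conventionally use RPE/Bruch's; the phantom RPE is a
  single surface).
* `ez_disruption()`: on the horizontal and vertical B-scans through the
  fovea, within ±1.5 mm, the mean reflectivity in a ±10 µm band around
  the EZ surface is compared with a floor of 0.5 (intact band ≈ 0.9,
  nuclear layers ≈ 0.25); a contiguous dark run of ≥ 50 µm on either scan
  counts as disruption.  The 50 µm floor replaces a visual judgment and
  is exposed as a parameter.
* `detect_erm()`: on the retinal-surface plane, membrane present when
  pixels above 1.5× the image median cover ≥ 2% of the frame
  (median-relative, hence invariant to global intensity scaling).
* `max_depth_retinal_folds()` (MDRF): sample planes below the ILM every
  10 µm; folds are dark elongated components (eccentricity ≥ 0.9,
  ≥ 0.05 mm²); the measurement is the deepest plane on which folds are
  still seen — the depth just before the deepest fold disappears.  With a
  10 µm step the estimate sits within one step of the true vanishing
  depth.
* `decimal_to_logmar()`: logMAR = −log10(decimal acuity).

### Cohort statistics

The statistics module mirrors the analysis plan used for this kind of
cohort: χ² tests of independence (Pearson, no continuity correction) for
the categorical rows, one-way ANOVA for age/HbA1c/CST/MDRF,
Kruskal–Wallis for BCVA, Student's t (Welch available) for the pooled
two-group comparison by Segment-2 fluid, and logistic regression (IRLS
via `glm`, Wald 95% CIs, separation flagged) for EZ disruption.  No
multiple-testing correction is applied, matching the plan it reproduces.
`pooled_proportion()` and `pooled_mean_sd()` reproduce computation on
concatenated raw data exactly.  When the edema classification enters the
regression as a predictor it is encoded ordinally 1–5 in progression
order; a single published odds ratio for "classification" implies an
ordinal coding, but this is an assumption and is stated as such.

## The synthetic phantom

No public volumes exist for this task, so `generate_phantom()` renders
parameterized macular volumes with exact ground truth.  What it emulates:

* flat RPE with bands built upward: photoreceptor complex (ELM at
  RPE − 70 µm, a bright EZ band at RPE − 45 ± 10 µm), ONL (70 µm),
  OPL/Henle (35 µm), INL (35 µm), inner retinal complex (100 µm), each
  with representative reflectivities (nuclear ≈ 0.25, plexiform ≈ 0.55,
  EZ/RPE ≈ 0.9, fluid ≈ 0.05);
* a Gaussian foveal pit (σ = 0.35 mm) thinning the inner complex by 90%
  and the INL by 85% at its centre — pit geometry is a modeling choice,
  fixed once;
* fluid pockets per compartment: steep-walled cylinders for cystoid
  spaces (so the painted lateral extent is exact) and band-filling disks
  for diffuse sheets;
* subretinal fluid as a plateau blister with a short cosine taper over
  the outer 5% of its radius, lifting the whole neurosensory retina — a
  smooth dome would make the painted lateral extent ill-defined for the
  area-recovery checks, and the lifted bright bands reproduce the ring
  appearance on Segment 2;
* an adherent hyperreflective membrane over irregular patches (the truth
  ILM includes it, as any surface tracker would) plus traction folds
  rendered as hyporeflective clefts from the ILM down to a sharp
  vanishing depth — that depth is the ground-truth MDRF.  Folds are
  suppressed within 0.9 mm of the fovea, where the thin inner retina
  could not host them.  We deliberately render the folds in the intensity
  domain rather than as geometric sinusoidal corrugation: corrugation
  would make MDRF recovery hinge on sub-voxel ILM accuracy, conflating
  generator realism with segmentation error, while the clefts give
  exactly the en face dark-line signature the measurement is defined on;
* an optional ellipsoid-zone gap (disk where the EZ band is erased);
* multiplicative gamma speckle (`shape = 1/amplitude²`, default
  amplitude 0.15 — no published noise model exists for the target
  device, and 0.15 gives bands that visually flirt with each other
  without merging).

Defaults: 6×6 mm, 128×128 A-scans, 5 µm axial sampling over 1500 µm.
Axial sampling is configurable; 5 µm makes the 50 µm slabs 10 voxels
deep.  `preset_cohort()` draws randomized phantoms of the five observed
types within their extent constraints (e.g. parafoveal rings of paired
INL+Henle cysts reaching at most 1.3 mm; diffuse sheets of radius
1.6–2.2 mm) and decorates them with ERM, EZ gaps and incomplete PVD at
the per-type rates of the reference cohort.

What the phantom does **not** emulate: vascular shadows, hyperreflective
foci, motion artifacts, realistic speckle correlation, drusen, or an
optic disc (so incomplete PVD is carried as a label, never detected).
Passing the recovery suites therefore demonstrates that the pipeline's
geometry, thresholds and bookkeeping are correct — not that it would
grade real pathology at clinical accuracy.

```{r example, eval = FALSE}
ph <- generate_phantom(preset_spec("DF/DF + SF", speckle = 0.15, seed = 7))
res <- classify_eye(ph$volume)
res$classification$label   # "DF/DF + SF"
measure_biomarkers(ph$volume)
```

## Validation choices and problem sizes

The test suite exercises unit behaviour on 64×64 phantoms (94 µm lateral
pixels) and the end-to-end recovery claims at the 128×128 default:
surfaces within one axial voxel noise-free, median within two voxels
under speckle, CST within one axial voxel, MDRF within one depth step,
all five noise-free presets classified correctly, and at least 90% label
recovery on a 50-phantom speckled cohort.  `scripts/acceptance.R`
recomputes the same quantities from scratch together with the pooled
cohort statistics.

## Known limitations

* The IPL/INL rule stands in for an unreleased vendor algorithm; on real
  scans its absolute placement would need validation.
* Whether the published Segment-2 slab is measured upward from the
  shifted line or centred on it is not stated; we take the sentence
  literally (inferior boundary at RPE − 70 µm, slab above it).
* The median-threshold fluid detector assumes fluid occupies less than
  half the frame.
* Eyes contributing two volumes are treated as independent in the
  statistics module, as in the analysis plan it mirrors.
* Segment-2 images of real eyes can show outward extension of Henle-layer
  fluid or shadowing from inner-retinal lesions; no disambiguation rule
  exists and none is modeled.
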