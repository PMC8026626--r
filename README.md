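# enfaceDME

Classification of diabetic macular edema (DME) from en face OCT slab
images, with structural biomarkers and cohort statistics.

DME is the leading cause of visual loss in diabetic retinopathy, and how
it should be graded depends on two properties that B-scan-based schemes
struggle to capture at once: **where** the fluid sits (INL and OPL/Henle,
the ONL, or the subretinal space) and **how far** it extends laterally.
This package implements a depth-resolved en face approach for researchers
working with 3D macular swept-source OCT volumes: flatten the volume
along a retinal boundary, project thin slabs, detect fluid as
well-demarcated low-intensity regions, and grade its extent against the
ETDRS grid.

The core constructs are two standard slabs:

* **Segment 1** — IPL/INL reference plane, 50 µm scan depth: the inner
  nuclear layer plus the outer plexiform layer including Henle's fiber
  layer;
* **Segment 2** — RPE reference moved 70 µm toward the vitreous as the
  inferior boundary, 50 µm scan depth above it: the outer nuclear layer.

Segment-1 fluid is graded FC / PC / DF (foveal cystoid space within the
1 mm ETDRS circle; parafoveal within the 3 mm circle; diffuse beyond),
Segment 2 for fluid presence, and subretinal fluid (SF) volumetrically in
the 70 µm band above the RPE.  The cross product yields 15 combination
labels, five of which occur in practice:
`FC/NF, PC/NF, PC/DF, DF/DF, DF/DF + SF`.

Because no public volumes exist for this task, the package ships a
synthetic macular phantom generator (`generate_phantom()`,
`preset_cohort()`) producing layered volumes with exact ground-truth
surfaces, fluid masks, biomarkers and type labels, used throughout the
test suite.  Biomarkers: central subfield thickness (CST), ellipsoid-zone
(EZ) disruption, epiretinal membrane (ERM) and maximum depth of retinal
folds (MDRF).  The statistics module reproduces the cohort comparisons
such data support (χ², one-way ANOVA, Kruskal–Wallis, Student's t,
logistic regression on EZ disruption, pooled proportions and pooled
mean ± SD).

## Worked example

Generate a randomized phantom of the most advanced observed type and
classify it end to end:

```r
library(enfaceDME)

ph  <- generate_phantom(preset_spec("DF/DF + SF", speckle = 0.15, seed = 7))
res <- classify_eye(ph$volume)
res$classification
#> <dme_classification> DF/DF + SF
sprintf("Segment 1 fluid area: %.2f mm^2", res$provenance$segment1_area_mm2)
#> [1] "Segment 1 fluid area: 8.38 mm^2"
sprintf("SRF area: %.2f mm^2", res$provenance$srf_area_mm2)
#> [1] "SRF area: 2.39 mm^2"

bm <- measure_biomarkers(ph$volume)
sprintf("CST %.1f um | EZ disrupted %s | ERM %s | MDRF %s um",
        bm$cst_um, bm$ez_disrupted, bm$erm_present, bm$mdrf_um)
#> [1] "CST 319.3 um | EZ disrupted TRUE | ERM TRUE | MDRF 30 um"
```

The classifier recovered the phantom's ground-truth label
(`ph$truth$type_label` is `"DF/DF + SF"`); the detected Segment-1 fluid
is diffuse (8.38 mm², extending past the 3 mm parafoveal circle), the subretinal
blister is found volumetrically, and the fold measurement (30 µm) sits
within one 10 µm depth step of the generated fold depth (32.7 µm).

Summary-level cohort statistics work directly from published-style group
tables:

```r
pooled_mean_sd(data.frame(n = c(24, 25), mean = c(304.4, 385.2),
                          sd = c(42.7, 80.4)))
#> $n 49; $mean 345.62; $sd 75.97   (CST, eyes without Segment-2 fluid)
pooled_proportion(list(c(0, 24), c(5, 25)))
#> [1] 0.1020408                    (EZ disruption rate, same group)
```

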