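Package: enfaceDME
Title: En Face OCT Slab Imaging and Classification of Diabetic Macular Edema
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds depth-resolved en face slab images from 3D macular
    optical coherence tomography (OCT) volumes, detects intraretinal and
    subretinal fluid as well-demarcated low-intensity regions, and
    classifies diabetic macular edema by the localization and extent of
    the fluid against the ETDRS grid (foveal cystoid space, parafoveal
    cystoid space, diffuse fluid, with or without subretinal fluid).
    Extracts structural biomarkers (central subfield thickness,
    ellipsoid-zone disruption, epiretinal membrane, maximum depth of
    retinal folds) and provides the cohort statistics used to compare
    edema types.  Includes a parameterized synthetic macular phantom
    generator with exact ground-truth surfaces, fluid masks and type
    labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
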