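Package: simplifiedIVIM
Title: Simplified Intravoxel Incoherent Motion Mapping and Two-Colour
    Index Maps for Liver Lesion Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-wise estimation of the simplified intravoxel
    incoherent motion (IVIM) parameters D' and f' and the apparent
    diffusion coefficient (ADC) from three-b-value diffusion-weighted
    MRI, construction of binary two-colour (red/green) index maps and
    their combination, ROI-based percent-red scoring, and an
    ROC/Youden/DeLong/ICC evaluation pipeline for deriving and
    validating malignancy cutoffs. Includes a synthetic liver DWI
    phantom generator with a biexponential IVIM forward model and
    Rician noise so the complete workflow is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    jsonlite,
    yaml,
    png
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'phantom.R'
    'cohort.R'
    'ivim-maps.R'
    'index-maps.R'
    'roi-analysis.R'
    'eval-stats.R'
    'io.R'
    'pipeline.R'
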