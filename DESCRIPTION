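Package: crossmodal
Title: Cross-Modal Spatial Analysis of Hyperpolarized 13C MRI and Metabolic PET Brain Maps
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating volumetric brain maps acquired with different
    modalities, built around the workflow used to compare hyperpolarized
    [1-13C]pyruvate MRI metabolite maps (pyruvate, lactate, bicarbonate) with
    metabolic PET maps (CMRglc, CBF, CMRO2, CBV and derived OEF and glycolytic
    index). Provides temporal integration of dynamic series into sum images,
    whole-brain-mean normalization, group medians, mask-aware Gaussian
    smoothing with empirical FWHM selection, spatial-regression residual maps
    (GI, LBR, LPR, BPR), parcel-level summaries, Spearman correlation with
    spin-permutation inference and Benjamini-Hochberg FDR control, and
    two-block canonical-mode partial least squares. Includes a synthetic
    multi-subject data generator with known latent spatial structure so the
    full pipeline can be exercised against ground truth, plus minimal NIfTI-1
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
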