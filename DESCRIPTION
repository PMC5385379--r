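Package: endoprofile
Title: Endothelial Function and Permeability Profiling from MRI and Plasma Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for in-vivo endothelial profiling in mouse
    models of atherosclerosis. Quantifies acetylcholine-induced changes in
    end-diastolic brachiocephalic artery volume from cine gradient-echo MRI
    (threshold segmentation, slice-wise volumetry), estimates per-pixel T1 by
    the variable flip angle method from spoiled gradient-echo series, and
    derives the Npx50 endothelial permeability statistic (count of
    perivascular pixels whose T1 changed by more than 50 percent after an
    albumin-binding contrast agent). Includes a synthetic phantom and plasma
    cohort generator with known ground truth, renin-angiotensin and
    L-arginine/ADMA panel analysis with group comparisons
    (Kruskal-Wallis/Dunn, ANOVA/Tukey) and function-biochemistry
    correlations, plus NIfTI/CSV/YAML input-output and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
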