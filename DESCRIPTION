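Package: petrad
Title: PET Radiomic Texture Features and Tumor-to-Normal Uptake Ratio Modeling
Version: 0.1.0
Authors@R:
    person("petrad", "authors", email = "petrad@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of 3D PET volumes of brain tumors:
    NIfTI voxel-grid input/output, gray-level discretization (equal-size and
    equal-probability schemes), first-order, co-occurrence (GLCM), run-length
    (GLRLM) and geometric/fractal texture features, tumor-to-normal brain
    uptake ratio (TNR) quantification from the hottest 1 cubic centimeter,
    and a repeated-split LASSO stability-selection protocol linking texture
    to log10(TNR). Includes a synthetic phantom and cohort generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
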