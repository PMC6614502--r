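Package: blankqc
Title: Assessment of UPLC-MS System Conditioning After Blank Injections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-acquisition quality assessment of untargeted UPLC-MS
    metabolomic batches that interleave extraction blanks with sample
    injections. Implements within-batch signal-drift correction by
    quality-control-based support vector regression (QC-SVRC) with
    leave-one-out hyperparameter selection, blank-based feature screening
    into informative, contaminant and column carry-over classes, guided
    principal component analysis with the delta statistic and a
    permutation test to quantify system reconditioning after a blank,
    univariate Welch t-test counts for peak area, retention time and peak
    width, and hierarchical clustering of deconditioning response
    profiles. A synthetic batch generator with planted ground truth
    emulates the cyclic blank/sample designs used to study column
    deconditioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
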