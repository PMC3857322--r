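Package: reliacase
Title: Reliability-Masked Single-Case Analysis of Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-case diagnostic pipeline for task fMRI contrast maps.
    Builds voxelwise test-retest reliability maps using the two-way random
    single-measures intraclass correlation ICC(2,1), combines them across
    tasks with Fisher's z transform, and restricts all inference to a
    reliability mask.  Provides first-level block-design GLM fitting with
    AR(1) prewhitening and motion confounds, second-level one- and two-sample
    t maps with Monte-Carlo cluster-extent correction, voxelwise Crawford
    tests comparing one case against a control sample with
    frequency-of-deviation maps, exhaustive power-set region-of-interest
    classification with leave-one-out linear support vector machines, and
    complete-linkage hierarchical clustering of subjects on Spearman
    correlations.  Includes a synthetic-data generator that emulates
    self-paced block designs and test-retest beta-map studies with planted
    reliability fields and localized group effects, so the whole pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
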