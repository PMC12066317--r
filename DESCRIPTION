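Package: dbsmap
Title: Mapping Deep Brain Stimulation Outcomes to Stimulation Sites and
    Fiber Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for subthalamic deep brain stimulation
    (DBS) outcome mapping. Estimates volumes of tissue activated (VTA)
    around active electrode contacts with an analytic point-source field
    model thresholded at an electric-field magnitude, quantifies VTA
    overlap with atlas-defined nucleus subregions, maps voxel-wise
    "sweet" and "sour" spots for changes in clinical scale scores using
    Wilcoxon signed-rank tests with false-discovery-rate correction,
    scores tractogram streamlines by a two-sample fiber T-score
    contrasting outcomes of connected versus unconnected patients, and
    validates both models by leave-one-out and k-fold cross-validation.
    Includes a synthetic cohort generator with planted ground truth
    (sweet-spot sphere and signed tract effects) so every stage has a
    recoverable answer, plus readers and writers for NIfTI volumes,
    TCK/TRK tractograms and cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
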