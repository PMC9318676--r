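Package: thickshot
Title: Two-Dimensional Thickness Encoding and Few-Shot Subspace
    Classification of Cardiac Segmentation Maps
Version: 0.1.0
Authors@R:
    person("thickshot", "maintainers", email = "maintainers@thickshot.dev",
           role = c("aut", "cre"))
Description: Tools for diagnosing cardiomyopathy morphology groups from
    short-axis cardiac segmentation maps alone.  Multi-slice end-diastole
    and end-systole label maps (background, right ventricle, myocardium,
    left ventricle) are collapsed into a single 128 x 64 x 3 per-patient
    "thickness image" in which per-slice intensities summing to 255
    accumulate per structure channel, and the resulting images are
    classified with an episodically trained few-shot model that scores
    queries by their residual distance to adaptive class subspaces built
    from support features, regularised by the Grassmannian projection
    metric between class subspaces.  Includes a synthetic generator for
    the five morphology groups (DCM, HCM, MINF, NOR, ARV), segmentation
    pre/post-processing utilities, the Jaccard loss, NIfTI and PNG
    round-trip I/O, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
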