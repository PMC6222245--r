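Package: seegplan
Title: Experience-Based Planning of SEEG Electrode Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines retrospective stereoelectroencephalography (SEEG)
    implantation plans into a reusable model of a clinical centre's practice.
    Electrode trajectories are classified by the atlas zones they enter and
    target, pooled across patients into exploratory patterns in an average
    brain space, and compressed into mean trajectories by an iterative
    k-means procedure with a cluster-significance rule. Whole plans are then
    encoded as binary presence vectors over the mean-trajectory set and
    grouped into planning strategies by hierarchical clustering under the
    Jaccard distance. A selected strategy can be mapped through a subject's
    affine registration to initialise a new plan, and mapped trajectories are
    validated against manual ones with a two-standard-deviation criterion.
    Includes a synthetic-cohort simulator with known ground truth, simple
    safety metrics (insertion angle, vessel clearance), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
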