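Package: netabnorm
Title: Structural Connectome Abnormality Mapping with Network-Based
    Statistics
Version: 0.1.0
Authors@R:
    person("Connectome", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-brain structural network abnormality analysis for
    case-control diffusion-MRI connectome studies.  Implements
    network-based statistics (edgewise t-scores, suprathreshold
    connected components, permutation null distributions, threshold
    sweeps), per-subject normative z-scoring of connections against a
    control cohort with node abnormality and abnormality load at
    whole-brain, lobe, and region resolution, and estimation statistics
    (Cohen's d, AUROC, BCa bootstrap confidence intervals, rank tests,
    Benjamini-Hochberg correction).  Ships a synthetic connectome-cohort
    generator with ground truth so every stage of the pipeline can be
    validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
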