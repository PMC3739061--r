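Package: brainmod
Title: Modular Reorganization Analysis of Resting-State Brain Networks
Version: 0.1.0
Authors@R: person("brainmod", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Builds per-subject functional connectivity networks from
    region-averaged resting-state time series, combines them into a group
    network (entrywise mean over standard deviation, positive-masked),
    detects modules by Newman's spectral (leading-eigenvector) modularity
    maximization with Kernighan-Lin style refinement, compares modularity
    against degree-preserving random null networks, maps module
    reorganization between groups, flags homotopic (left-right mirror)
    region pairs whose members separate into different modules, and
    computes interhemispheric (index A) and intrahemispheric (index B)
    connectivity biomarkers together with gray-matter-concentration
    adjustment and ROC/AUC classification. Ships a synthetic cohort
    generator with planted modular covariance and group contrasts so the
    whole pipeline is testable without human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
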