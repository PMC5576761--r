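Package: screenrep
Title: Replicability Analysis Across Multiple Studies with Local FDR Control
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects k-replicable associations across a genes-by-studies
    matrix of p-values or z-scores under empirical Bayes local false
    discovery rate control. Fits a two-groups model per study, computes the
    exact partial-conjunction local fdr under independence by dynamic
    programming, estimates a prior over binary study configurations by
    (restricted) EM with a proven fdr upper bound, clusters studies via a
    bootstrapped configuration-space correlation network, and merges
    per-cluster non-null-count posteriors across independent clusters
    (the SCREEN pipeline). Includes Fisher meta-analysis, BH-count and
    expected-count baselines, simulation generators with known ground
    truth, and evaluation utilities (FDP, Jaccard, direction calls).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, igraph
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
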