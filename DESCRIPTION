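Package: flyfitness
Title: Leslie-Matrix Fitness Analysis for Gnotobiotic Drosophila Vial Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating host fitness from vial-level fecundity and
    survival records of gnotobiotic Drosophila melanogaster cultures. Each
    vial's twice-weekly pupae counts and interval mortality are assembled
    into an age-structured Leslie matrix whose dominant eigenvalue (lambda)
    is the vial's fitness, with an independent Euler-Lotka root-finding
    cross-check. Includes an age-class perturbation engine that rescales
    survival or fecundity of chosen age classes and recomputes lambda,
    nonparametric treatment comparisons (Kruskal-Wallis, Dunn post hoc with
    Benjamini-Hochberg correction, pairwise log-rank, compact letter
    displays), a metagenome-wide association stage that collapses an
    ortholog-group presence/absence matrix into phylogenetic distribution
    groups and tests each against fitness with a linear mixed model, and a
    synthetic-data generator reproducing the statistical structure of the
    vial assay design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    survival,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
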