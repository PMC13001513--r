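Package: evoltraj
Title: Allele-Frequency Trajectory Analysis for Reciprocal Selection Pool-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evolve-and-resequence (E&R) studies in which replicate
    populations are shifted between antiparallel selection regimes and tracked
    with pooled whole-genome sequencing. Reads and filters PoPoolation2 sync
    files and SNP count tables; fits per-locus beta-binomial generalized
    linear mixed models of minor-allele counts with trajectory, generation and
    interaction effects and a replicate random intercept; summarises
    genome-wide structure with scaled-uncentered PCA and per-component mixed
    models; tracks expected heterozygosity through time; tests pseudo-fixed
    sites for hidden low-frequency variation against deep-sequencing data with
    a permutation null; scans for evolved-versus-founder convergence with
    overdispersed binomial models; and quantifies replicate-level parallelism
    with a leave-one-out target/control framework. A forward Wright-Fisher
    Pool-seq simulator with antagonistic-pleiotropy style balanced loci
    provides ground-truthed synthetic data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    glmmTMB,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
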