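Package: cernet
Title: Screening Competing Endogenous RNA Networks from Paired Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to screen lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    regulatory networks from paired tumor/normal expression profiles. Implements
    quantile normalization, paired differential-expression screening with
    fold-change and p-value thresholds, candidate lncRNA filtering, hypergeometric
    over-representation analysis against user-supplied gene sets,
    partial-correlation ceRNA triplet inference restricted by 6-mer miRNA seed
    matches, miRNA-mediated interaction (MMI) network assembly with SIF/GraphML
    export, Kaplan-Meier/log-rank survival screening, cohort summarization and
    qRT-PCR relative quantification. A synthetic-data module generates paired
    cohorts with planted fold changes, planted ceRNA triplets driven by latent
    miRNA activity, planted seed sites and group-dependent survival hazards, so
    every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    multcomp,
    igraph,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
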