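Package: packped
Title: Pedigree, Relatedness, and Mate-Choice Inference from Noninvasive
    Microsatellite Genotypes in Group-Living Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring socially structured (pack-living) wildlife
    populations from noninvasive genetic samples. Turns replicate PCR allele
    calls at codominant microsatellite loci into consensus genotypes, merges
    samples into unique individuals under an allelic-dropout-tolerant matching
    rule, reconstructs pedigrees by trio maximum likelihood with an explicit
    dropout/false-allele error model (with mismatch-tolerant exclusion as a
    fallback and reconstruction of unsampled "sneaker" sires), estimates
    pairwise relatedness (Queller-Goodnight moment and dyadic maximum
    likelihood over IBD modes), builds random-mating resampling nulls for
    mated-pair relatedness, derives pair-bond histories, genotype-recapture
    harvest rates and apparent pup survival, and fits the associated fixed and
    mixed-effects logistic regression models. A synthetic-data generator
    emulates multi-year pack pedigrees, summer fecal sampling with replicate
    PCRs, and fall/winter harvest sampling so that every stage of the pipeline
    can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
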