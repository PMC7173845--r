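Package: admixscan
Title: Admixture Mapping of Blood Pressure Phenotypes in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Local-ancestry association (admixture mapping) of blood-pressure
    phenotypes in recently admixed cohorts, such as African Americans, using
    the global-minus-local ancestry parameterization. Provides marker-level
    quality control (Hardy-Weinberg exact test, minor-allele-frequency and
    call-rate filters, depth-aware LD pruning), phenotype construction
    (antihypertensive medication adjustment, mean arterial pressure, log10
    systolic blood pressure), effective-number-of-tests significance
    thresholds from the spectral density at frequency zero of autoregressive
    models fitted to local ancestry, peak-region extraction by one-LOD drop,
    regional fine-mapping restricted to ancestry-differentiated SNPs with
    principal-component adjustment, conditional admixture scans to test
    whether candidate SNPs mediate ancestry signals, and local-ancestry
    stratified genotypic tests combined by DerSimonian-Laird random-effects
    meta-analysis. Includes a generative simulator of admixed cohorts
    (Markov ancestry tracts along a genetic map, ancestry-conditional
    genotypes, blood-pressure phenotypes) so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    rlang,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    coda,
    metafor,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'AdmixtureExperiment.R'
    'utils.R'
    'config.R'
    'simulate.R'
    'io-vcf.R'
    'io-tables.R'
    'qc.R'
    'phenotypes.R'
    'ancestry.R'
    'meff.R'
    'scan.R'
    'regional.R'
    'pipeline.R'
    'admixscan-package.R'
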