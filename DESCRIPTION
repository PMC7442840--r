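Package: coregreml
Title: Variance Partitioning with Covariance Between Random Effects (CORE GREML)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear mixed-model variance partitioning for complex traits that
    estimates, rather than assumes away, the covariance between random effects.
    Relationship kernels (genomic, transcriptomic, functional-region) enter the
    phenotypic covariance together with symmetrized Cholesky-root cross-terms
    that each carry a free covariance parameter; all parameters are fitted by
    average-information REML. Includes delta-method standard errors for
    heritability and effect correlations, likelihood-ratio and Wald tests,
    covariance-aware BLUP with k-fold cross-validation, a synthetic-data
    generator (genotypes with local LD, imputed-transcriptome proxies,
    phenotypes from multi-kernel models), replicate study drivers for type-I
    error and bias experiments, and readers/writers for PLINK BED/BIM/FAM and
    GCTA GRM binary formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
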