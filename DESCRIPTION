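Package: breedkit
Title: Breed-Informative SNP Panels, Genomic Breed Composition and
    Conservation Genetics for Livestock
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genetic evaluation of livestock conservation
    populations from diploid biallelic SNP genotypes: design of
    breed-discriminating SNP panels by the delta-MAF criterion with uniform
    chromosomal coverage, supervised-admixture estimation of genomic breed
    composition (GBC) against a multi-breed reference with purity calling,
    PLINK-style quality control including an exact Hardy-Weinberg test,
    per-population diversity statistics (MAF, Ho, He, Pi, Pn, PIC), runs of
    homozygosity and the F_ROH genomic inbreeding coefficient, linkage
    disequilibrium decay, principal component analysis, and IBS-based
    molecular-family clustering with purebred mate selection. Includes a
    Balding-Nichols multi-breed genotype simulator with admixture, implanted
    autozygous tracts, linkage disequilibrium and family structure, plus
    PLINK bed/bim/fam and VCF readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    randomForest,
    nnet,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
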