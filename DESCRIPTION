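Package: ddradpop
Title: Double-Digest RAD Enzyme Selection and Population Genomic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for double-digest RAD (ddRAD) study design and downstream
    population genomics of diploid biallelic SNP data. Simulates double
    restriction digestion of a genome to rank enzyme pairs by the number of
    size-selectable fragments; loads and quality-filters SNP genotype
    matrices from VCF (call rate, minor allele frequency); computes
    heterozygosity, pairwise Fst with permutation tests, and hierarchical
    AMOVA variance components; infers population structure by genotype PCA
    and maximum-likelihood admixture EM with cross-validated choice of the
    number of clusters; and builds minimum spanning networks and NeighborNet
    split networks from genetic distance matrices. Includes a synthetic-data
    generator (Balding-Nichols genotypes, genomes with planted restriction
    sites) with exposed ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    ape,
    pracma,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    vegan,
    cluster,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
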