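Package: ParalogModes
Title: Classification of Gene Duplication Modes and Divergence of Duplicate Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies homologous gene pairs within a genome into six modes of
    origin (whole-genome duplication, tandem, proximal, retrotransposed,
    DNA-transposed, dispersed) by chaining homology hits into collinear blocks in
    gene-rank space, applying rank-difference rules for local duplicates, and
    using outgroup synteny to separate transposed copies from their parents at
    ancestral loci. Quantifies divergence between duplicate copies: Ka/Ks under
    the Nei-Gojobori (1986) pathway-counting estimator with Jukes-Cantor
    correction, Ks-distribution decomposition by a two-component Gaussian mixture
    on log-Ks, expression divergence by Pearson correlation of TPM profiles
    against a resampling null, promoter (regulatory) divergence by shared-motif
    coverage, and whole-gene conversion by outgroup quartets with codon
    bootstrap support. A synthetic-genome simulator plants all six duplication
    modes with known truth so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
biocViews: Genetics, ComparativeGenomics, Phylogenetics, WholeGenome, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
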