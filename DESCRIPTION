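Package: osnseq
Title: Hierarchical Deconstruction of Olfactory Sensory Neuron Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to re-analyse single olfactory sensory neuron (OSN)
    RNA-seq count data: median-of-ratios normalization, hierarchical
    single-cell quality control, two-component Gaussian-mixture
    deconvolution of olfactory receptor (OR) abundance with intersection
    thresholding to call monogenic receptor expression, allele-specific
    expression from strain-discriminating SNP read counts, negative-binomial
    differential expression with Benjamini-Hochberg FDR control, variable
    gene detection by coefficient of variation, exhaustive pairwise
    unique-coexpression cell-type discovery, and a PC1-sign cell-cycle
    classifier. A synthetic-cohort generator reproduces the statistical
    structure of such experiments so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    SingleCellExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
biocViews: SingleCell, RNASeq, GeneExpression, Normalization,
    DifferentialExpression, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
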