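Package: refblend
Title: Modality-Aware Integration of Single-Nucleus Cells into Single-Cell Deconvolution References
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking strategies that blend single-nucleus RNA-seq
    (snRNA-seq) cell types into single-cell RNA-seq (scRNA-seq) references for
    bulk RNA-seq deconvolution. Provides paired-modality synthetic data
    generation with known cell-type programs and nucleus-specific expression
    shifts, pseudobulk simulation with known mixing proportions, cross-modality
    differential-expression gene pruning, three expression harmonization
    transforms (PCA neighbour shift, variational-autoencoder latent shift, and
    conditional variational-autoencoder label switching), held-out reference
    assembly, non-negative least-squares deconvolution with an external-tool
    adapter contract, and the accuracy and robustness scoring used to rank
    reference-construction strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
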