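Package: miRNoise
Title: Expression Noise of miRNA Target Genes in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the effect of microRNAs on the cell-to-cell
    expression variability ("noise") of their target mRNAs from paired
    single-cell mRNA and miRNA profiles. Noise is measured as the residual
    coefficient of variation (RCV): the residual of log10(CV) after
    ordinary-least-squares regression on log10(mean), which removes the
    strong mean dependence of single-cell noise. The package stratifies
    miRNAs by expression level, compares RCV distributions of union target
    sets with two-sample Kolmogorov-Smirnov tests, evaluates differentially
    expressed miRNAs through per-miRNA t-tests with Benjamini-Hochberg
    correction, combinatorial targeting frequencies, hierarchical-clustering
    mixing, and log-fold-change summaries, and ships a negative-binomial
    dropout-aware simulator with planted noise-reduction effects for
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
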