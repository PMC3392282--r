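Package: admixPCA
Title: Principal Components Analysis of Population Admixture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theoretical and empirical principal components analysis of
    structured and admixed populations in the individuals-as-features
    orientation. Builds and solves the reduced K x K eigenequation over
    population-level allele-count variance-covariance parameters (exact and
    asymptotic forms), maps allele-frequency moments with admixture to
    allele-count moments, estimates admixture proportions from
    eigenvector-plot geometry (segment ratios, triangle areas, general
    barycentric solution) with affine-residual diagnostics, ranks
    ancestry-informative markers by eigenvector projection, and simulates
    genotype panels under the Balding-Nichols model with homogeneous or
    recently admixed groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
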