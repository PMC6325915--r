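Package: xdosage
Title: X Chromosome Dosage Compensation Analysis from Gene-Level Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chromosome-relative expression statistics for studying X chromosome
    dosage compensation (Ohno's hypothesis) in species with 26 autosome pairs
    plus X, such as sheep. Computes the relative X expression (RXE, the log2
    X:autosome mean-TPM ratio) and per-autosome relative gene expression (RGE)
    within configurable gene subgroups (all genes, expressed genes, genes
    subject to X inactivation after pseudoautosomal-region removal, and
    dosage-sensitive genes), classifies compensation status, calls
    diet-responsive genes with a stratified sample-level bootstrap
    differential-expression test, and runs the associated group comparisons
    (Student t, Wilcoxon rank-sum, one-way ANOVA, Pearson correlation).
    Includes a synthetic expression-data generator with a planted
    X-upregulation factor and planted differential effects for end-to-end,
    download-free validation of every stage, plus a deterministic pipeline
    driver that writes a reproducible result bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
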