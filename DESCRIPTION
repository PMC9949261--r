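Package: otsp
Title: Amplification-Bias Normalization for Multiplex-PCR TCR Repertoire
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects multiplex-PCR amplification bias in TCR-beta CDR3
    clonotype counts using scaling factors derived from equimolar
    synthetic-template spike-ins under a negative-binomial count model.
    Provides barcode demultiplexing of spike-in reads from merged FASTQ,
    per-template negative-binomial mean and dispersion estimation with a
    common (median) dispersion, batch-mean and NB-mean scaling factors,
    proportional redistribution of normalized primer-pair totals to
    clonotypes, V-by-J primer-interaction diagnostics via signed Pearson
    residuals, repertoire metrics (Shannon diversity, clonality,
    hyperexpanded fraction, replicate dropout), and seeded simulators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
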