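Package: mircoop
Title: Cooperative miRNA-mRNA Regulatory Networks from Paired Tumor-Normal Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated small-RNA / mRNA analysis pipeline for paired
    tumor-normal designs that discovers transcription factors cooperatively
    suppressed by multiple co-upregulated microRNAs. Provides RPKM/TPM/CPM
    quantification and expression filters, a per-pair negative-binomial exact
    test for designs without replicates, canonical seed-match target
    prediction with a hybridization-alignment score and a context-style site
    score, assembly of the negative miRNA-mRNA regulatory network with a
    cross-pair recurrence filter and hub statistics, hypergeometric and
    Wallenius term enrichment with rich factors, closed-form
    immunohistochemistry, qPCR and xenograft formulas, and a synthetic paired
    cohort generator with planted cooperative suppression structure for
    parameter-recovery testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
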