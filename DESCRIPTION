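Package: codongrowth
Title: Predict Prokaryotic Maximal Growth Rates from Codon Usage Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates minimal generation times (maximal growth rates) of
    bacteria and archaea from coding sequences alone. Implements the
    background-corrected effective number of codons (ENC'), the
    differential index dENC' contrasting highly expressed genes with the
    rest of the genome, the selection-strength index S over two-codon
    amino acids, their composite first principal component F, and a
    Box-Cox linear predictor of minimal doubling time with an optional
    growth-temperature term. Includes a metagenome workflow (ORF
    extraction from contigs, gene-level indices, bootstrap community
    averages and comparisons, discrete growth-class calls), extraction of
    growth-associated genome traits (rRNA operon and tRNA multiplicity,
    replication-origin-relative gene positions), and a synthetic-data
    generator with controlled translational selection for validation.
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
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
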