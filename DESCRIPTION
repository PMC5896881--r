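Package: codonexpress
Title: Codon Usage Bias and Sequence-Based Expression Prediction for
    Trypanosomatids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-scale codon usage analysis in organisms with
    largely unregulated transcription, built around the trypanosomatid
    model. Computes codon usage tables, GC3 content, Codon Adaptation
    Index (CAI) weights and scores, codon over/under-representation maps
    and codon-pair bias residuals from coding sequences; predicts
    relative mRNA and protein abundance from sequence alone via a
    length-adjusted CAI score fitted against expression tables; builds
    the gene cohorts used for reference and analysis sets (highly
    expressed reference genes, strand-switch-region genes, stage-stable
    genes); designs GC3-recoded reporter genes; and ships a synthetic
    genome generator so every stage can be exercised and validated
    without external data.
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
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
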