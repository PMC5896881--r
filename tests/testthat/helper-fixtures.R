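# Shared fixtures: tiny FASTA/GFF writers, toy count tables, and a
# random-CDS generator used by the property tests.

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}

# codon counts with every codon zero except those given
toy_counts <- function(...) {
  given <- c(...)
  cnt <- count_codons(character(0))
  cnt$count[match(names(given), cnt$codon)] <- unname(given)
  cnt
}

# random in-frame CDS of n sense codons (uniform over the 61), plus stop
random_cds <- function(n_codons, with_stop = FALSE) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste0(paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         if (with_stop) "TAA" else "")
}

# random CAI-style weight table: uniform(0,1] per codon, rescaled so each
# family's max is 1 (the shape cai_weights() guarantees)
random_weights <- function() {
  ct <- tibble::tibble(
    codon = names(Biostrings::GENETIC_CODE),
    aa = unname(Biostrings::GENETIC_CODE)
  ) |> dplyr::filter(aa != "*")
  ct$w <- stats::runif(nrow(ct), 0.01, 1)
  ct |>
    dplyr::group_by(aa) |>
    dplyr::mutate(w = w / max(w)) |>
    dplyr::ungroup()
}

# independent brute-force CAI oracle: product of w over scoreable codons,
# then the n-th root (no log-domain shortcut)
cai_oracle <- function(seq, weights) {
  cods <- substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
  excluded <- c("TAA", "TAG", "TGA",
                weights$codon[weights$aa %in% c("M", "W")])
  cods <- cods[!cods %in% excluded]
  w <- weights$w[match(cods, weights$codon)]
  prod(w)^(1 / length(w))
}
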