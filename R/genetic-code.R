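# Internal genetic-code machinery shared by all modules. The standard nuclear
# code is used throughout (trypanosomatid nuclear genes use the standard code);
# the six-codon Ser/Leu/Arg families are treated as single synonymous families,
# keyed by amino acid, matching the family structure CAI assumes.

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows n distinct pull rename across
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map2 imap
#' @importFrom stats lm coef cor sd rnorm rpois rbeta rbinom setNames
NULL

# 64 codons in alphabetical order, amino acid from the standard code ("*" = stop)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble(codon = sort(names(gc)), aa = unname(gc[sort(names(gc))]))
}

sense_codons <- function() {
  ct <- codon_table()
  ct$codon[ct$aa != "*"]
}

stop_codons <- function() c("TAA", "TAG", "TGA")

aa_of <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# family sizes keyed by amino acid letter
family_sizes <- function() {
  ct <- codon_table()
  ct <- ct[ct$aa != "*", ]
  table(ct$aa)
}

single_codon_aas <- function() c("M", "W")

# split an in-frame CDS string into its codon vector
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort("sequence length is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# translate an in-frame CDS; trailing stop rendered as "*"
translate_cds <- function(seq) {
  paste(aa_of(split_codons(seq)), collapse = "")
}

third_base <- function(codons) substr(codons, 3L, 3L)
first_base <- function(codons) substr(codons, 1L, 1L)

is_dna <- function(x) grepl("^[ACGT]*$", x)

check_cds <- function(seq, gene_id = "<cds>") {
  if (!is_dna(seq)) {
    abort(paste0("sequence for ", gene_id, " contains non-ACGT characters"))
  }
  if (nchar(seq) == 0L || nchar(seq) %% 3L != 0L) {
    abort(paste0("sequence length for ", gene_id,
                 " is not a positive multiple of 3"))
  }
  cods <- split_codons(seq)
  internal <- cods[-length(cods)]
  if (any(internal %in% stop_codons())) {
    abort(paste0("sequence for ", gene_id, " contains an internal stop codon"))
  }
  invisible(seq)
}
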