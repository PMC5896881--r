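# Codon counting, usage tables, GC3, CAI weights and scores, and
# over/under-representation maps.

#' Count codons across a set of coding sequences
#'
#' Counts in-frame triplets over all sequences. Trailing stop codons are
#' counted (and flagged via the `aa == "*"` rows) unless `drop_stops = TRUE`.
#'
#' @param cds Tibble with a `seq` column of in-frame coding sequences, or a
#'   character vector of sequences.
#' @param drop_stops Drop stop-codon counts entirely.
#' @return Tibble with one row per codon (64, or 61 when stops are dropped):
#'   `codon`, `aa`, `count`.
#' @export
count_codons <- function(cds, drop_stops = FALSE) {
  seqs <- if (is.data.frame(cds)) cds$seq else cds
  cods <- unlist(map(seqs, split_codons), use.names = FALSE)
  ct <- codon_table()
  tab <- table(factor(cods, levels = ct$codon))
  out <- ct |> mutate(count = as.numeric(tab[.data$codon]))
  if (drop_stops) out <- filter(out, .data$aa != "*")
  out
}

#' Per-family codon usage fractions
#'
#' Converts codon counts into within-family usage fractions: each sense
#' codon's count divided by the total count of its synonymous family (the
#' codons sharing its amino acid; Ser/Leu/Arg six-codon sets are single
#' families). Families with zero total count are flagged undefined and get
#' `NA` fractions.
#'
#' @param counts Codon counts as returned by [count_codons()].
#' @return Tibble `codon`, `aa`, `fraction`, `family_defined`. Fractions sum
#'   to 1 within each defined family.
#' @export
usage_table <- function(counts) {
  counts <- filter(counts, .data$aa != "*")
  if (sum(counts$count) == 0) abort("all codon counts are zero")
  counts |>
    group_by(.data$aa) |>
    mutate(family_defined = sum(.data$count) > 0,
           fraction = ifelse(.data$family_defined,
                             .data$count / sum(.data$count), NA_real_)) |>
    ungroup() |>
    select("codon", "aa", "fraction", "family_defined")
}

#' GC3 content of coding sequences
#'
#' Fraction of non-stop codons with G or C at the third (wobble) position.
#'
#' @param seq Character vector of in-frame coding sequences (or a tibble with
#'   a `seq` column).
#' @return Numeric vector of GC3 fractions.
#' @export
gc3 <- function(seq) {
  seqs <- if (is.data.frame(seq)) seq$seq else seq
  map_dbl(seqs, function(s) {
    cods <- split_codons(s)
    cods <- cods[!cods %in% stop_codons()]
    if (length(cods) == 0L) abort("no non-stop codons; GC3 undefined")
    mean(third_base(cods) %in% c("G", "C"))
  })
}

#' Relative adaptiveness weights for the Codon Adaptation Index
#'
#' Computes per-codon relative adaptiveness `w` from codon counts of a
#' reference set of highly expressed genes: within each synonymous family,
#' `w = usage fraction / max usage fraction`, so the most-used codon of each
#' family has `w = 1`. Zero reference counts are replaced with a pseudo-count
#' of 0.5 before fractions are formed, and `w` is floored at 0.01 — the
#' standard convention where the reference set is small. Stop codons are
#' excluded; single-codon families (Met, Trp) get `w = 1`.
#'
#' @param reference_counts Codon counts from the reference gene set (see
#'   [count_codons()] and [select_reference_set()]).
#' @param reference_ids Optional character vector recording which genes the
#'   counts came from; stored as an attribute for provenance.
#' @return Tibble `codon`, `aa`, `w` over the 61 sense codons, with attribute
#'   `reference_ids`.
#' @export
cai_weights <- function(reference_counts, reference_ids = NULL) {
  counts <- filter(reference_counts, .data$aa != "*")
  if (sum(counts$count) == 0) abort("empty reference: all counts zero")
  out <- counts |>
    mutate(count = ifelse(.data$count == 0, 0.5, .data$count)) |>
    group_by(.data$aa) |>
    mutate(w = (.data$count / sum(.data$count)) /
             max(.data$count / sum(.data$count))) |>
    ungroup() |>
    mutate(w = pmax(.data$w, 0.01)) |>
    select("codon", "aa", "w")
  attr(out, "reference_ids") <- reference_ids
  out
}

#' Codon Adaptation Index of coding sequences
#'
#' Geometric mean of relative adaptiveness `w` over a gene's codons, computed
#' in the log domain as `exp(mean(log w))` to avoid underflow on long genes.
#' Stop codons and the single-codon families Met and Trp (whose `w` is
#' constitutively 1) are excluded from the mean.
#'
#' @param seq Character vector of in-frame coding sequences (or a tibble with
#'   a `seq` column).
#' @param weights CAI weights from [cai_weights()].
#' @return Numeric vector of CAI scores in (0, 1].
#' @export
cai <- function(seq, weights) {
  seqs <- if (is.data.frame(seq)) seq$seq else seq
  w <- setNames(weights$w, weights$codon)
  excluded <- c(stop_codons(),
                weights$codon[weights$aa %in% single_codon_aas()])
  map_dbl(seqs, function(s) {
    cods <- split_codons(s)
    cods <- cods[!cods %in% excluded]
    if (length(cods) == 0L) abort("no scoreable codons for CAI")
    exp(mean(log(w[cods])))
  })
}

#' Codon over/under-representation map
#'
#' Signed percentage-point difference in within-family codon usage between a
#' gene cohort and a baseline (typically the genome): per codon,
#' `100 * (cohort fraction - baseline fraction)`. Positive values mark codons
#' over-represented in the cohort; per-family values sum to zero. A family
#' undefined in either table is flagged absent (`NA`).
#'
#' @param cohort_usage,baseline_usage Usage tables from [usage_table()],
#'   defined on the same families.
#' @return Tibble `codon`, `aa`, `rep_pp` (percentage points).
#' @export
representation_map <- function(cohort_usage, baseline_usage) {
  joined <- cohort_usage |>
    select("codon", "aa", cohort = "fraction",
           cohort_def = "family_defined") |>
    inner_join(baseline_usage |>
                 select("codon", base = "fraction",
                        base_def = "family_defined"),
               by = "codon")
  joined |>
    mutate(rep_pp = ifelse(.data$cohort_def & .data$base_def,
                           100 * (.data$cohort - .data$base), NA_real_)) |>
    select("codon", "aa", "rep_pp")
}

#' Per-codon representation values along a gene
#'
#' The heat-map values for one coding sequence: the i-th value is the
#' representation-map entry of the i-th codon. Stop codons emit `NA`.
#'
#' @param seq One in-frame coding sequence.
#' @param rep_map Representation map from [representation_map()].
#' @return Tibble `position`, `codon`, `value`.
#' @export
annotate_codons <- function(seq, rep_map) {
  cods <- split_codons(seq)
  vals <- setNames(rep_map$rep_pp, rep_map$codon)[cods]
  vals[cods %in% stop_codons()] <- NA_real_
  tibble(position = seq_along(cods), codon = cods, value = unname(vals))
}

#' Heat-map of a codon representation map
#'
#' One tile per sense codon, grouped by amino-acid family, coloured by
#' over-representation (green) vs under-representation (red) in percentage
#' points — the per-cohort codon usage display.
#'
#' @param rep_map Representation map from [representation_map()].
#' @return A ggplot object.
#' @export
plot_representation <- function(rep_map) {
  dat <- rep_map |>
    filter(!is.na(.data$rep_pp)) |>
    group_by(.data$aa) |>
    mutate(slot = dplyr::row_number()) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$aa, y = .data$slot,
                                    fill = .data$rep_pp)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$codon), size = 2.4) +
    ggplot2::scale_fill_gradient2(low = "red3", mid = "white",
                                  high = "green4", name = "pp") +
    ggplot2::labs(x = "amino acid", y = NULL,
                  title = "Codon representation (cohort - baseline)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
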