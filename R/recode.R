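# Reporter-gene recoding: deterministic synonymous recoding schemes that
# maximize, minimize or alternate GC3 content, or pick each family's most
# frequent codon from a usage table.

# choose one codon per amino acid under a target third-base class,
# tie-breaking by usage fraction then alphabetically
pick_codon <- function(aa, target3 = NULL, usage = NULL) {
  ct <- codon_table()
  fam <- ct$codon[ct$aa == aa]
  if (length(fam) == 0L) abort(paste0("invalid residue: ", aa))
  cand <- fam
  if (!is.null(target3)) {
    qualifying <- fam[third_base(fam) %in% target3]
    if (length(qualifying) > 0L) cand <- qualifying
  }
  if (!is.null(usage)) {
    frac <- setNames(usage$fraction, usage$codon)[cand]
    frac[is.na(frac)] <- 0
    cand <- cand[order(-frac, cand)]
  } else {
    cand <- sort(cand)
  }
  cand[1L]
}

#' Recode a protein or coding sequence under a GC3 scheme
#'
#' Designs a synonymous coding sequence for a protein under one of four
#' deterministic schemes:
#' \describe{
#'   \item{`max_gc3`}{every residue gets a codon with G or C at the third
#'     position (every synonymous family has one, and the single codons of
#'     Met and Trp already end in G), so the output's GC3 is 1.}
#'   \item{`min_gc3`}{every residue gets an A/T-ending codon where one
#'     exists; Met and Trp emit their sole (G-ending) codons.}
#'   \item{`alternating`}{positions alternate between the GC3 and AT3 target
#'     classes, starting at `alternating_start`; fixed-codon residues emit
#'     their codon and still advance the alternation phase.}
#'   \item{`table_optimal`}{each family's most frequent codon in the supplied
#'     usage table (the "codon optimised" design).}
#' }
#' Ties among qualifying codons are broken by higher usage fraction, then
#' alphabetically, so output is deterministic.
#'
#' @param x An amino-acid sequence, or an in-frame CDS (detected by DNA
#'   alphabet and length; translated first).
#' @param scheme One of `"max_gc3"`, `"min_gc3"`, `"alternating"`,
#'   `"table_optimal"`.
#' @param usage Optional usage table ([usage_table()]) for tie-breaking and
#'   for `table_optimal`; without one, ties resolve alphabetically.
#' @param alternating_start `"GC3"` or `"AT3"`: the target class of the first
#'   position under the alternating scheme.
#' @param append_stop Append a trailing `TAA` stop codon to the design (for
#'   cloning-ready output). Off by default so the recoded sequence maps
#'   codon-for-codon onto the input protein.
#' @return The recoded coding sequence (character scalar).
#' @examples
#' recode_cds("KN", "max_gc3")   # "AAGAAC"
#' recode_cds("KN", "min_gc3")   # "AAAAAT"
#' @export
recode_cds <- function(x, scheme = c("max_gc3", "min_gc3", "alternating",
                                     "table_optimal"),
                       usage = NULL, alternating_start = c("GC3", "AT3"),
                       append_stop = FALSE) {
  scheme <- match.arg(scheme)
  alternating_start <- match.arg(alternating_start)
  if (length(x) != 1L || nchar(x) == 0L) abort("empty or non-scalar input")
  x <- toupper(x)
  add_stop <- append_stop
  if (is_dna(x) && nchar(x) %% 3L == 0L) {
    check_cds(x)
    aa <- aa_of(split_codons(x))
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  } else {
    aa <- strsplit(x, "")[[1L]]
  }
  valid <- aa %in% codon_table()$aa[codon_table()$aa != "*"]
  if (!all(valid)) {
    abort(paste0("invalid residue(s): ",
                 paste(unique(aa[!valid]), collapse = ", ")))
  }
  gc <- c("G", "C")
  at <- c("A", "T")
  cods <- switch(
    scheme,
    max_gc3 = map_chr(aa, pick_codon, target3 = gc, usage = usage),
    min_gc3 = map_chr(aa, pick_codon, target3 = at, usage = usage),
    table_optimal = {
      if (is.null(usage)) abort("table_optimal needs a usage table")
      map_chr(aa, pick_codon, target3 = NULL, usage = usage)
    },
    alternating = {
      phase_gc <- alternating_start == "GC3"
      out <- character(length(aa))
      for (i in seq_along(aa)) {
        out[i] <- pick_codon(aa[i], target3 = if (phase_gc) gc else at,
                             usage = usage)
        phase_gc <- !phase_gc
      }
      out
    }
  )
  paste0(paste(cods, collapse = ""), if (add_stop) "TAA" else "")
}

#' Verify a recoded sequence against its source
#'
#' Checks that recoding preserved the encoded protein and reports the
#' sequence statistics of the design: GC3, CAI (when weights are given) and
#' the per-codon representation values (when a representation map is given).
#'
#' @param recoded The recoded CDS.
#' @param original The original protein or CDS it was derived from.
#' @param weights Optional CAI weights ([cai_weights()]).
#' @param rep_map Optional representation map ([representation_map()]).
#' @return List with `translation_preserved`, `gc3`, and optionally `cai` and
#'   `codon_values` (tibble from [annotate_codons()]).
#' @export
verify_recode <- function(recoded, original, weights = NULL, rep_map = NULL) {
  strip_stop <- function(p) sub("\\*$", "", p)
  orig_aa <- if (is_dna(toupper(original)) &&
                 nchar(original) %% 3L == 0L) {
    strip_stop(translate_cds(toupper(original)))
  } else toupper(original)
  rec_aa <- strip_stop(translate_cds(recoded))
  out <- list(translation_preserved = identical(rec_aa, orig_aa),
              gc3 = gc3(recoded))
  if (!is.null(weights)) out$cai <- cai(recoded, weights)
  if (!is.null(rep_map)) out$codon_values <- annotate_codons(recoded, rep_map)
  out
}
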