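# Gene-cohort construction: reference/analysis sets per species, strand-switch
# genes, and the developmental-stage stability filter. All printed thresholds
# are strict (">"), matching the rules as stated.

#' Select the highly expressed reference gene set
#'
#' The reference set for CAI weight estimation: genes whose proteome evidence
#' passes strict thresholds. For the default (T. brucei-style) rule these are
#' proteins of more than `min_len_aa` amino acids with more than
#' `min_unique_peptides` unique peptides and more than `min_coverage`
#' sequence coverage. Species-specific variants: `"tvivax"` uses
#' `unique_peptides > 20` and `peptides/kbp > 15`; `"lmexicana"` uses
#' `mrna_level > 100` (FPKM) restricted to orthologs of a supplied reference
#' set.
#'
#' @param evidence Tibble with `gene_id`, `unique_peptides`, `coverage`
#'   (fraction), `protein_length_aa`, and for the species variants
#'   `cds_length_bp` or `mrna_level`.
#' @param species One of `"tbrucei"` (threshold rule), `"tvivax"`,
#'   `"lmexicana"`.
#' @param min_len_aa,min_unique_peptides,min_coverage Strict lower thresholds
#'   for the default rule.
#' @param orthologs_of For `"lmexicana"`: character vector of ids (after
#'   ortholog mapping) the set is restricted to.
#' @return Character vector of gene ids, sorted.
#' @export
select_reference_set <- function(evidence, species = "tbrucei",
                                 min_len_aa = 250, min_unique_peptides = 25,
                                 min_coverage = 0.75, orthologs_of = NULL) {
  if (nrow(evidence) == 0L) abort("empty evidence table")
  species <- match.arg(species, c("tbrucei", "tvivax", "lmexicana"))
  ids <- switch(
    species,
    tbrucei = evidence |>
      filter(.data$protein_length_aa > min_len_aa,
             .data$unique_peptides > min_unique_peptides,
             .data$coverage > min_coverage) |>
      pull("gene_id"),
    tvivax = evidence |>
      filter(.data$unique_peptides > 20,
             .data$unique_peptides / (.data$cds_length_bp / 1000) > 15) |>
      pull("gene_id"),
    lmexicana = {
      out <- evidence |> filter(.data$mrna_level > 100) |> pull("gene_id")
      if (!is.null(orthologs_of)) out <- intersect(out, orthologs_of)
      out
    }
  )
  sort(ids)
}

#' Select the proteome and transcriptome analysis sets
#'
#' Builds the per-species gene sets used for genome-scale evaluation. For the
#' default rule the proteome set is the non-redundant genes with more than 3
#' unique peptides and the transcriptome set all non-redundant genes, both
#' excluding RNA polymerase I transcribed genes. Variants: `"tvivax"`
#' additionally restricts both sets to orthologs and requires
#' `mrna_level > 10` (tags) for the transcriptome set; `"lmexicana"` uses
#' `mrna_level > 5` (FPKM) plus the ortholog restriction for its
#' transcriptome set.
#'
#' @param evidence Tibble with `gene_id`, `unique_peptides`, and `mrna_level`
#'   where the species rule needs it.
#' @param annotation Tibble with `gene_id` and `is_pol_I`.
#' @param species One of `"tbrucei"`, `"tvivax"`, `"lmexicana"`.
#' @param orthologs Optional two-column ortholog map (or character vector of
#'   ids); when supplied, genes absent from it are dropped.
#' @param redundancy_map Optional tibble `gene_id`, `group`; one
#'   representative (first by id) is kept per group.
#' @return List with character vectors `proteome` and `transcriptome`.
#' @export
select_analysis_sets <- function(evidence, annotation, species = "tbrucei",
                                 orthologs = NULL, redundancy_map = NULL) {
  species <- match.arg(species, c("tbrucei", "tvivax", "lmexicana"))
  need <- switch(species, tbrucei = "unique_peptides",
                 tvivax = c("unique_peptides", "mrna_level"),
                 lmexicana = "mrna_level")
  absent <- setdiff(need, names(evidence))
  if (length(absent) > 0L) {
    abort(paste0("rule for ", species, " needs column(s): ",
                 paste(absent, collapse = ", ")))
  }
  pol1 <- annotation$gene_id[annotation$is_pol_I]
  ids <- evidence$gene_id
  if (!is.null(redundancy_map)) {
    reps <- redundancy_map |>
      arrange(.data$gene_id) |>
      distinct(.data$group, .keep_all = TRUE) |>
      pull("gene_id")
    ids <- intersect(ids, union(reps,
                                setdiff(ids, redundancy_map$gene_id)))
  }
  ortho_ids <- if (is.null(orthologs)) NULL
  else if (is.data.frame(orthologs)) orthologs[[1L]]
  else orthologs
  base <- evidence |> filter(.data$gene_id %in% ids,
                             !.data$gene_id %in% pol1)
  restrict <- function(v) if (is.null(ortho_ids)) v else
    intersect(v, ortho_ids)
  out <- switch(
    species,
    tbrucei = list(
      proteome = base |> filter(.data$unique_peptides > 3) |>
        pull("gene_id"),
      transcriptome = base |> pull("gene_id")
    ),
    tvivax = list(
      proteome = restrict(base |> filter(.data$unique_peptides > 3) |>
                            pull("gene_id")),
      transcriptome = restrict(base |> filter(.data$mrna_level > 10) |>
                                 pull("gene_id"))
    ),
    lmexicana = list(
      proteome = restrict(base |> filter(.data$mrna_level > 5) |>
                            pull("gene_id")),
      transcriptome = restrict(base |> filter(.data$mrna_level > 5) |>
                                 pull("gene_id"))
    )
  )
  map(out, sort)
}

#' Genes flanking strand-switch regions
#'
#' Finds genes immediately adjacent to divergent or convergent polycistron
#' boundaries: for each adjacent gene pair on the same chromosome whose
#' strands oppose — `(+,-)` convergent or `(-,+)` divergent — the flanking
#' genes on each side are returned. Chromosome-terminal genes are not counted
#' by position alone. `flank` generalizes "immediately adjacent" to that many
#' genes on each side of each transition.
#'
#' @param annotation Tibble with `gene_id`, `chrom`, `start`, `strand`.
#' @param flank Number of genes taken on each side of a strand transition.
#' @return Character vector of gene ids (unique, in genome order).
#' @export
strand_switch_genes <- function(annotation, flank = 1) {
  if (any(!annotation$strand %in% c("+", "-"))) {
    abort("unstranded gene(s) in annotation")
  }
  ann <- annotation |> arrange(.data$chrom, .data$start)
  hits <- ann |>
    group_by(.data$chrom) |>
    summarise(ids = list({
      st <- .data$strand
      gid <- .data$gene_id
      sel <- logical(length(st))
      trans <- which(st[-length(st)] != st[-1L])
      for (i in trans) {
        lo <- max(1L, i - flank + 1L)
        hi <- min(length(st), i + flank)
        sel[lo:hi] <- TRUE
      }
      gid[sel]
    }), .groups = "drop")
  unlist(hits$ids, use.names = FALSE)
}

#' Filter genes stable between two life-cycle stages
#'
#' Retains genes whose expression differs by at most `max_fold` between two
#' stages (boundary inclusive), removing developmentally regulated genes
#' before codon-usage/expression comparisons. Genes with non-positive
#' expression in either stage are dropped with a message.
#'
#' @param data Tibble with `gene_id` and two stage-expression columns.
#' @param stage_a,stage_b Column names of the two stages.
#' @param max_fold Maximum tolerated fold-change.
#' @return Tibble `gene_id`, `fold_change`, `retained`, with attributes
#'   `n_removed` and `fraction_removed` (among genes with usable values).
#' @export
stage_filter <- function(data, stage_a = "stage_a", stage_b = "stage_b",
                         max_fold = 3) {
  a <- data[[stage_a]]
  b <- data[[stage_b]]
  bad <- is.na(a) | is.na(b) | a <= 0 | b <= 0
  if (any(bad)) {
    inform(paste0("dropping ", sum(bad),
                  " gene(s) with non-positive stage expression"))
  }
  out <- tibble(gene_id = data$gene_id[!bad],
                fold_change = pmax(a[!bad] / b[!bad], b[!bad] / a[!bad])) |>
    mutate(retained = .data$fold_change <= max_fold)
  attr(out, "n_removed") <- sum(!out$retained)
  attr(out, "fraction_removed") <- mean(!out$retained)
  out
}
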