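# Readers and writers for the external formats the pipeline touches.
# Internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
# bedGraph (natively 0-based half-open) are converted at the boundary.

#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA of in-frame coding sequences into a tibble.
#' Sequences are uppercased and RNA `U` is mapped to `T`; record ids are the
#' first whitespace-delimited token of each header. Each sequence must be a
#' positive multiple of 3 in length, contain only A/C/G/T, and carry no
#' internal in-frame stop codon (a trailing stop is permitted and retained).
#'
#' @param path Path to a FASTA file.
#' @param skip_invalid If `TRUE`, records violating the coding-sequence
#'   invariants are dropped with a warning naming them instead of raising an
#'   error. Duplicated ids always raise an error.
#' @return A tibble with columns `gene_id`, `seq`, `length_bp`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 some description", "ATGGCCTAA"), fa)
#' read_cds_fasta(fa)
#' @export
read_cds_fasta <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- map_chr(strsplit(names(set), "\\s+"), 1L)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  cds <- tibble(gene_id = ids, seq = unname(seqs),
                length_bp = nchar(unname(seqs)))
  bad <- map_chr(seq_len(nrow(cds)), function(i) {
    tryCatch({
      check_cds(cds$seq[i], cds$gene_id[i])
      NA_character_
    }, error = function(e) conditionMessage(e))
  })
  if (any(!is.na(bad))) {
    msgs <- bad[!is.na(bad)]
    if (skip_invalid) {
      warn(paste0("dropping ", length(msgs), " invalid record(s):\n  ",
                  paste(msgs, collapse = "\n  ")))
      cds <- cds[is.na(bad), ]
    } else {
      abort(paste0("invalid coding sequence record(s):\n  ",
                   paste(msgs, collapse = "\n  ")))
    }
  }
  cds
}

#' Write coding sequences to a FASTA file
#'
#' Inverse of [read_cds_fasta()]: `read -> write -> read` is the identity on
#' `(gene_id, seq)`.
#'
#' @param cds Tibble with columns `gene_id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  set <- Biostrings::DNAStringSet(setNames(cds$seq, cds$gene_id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Extract coding sequences from a genome FASTA plus GFF3 annotation
#'
#' Pulls one CDS per gene out of a genome using its GFF3 annotation.
#' Minus-strand genes are reverse-complemented so all returned sequences read
#' 5'→3' in the coding sense. GFF3 1-based inclusive coordinates are converted
#' to the package's internal 0-based half-open convention.
#'
#' @param fasta_path Genome FASTA (chromosome/contig sequences).
#' @param gff_path GFF3 file with `CDS` features; the gene id is taken from the
#'   feature's `Parent` attribute when present, else its `ID`.
#' @param join_segments If `FALSE` (strict, the default) a gene whose CDS is
#'   split over several segments is an error; if `TRUE` segments are joined in
#'   transcript order.
#' @return A list with elements `cds` (tibble `gene_id`, `seq`, `length_bp`)
#'   and `annotation` (tibble `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `is_pol_I`, `is_VSG`; `start`/`end` 0-based half-open), the latter sorted
#'   by `(chrom, start)`.
#' @export
read_gff3_cds <- function(fasta_path, gff_path, join_segments = FALSE) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- map_chr(strsplit(names(genome), "\\s+"), 1L)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  cds_feat <- gff[gff$type == "CDS"]
  if (length(cds_feat) == 0L) abort("no CDS features in GFF3")
  parent <- as.character(cds_feat$Parent)
  id <- if (!is.null(cds_feat$ID)) as.character(cds_feat$ID) else NA_character_
  gene <- ifelse(is.na(parent) | parent == "character(0)" | parent == "",
                 id, parent)
  gene <- sub("^(transcript|mRNA|gene):", "", gene)
  feats <- tibble(
    gene_id = gene,
    chrom = as.character(GenomicRanges::seqnames(cds_feat)),
    start1 = GenomicRanges::start(cds_feat),
    end1 = GenomicRanges::end(cds_feat),
    strand = as.character(GenomicRanges::strand(cds_feat))
  )
  if (any(!feats$strand %in% c("+", "-"))) {
    abort("CDS features with undefined strand")
  }
  n_seg <- table(feats$gene_id)
  if (!join_segments && any(n_seg > 1L)) {
    abort(paste0("multi-segment CDS for: ",
                 paste(names(n_seg)[n_seg > 1L], collapse = ", "),
                 " (use join_segments = TRUE to join in transcript order)"))
  }
  per_gene <- feats |>
    group_by(.data$gene_id) |>
    arrange(.data$start1, .by_group = TRUE) |>
    summarise(
      chrom = .data$chrom[1L], strand = .data$strand[1L],
      start = min(.data$start1) - 1L, end = max(.data$end1),
      seq = {
        segs <- map2(.data$start1, .data$end1, function(s, e) {
          as.character(Biostrings::subseq(genome[[.data$chrom[1L]]], s, e))
        })
        joined <- paste(unlist(segs), collapse = "")
        if (.data$strand[1L] == "-") {
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(joined)))
        } else joined
      },
      .groups = "drop"
    )
  meta_lgl <- function(field) {
    if (!is.null(gff@elementMetadata[[field]])) {
      v <- gff@elementMetadata[[field]][gff$type == "CDS"]
      as.logical(toupper(as.character(v)) %in% c("TRUE", "1", "YES"))
    } else rep(FALSE, length(cds_feat))
  }
  flags <- tibble(gene_id = gene,
                  is_pol_I = meta_lgl("is_pol_I"),
                  is_VSG = meta_lgl("is_VSG")) |>
    distinct(.data$gene_id, .keep_all = TRUE)
  annotation <- per_gene |>
    select("gene_id", "chrom", "start", "end", "strand") |>
    left_join(flags, by = "gene_id") |>
    arrange(.data$chrom, .data$start)
  cds <- per_gene |>
    mutate(length_bp = nchar(.data$seq)) |>
    select("gene_id", "seq", "length_bp")
  for (i in seq_len(nrow(cds))) check_cds(cds$seq[i], cds$gene_id[i])
  list(cds = cds, annotation = annotation)
}

#' Read a gene-keyed TSV table with schema checking
#'
#' Backbone reader for expression, proteome-evidence, cohort and ortholog
#' tables. Requires a header row; checks that required columns are present and
#' numeric columns parse; percentage-style columns (values in 0–100) named in
#' `rescale_percent` are rescaled to fractions in \[0, 1\]. Missing optional
#' fields stay `NA` (absent), never zero.
#'
#' @param path Path to a TSV file with a header row.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers; a non-numeric cell
#'   raises an error with its row number.
#' @param rescale_percent Columns interpreted as percentages when any value
#'   exceeds 1 (rescaled by 1/100).
#' @return A tibble with one row per input row.
#' @export
read_gene_table <- function(path, required = "gene_id",
                            numeric_cols = character(),
                            rescale_percent = character()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in intersect(numeric_cols, names(tab))) {
    raw <- tab[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad) > 0L) {
      abort(paste0("non-numeric value in column '", col, "' at row ",
                   bad[1L], ": '", raw[bad[1L]], "'"))
    }
    tab[[col]] <- parsed
  }
  for (col in intersect(rescale_percent, names(tab))) {
    v <- tab[[col]]
    if (any(v > 1, na.rm = TRUE)) tab[[col]] <- v / 100
  }
  tab
}

#' Read an expression table (gene id to mRNA level)
#'
#' @param path TSV with columns `gene_id` and one of `mrna_level` (or a column
#'   named by `value_col`) holding RPKM/FPKM/tag counts.
#' @param value_col Name of the expression column in the file.
#' @return Tibble `gene_id`, `mrna_level`.
#' @export
read_expression_table <- function(path, value_col = "mrna_level") {
  tab <- read_gene_table(path, required = c("gene_id", value_col),
                         numeric_cols = value_col)
  tab |>
    rename(mrna_level = !!rlang::sym(value_col)) |>
    select("gene_id", "mrna_level")
}

#' Read a proteome-evidence table
#'
#' Expects `gene_id`, `unique_peptides`, `coverage` (fraction or percentage;
#' percentages are rescaled to \[0, 1\]), `protein_length_aa`, and optionally
#' `cds_length_bp`. When both lengths are present,
#' `cds_length_bp == 3 * (protein_length_aa + 1)` (stop codon included) is
#' checked and a discrepancy produces a warning, not an error.
#'
#' @param path TSV path.
#' @return Tibble with the evidence columns, numerics parsed.
#' @export
read_proteome_table <- function(path) {
  tab <- read_gene_table(
    path,
    required = c("gene_id", "unique_peptides", "coverage",
                 "protein_length_aa"),
    numeric_cols = c("unique_peptides", "coverage", "protein_length_aa",
                     "cds_length_bp", "mrna_level"),
    rescale_percent = "coverage"
  )
  if ("cds_length_bp" %in% names(tab)) {
    both <- !is.na(tab$cds_length_bp) & !is.na(tab$protein_length_aa)
    off <- both & tab$cds_length_bp != 3 * (tab$protein_length_aa + 1)
    if (any(off)) {
      warn(paste0(sum(off), " gene(s) where cds_length_bp != 3*(aa+1): ",
                  paste(utils::head(tab$gene_id[off], 5L), collapse = ", ")))
    }
  }
  tab
}

#' Read a cohort-definition table
#'
#' @param path TSV with columns `cohort` and `gene_id`, one member per row.
#' @return Tibble `cohort`, `gene_id`.
#' @export
read_cohort_table <- function(path) {
  read_gene_table(path, required = c("cohort", "gene_id")) |>
    select("cohort", "gene_id")
}

#' Read a two-column ortholog map
#'
#' @param path TSV whose first two columns map ids in one species to ids in
#'   another.
#' @return Tibble with the file's first two columns.
#' @export
read_ortholog_table <- function(path) {
  tab <- read_gene_table(path, required = character())
  if (ncol(tab) < 2L) abort("ortholog map needs two columns")
  tab[, 1:2]
}

#' Write per-gene scores as a bedGraph track
#'
#' Emits one bedGraph line per scored gene (`chrom start end score`, 0-based
#' half-open), sorted by chromosome then start — a per-gene CAI track suitable
#' for display on a physical chromosome map.
#'
#' @param annotation Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param scores Tibble with `gene_id` and `score`; every scored gene must be
#'   present in `annotation`.
#' @param path Optional output file; when `NULL` the lines are returned only.
#' @return Character vector of bedGraph lines, invisibly when written.
#' @export
write_cai_track <- function(annotation, scores, path = NULL) {
  unknown <- setdiff(scores$gene_id, annotation$gene_id)
  if (length(unknown) > 0L) {
    abort(paste0("score(s) for gene(s) absent from annotation: ",
                 paste(unknown, collapse = ", ")))
  }
  rows <- scores |>
    inner_join(annotation, by = "gene_id") |>
    arrange(.data$chrom, .data$start)
  lines <- sprintf("%s\t%d\t%d\t%g", rows$chrom, as.integer(rows$start),
                   as.integer(rows$end), rows$score)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
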