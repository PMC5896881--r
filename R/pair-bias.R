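# Codon-pair bias: adjacent sense-codon pair counts and adjusted Pearson
# residuals on the pair contingency table, with amino-acid and positional
# (third/first, third/third base) aggregations.

#' Count adjacent codon pairs
#'
#' Counts in-frame adjacent sense-codon pairs within each coding sequence.
#' Pairs never straddle gene boundaries, and pairs involving a stop codon are
#' dropped, so each gene with `k` sense codons contributes `k - 1` pairs.
#'
#' @param cds Tibble with a `seq` column of in-frame coding sequences, or a
#'   character vector.
#' @return Object of class `pair_counts`: list with `pairs` (tibble `codon1`,
#'   `codon2`, `observed` over the full 61x61 grid) and `total_pairs`.
#' @export
count_pairs <- function(cds) {
  seqs <- if (is.data.frame(cds)) cds$seq else cds
  sense <- sense_codons()
  mat <- matrix(0, length(sense), length(sense),
                dimnames = list(sense, sense))
  for (s in seqs) {
    cods <- split_codons(s)
    cods <- cods[!cods %in% stop_codons()]
    if (length(cods) >= 2L) {
      a <- cods[-length(cods)]
      b <- cods[-1L]
      t2 <- table(factor(a, levels = sense), factor(b, levels = sense))
      mat <- mat + as.matrix(t2)
    }
  }
  pairs <- as_tibble(as.table(mat), .name_repair = "minimal")
  names(pairs) <- c("codon1", "codon2", "observed")
  structure(list(pairs = as_tibble(pairs), total_pairs = sum(mat),
                 matrix = mat),
            class = "pair_counts")
}

# adjusted Pearson residuals of an observed contingency matrix under
# row/column independence: z = (O - E) / sqrt(E (1 - row/N)(1 - col/N))
adjusted_residuals <- function(obs) {
  n <- sum(obs)
  if (n == 0) abort("no codon pairs observed")
  row_tot <- rowSums(obs)
  col_tot <- colSums(obs)
  expected <- outer(row_tot, col_tot) / n
  denom <- sqrt(expected * outer(1 - row_tot / n, 1 - col_tot / n))
  z <- (obs - expected) / denom
  z[denom == 0] <- NA_real_
  list(expected = expected, z = z)
}

#' Codon-pair bias residuals
#'
#' Tests each adjacent codon pair against the independence expectation
#' `E = (row total)(column total) / N` on the 61x61 pair contingency table and
#' reports adjusted Pearson residuals
#' `z = (O - E) / sqrt(E (1 - row/N)(1 - col/N))`. Positive `z` marks
#' over-represented pairs, negative under-represented. Also returns the
#' amino-acid-level residual matrix (pair counts collapsed to the 20x20 table
#' first) and two 4x4 positional aggregations: mean `z` by (third base of the
#' first codon, first base of the second codon) and by (third, third).
#'
#' @param pair_counts Result of [count_pairs()].
#' @return Object of class `pair_bias`: list with `pairs` (tibble `codon1`,
#'   `codon2`, `observed`, `expected`, `z`), `aa_matrix` (20x20), `p3p1_matrix`
#'   and `p3p3_matrix` (4x4), and `total_pairs`.
#' @export
pair_residuals <- function(pair_counts) {
  obs <- pair_counts$matrix
  res <- adjusted_residuals(obs)
  pairs <- pair_counts$pairs |>
    mutate(expected = as.vector(res$expected[cbind(.data$codon1,
                                                   .data$codon2)]),
           z = as.vector(res$z[cbind(.data$codon1, .data$codon2)]))
  aa_matrix <- cooccurrence_by_aa(pair_counts)
  bases <- c("A", "C", "G", "T")
  agg <- function(key1, key2) {
    zv <- res$z
    k1 <- factor(key1[rownames(zv)], levels = bases)
    k2 <- factor(key2[colnames(zv)], levels = bases)
    out <- matrix(NA_real_, 4, 4, dimnames = list(bases, bases))
    for (b1 in bases) for (b2 in bases) {
      cell <- zv[k1 == b1, k2 == b2, drop = FALSE]
      out[b1, b2] <- mean(cell, na.rm = TRUE)
    }
    out
  }
  sense <- rownames(obs)
  third <- setNames(third_base(sense), sense)
  first <- setNames(first_base(sense), sense)
  structure(list(pairs = pairs, aa_matrix = aa_matrix,
                 p3p1_matrix = agg(third, first),
                 p3p3_matrix = agg(third, third),
                 total_pairs = pair_counts$total_pairs),
            class = "pair_bias")
}

#' Amino-acid-pair co-occurrence residuals
#'
#' Collapses codon-pair counts to encoded amino-acid pairs and computes the
#' same adjusted Pearson residuals on the resulting 20x20 contingency table.
#'
#' @param pair_counts Result of [count_pairs()].
#' @return 20x20 matrix of adjusted residuals (rows: first amino acid of the
#'   pair; columns: second).
#' @export
cooccurrence_by_aa <- function(pair_counts) {
  obs <- pair_counts$matrix
  aa_r <- aa_of(rownames(obs))
  aa_c <- aa_of(colnames(obs))
  aas <- sort(unique(aa_r))
  collapsed <- rowsum(t(rowsum(obs, aa_r)), aa_c)
  collapsed <- t(collapsed)[aas, aas]
  adjusted_residuals(collapsed)$z
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("Codon pair counts: ", x$total_pairs, " adjacent sense-codon pairs\n",
      sep = "")
  invisible(x)
}

#' @export
print.pair_bias <- function(x, ...) {
  cat("Codon pair bias over", x$total_pairs, "pairs\n")
  top <- x$pairs |> arrange(dplyr::desc(abs(.data$z))) |> utils::head(5)
  cat("largest |z| residuals:\n")
  print(as.data.frame(top), row.names = FALSE)
  invisible(x)
}

#' Heat-map of positional codon-pair bias
#'
#' Tiles the 4x4 mean residual matrix for (third base of codon i, first base
#' of codon i+1) or (third, third) pairs.
#'
#' @param x A `pair_bias` object.
#' @param which `"p3p1"` or `"p3p3"`.
#' @return A ggplot object.
#' @export
plot_pair_bias <- function(x, which = c("p3p1", "p3p3")) {
  which <- match.arg(which)
  m <- if (which == "p3p1") x$p3p1_matrix else x$p3p3_matrix
  dat <- as_tibble(as.table(m), .name_repair = "minimal")
  names(dat) <- c("base1", "base2", "z")
  ylab <- if (which == "p3p1") "first base, codon i+1" else
    "third base, codon i+1"
  ggplot2::ggplot(dat, ggplot2::aes(.data$base1, .data$base2,
                                    fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$z))) +
    ggplot2::scale_fill_gradient2(low = "red3", high = "green4") +
    ggplot2::labs(x = "third base, codon i", y = ylab,
                  title = "Mean adjusted residual") +
    ggplot2::theme_minimal()
}
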