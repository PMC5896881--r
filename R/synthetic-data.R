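# Synthetic-genome generator. Produces coding sequences with tunable
# per-gene codon bias, a chromosome layout of alternating-strand polycistrons
# (creating strand-switch regions), log-linear expression driven by the
# length-adjusted CAI score, a conditional protein layer, Poisson
# peptide-evidence sampling, and complex-style cohorts — the statistical
# structure the analysis assumes, so every stage can be validated offline.

#' Configuration for the synthetic genome generator
#'
#' Bundles every tunable of the generator with field-realistic defaults.
#' Genes get a codon-bias propensity `t ~ Beta(2, 2)`; per-family codon
#' probabilities are the mixture `(1 - t) * baseline + t * optimal`, so high-t
#' genes look like highly expressed, GC3-rich genes. Lengths are log-normal
#' with median 1.2 kbp. Expression follows
#' `log(mRNA) = alpha + beta * (CAI - c * sqrt(L_kbp)) + N(0, sigma^2)`, and
#' the protein layer is generated conditionally on mRNA. Genes are laid into
#' alternating-strand polycistrons, whose boundary (strand-switch-adjacent)
#' genes get their propensity multiplied by `ssr_factor`; a subset is flagged
#' VSG-like and drawn from an A3-enriched usage table.
#'
#' @param seed Integer seed; mandatory, sole source of randomness.
#' @param n_genes Number of genes.
#' @param median_kbp,sdlog_length Log-normal CDS length distribution
#'   (median in kbp; sdlog on the log scale).
#' @param baseline_usage,optimal_usage Usage tables (codon, aa, fraction);
#'   defaults: uniform within families, and 80% of family mass on G/C-ending
#'   codons split by count.
#' @param propensity_shape1,propensity_shape2 Beta parameters of the
#'   per-gene bias propensity.
#' @param n_chromosomes,genes_per_polycistron Chromosome layout; strands of
#'   consecutive polycistrons alternate, so every internal polycistron
#'   boundary is a strand-switch region.
#' @param ssr_factor Multiplier applied to the propensity of
#'   strand-switch-adjacent genes (< 1 lowers their codon bias).
#' @param n_vsg Number of VSG-like genes (A3-enriched usage, flagged).
#' @param alpha,beta,penalty_c,sigma Expression model: intercept, slope,
#'   length-penalty coefficient and log-scale noise SD.
#' @param protein_alpha,protein_slope,protein_sigma Protein layer:
#'   `log(protein) = protein_alpha + protein_slope * log(mRNA) + noise`.
#' @param n_multicopy,copy_max A few genes get an integer tandem copy-number
#'   multiplier in `2..copy_max` applied to both mRNA and protein (invisible
#'   to sequence-based prediction).
#' @param depth Proteome sampling depth: expected unique peptides per kbp
#'   for a protein at the mean abundance share.
#' @param n_cohorts,cohort_size_range Number of complex-style cohorts and
#'   their size range.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_genes = 2000, median_kbp = 1.2,
                       sdlog_length = 0.6,
                       baseline_usage = NULL, optimal_usage = NULL,
                       propensity_shape1 = 2, propensity_shape2 = 2,
                       n_chromosomes = 4, genes_per_polycistron = 10,
                       ssr_factor = 0.3, n_vsg = 0,
                       alpha = 1, beta = 5, penalty_c = 0.03, sigma = 0.5,
                       protein_alpha = 6, protein_slope = 1,
                       protein_sigma = 0.4,
                       n_multicopy = 0, copy_max = 8,
                       depth = 20, n_cohorts = 23,
                       cohort_size_range = c(3, 30)) {
  if (missing(seed)) abort("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              median_kbp = median_kbp, sdlog_length = sdlog_length,
              baseline_usage = baseline_usage %||% uniform_usage(),
              optimal_usage = optimal_usage %||% gc3_biased_usage(),
              propensity_shape1 = propensity_shape1,
              propensity_shape2 = propensity_shape2,
              n_chromosomes = n_chromosomes,
              genes_per_polycistron = genes_per_polycistron,
              ssr_factor = ssr_factor, n_vsg = n_vsg,
              alpha = alpha, beta = beta, penalty_c = penalty_c,
              sigma = sigma,
              protein_alpha = protein_alpha, protein_slope = protein_slope,
              protein_sigma = protein_sigma,
              n_multicopy = n_multicopy, copy_max = copy_max,
              depth = depth, n_cohorts = n_cohorts,
              cohort_size_range = cohort_size_range)
  stopifnot(all(map_dbl(cfg[!names(cfg) %in%
                              c("baseline_usage", "optimal_usage",
                                "cohort_size_range")], 1) |> is.finite()))
  structure(cfg, class = "sim_config")
}

# uniform within-family usage over the 61 sense codons
uniform_usage <- function() {
  ct <- codon_table() |> filter(.data$aa != "*")
  ct |>
    group_by(.data$aa) |>
    mutate(fraction = 1 / n(), family_defined = TRUE) |>
    ungroup() |>
    select("codon", "aa", "fraction", "family_defined")
}

# usage table concentrating `mass` of each family on its G/C-ending codons
gc3_biased_usage <- function(mass = 0.8) {
  ct <- codon_table() |> filter(.data$aa != "*")
  ct |>
    group_by(.data$aa) |>
    mutate(is_gc = third_base(.data$codon) %in% c("G", "C"),
           fraction = {
             n_gc <- sum(.data$is_gc)
             n_at <- n() - n_gc
             if (n_gc == 0L) rep(1 / n(), n())
             else if (n_at == 0L) rep(1 / n(), n())
             else ifelse(.data$is_gc, mass / n_gc, (1 - mass) / n_at)
           },
           family_defined = TRUE) |>
    ungroup() |>
    select("codon", "aa", "fraction", "family_defined")
}

# A3-enriched usage (VSG-like): weight `a_weight` on A-ending codons
a3_biased_usage <- function(a_weight = 3) {
  ct <- codon_table() |> filter(.data$aa != "*")
  ct |>
    group_by(.data$aa) |>
    mutate(wgt = ifelse(third_base(.data$codon) == "A", a_weight, 1),
           fraction = .data$wgt / sum(.data$wgt), family_defined = TRUE) |>
    ungroup() |>
    select("codon", "aa", "fraction", "family_defined")
}

#' Generate synthetic coding sequences with a chromosome layout
#'
#' Draws per-gene propensities `t ~ Beta`, lays genes into
#' alternating-strand polycistrons (every internal boundary a strand-switch
#' region, whose flanking genes get `t` scaled by `ssr_factor`), flags the
#' first `n_vsg` genes of the last chromosome VSG-like (drawn from an
#' A3-enriched table), and samples each gene's codons independently from its
#' mixed per-family distribution. Amino acids are sampled uniformly; a `TAA`
#' stop is appended to every gene. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `cds` (tibble `gene_id`, `seq`, `length_bp`),
#'   `annotation` (`gene_id`, `chrom`, `start`, `end`, `strand`, `is_pol_I`,
#'   `is_VSG`), and `truth` (`gene_id`, `propensity`, `is_ssr_adjacent`,
#'   `is_vsg`).
#' @export
sim_genes <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  # layout: chromosomes -> polycistrons of fixed size, strands alternate
  pc_size <- config$genes_per_polycistron
  pc_index <- (seq_len(n) - 1L) %/% pc_size
  n_pc <- max(pc_index) + 1L
  pc_per_chrom <- ceiling(n_pc / config$n_chromosomes)
  chrom_of_pc <- (seq_len(n_pc) - 1L) %/% pc_per_chrom
  chrom <- sprintf("chr%d", chrom_of_pc[pc_index + 1L] + 1L)
  pc_within <- pc_index - ave(pc_index, chrom, FUN = min)
  strand <- ifelse(pc_within %% 2L == 0L, "+", "-")

  # SSR-adjacent: genes flanking a strand transition within a chromosome
  is_ssr <- logical(n)
  for (i in seq_len(n - 1L)) {
    if (chrom[i] == chrom[i + 1L] && strand[i] != strand[i + 1L]) {
      is_ssr[i] <- TRUE
      is_ssr[i + 1L] <- TRUE
    }
  }

  is_vsg <- logical(n)
  if (config$n_vsg > 0) {
    last_chrom <- chrom == chrom[n]
    is_vsg[utils::tail(which(last_chrom), config$n_vsg)] <- TRUE
  }

  propensity <- rbeta(n, config$propensity_shape1, config$propensity_shape2)
  propensity[is_ssr] <- propensity[is_ssr] * config$ssr_factor

  len_codons <- pmax(30L, round(exp(rnorm(
    n, log(config$median_kbp * 1000 / 3), config$sdlog_length))))

  base_frac <- config$baseline_usage
  opt_frac <- config$optimal_usage
  vsg_frac <- a3_biased_usage()
  fam_split <- split(base_frac$codon, base_frac$aa)
  base_by_aa <- split(setNames(base_frac$fraction, base_frac$codon),
                      base_frac$aa)
  opt_by_aa <- split(setNames(opt_frac$fraction, opt_frac$codon),
                     opt_frac$aa)
  vsg_by_aa <- split(setNames(vsg_frac$fraction, vsg_frac$codon),
                     vsg_frac$aa)
  aas <- names(fam_split)

  seqs <- character(n)
  for (g in seq_len(n)) {
    k <- len_codons[g]
    aa_seq <- sample(aas, k, replace = TRUE)
    t <- propensity[g]
    cods <- character(k)
    for (a in unique(aa_seq)) {
      idx <- which(aa_seq == a)
      fam <- fam_split[[a]]
      p <- if (is_vsg[g]) vsg_by_aa[[a]][fam]
      else (1 - t) * base_by_aa[[a]][fam] + t * opt_by_aa[[a]][fam]
      cods[idx] <- sample(fam, length(idx), replace = TRUE, prob = p)
    }
    seqs[g] <- paste0(paste(cods, collapse = ""), "TAA")
  }

  length_bp <- nchar(seqs)
  # physical coordinates: sequential within chromosome, 200 bp gaps
  start <- integer(n)
  pos <- setNames(rep(0L, length(unique(chrom))), unique(chrom))
  for (g in seq_len(n)) {
    start[g] <- pos[chrom[g]]
    pos[chrom[g]] <- pos[chrom[g]] + length_bp[g] + 200L
  }

  list(
    cds = tibble(gene_id = gene_id, seq = seqs, length_bp = length_bp),
    annotation = tibble(gene_id = gene_id, chrom = chrom, start = start,
                        end = start + length_bp, strand = strand,
                        is_pol_I = is_vsg, is_VSG = is_vsg),
    truth = tibble(gene_id = gene_id, propensity = propensity,
                   is_ssr_adjacent = is_ssr, is_vsg = is_vsg)
  )
}

#' Generate synthetic expression from coding sequences
#'
#' Computes each gene's CAI under weights derived from the generator's
#' optimal usage table, forms the length-adjusted score
#' `s = CAI - c * sqrt(L_kbp)`, and draws
#' `log(mRNA) = alpha + beta * s + N(0, sigma^2)`. Protein is generated
#' conditionally on mRNA (`log(protein) = protein_alpha + protein_slope *
#' log(mRNA) + noise`), so the mRNA-protein link carries signal. Optional
#' tandem copy-number multipliers scale both layers. When a cohort map is
#' supplied, cohort members' protein abundance is replaced by their cohort's
#' shared true abundance before noise-free values are recorded.
#'
#' @param genes Result of [sim_genes()].
#' @param config The same [sim_config()].
#' @param cohorts Optional cohort map from [sim_cohorts()].
#' @return Tibble `gene_id`, `cai`, `length_bp`, `length_kbp`, `score`,
#'   `mrna`, `protein`, `true_mrna`, `true_protein`, `copy_number`.
#' @export
sim_expression <- function(genes, config, cohorts = NULL) {
  set.seed(config$seed + 1L)
  weights <- cai_weights(usage_to_counts(config$optimal_usage))
  dat <- genes$cds |>
    mutate(cai = cai(.data$seq, weights)) |>
    length_adjusted_cai(c = config$penalty_c)
  n <- nrow(dat)
  copy_number <- rep(1, n)
  if (config$n_multicopy > 0) {
    idx <- sample(n, config$n_multicopy)
    copy_number[idx] <- sample(2:config$copy_max, config$n_multicopy,
                               replace = TRUE)
  }
  log_mu <- config$alpha + config$beta * dat$score + log(copy_number)
  log_mrna <- log_mu + rnorm(n, 0, config$sigma)
  log_true_prot <- config$protein_alpha + config$protein_slope * log_mrna
  log_protein <- log_true_prot + rnorm(n, 0, config$protein_sigma)
  out <- dat |>
    mutate(mrna = exp(log_mrna), protein = exp(log_protein),
           true_mrna = exp(log_mu), true_protein = exp(log_true_prot),
           copy_number = copy_number) |>
    select("gene_id", "cai", "length_bp", "length_kbp", "score", "mrna",
           "protein", "true_mrna", "true_protein", "copy_number")
  if (!is.null(cohorts)) {
    # complex members share one true abundance: the geometric mean of their
    # individually generated protein levels, so the shared value remains
    # driven by the members' codon-bias scores
    shared <- cohorts |>
      select("cohort", "gene_id") |>
      left_join(out |> select("gene_id", "true_protein"), by = "gene_id") |>
      group_by(.data$cohort) |>
      mutate(shared_protein = exp(mean(log(.data$true_protein)))) |>
      ungroup() |>
      select("gene_id", "shared_protein")
    out <- out |>
      left_join(shared, by = "gene_id") |>
      mutate(true_protein = ifelse(is.na(.data$shared_protein),
                                   .data$true_protein,
                                   .data$shared_protein),
             protein = ifelse(is.na(.data$shared_protein), .data$protein,
                              .data$shared_protein)) |>
      select(-"shared_protein")
  }
  out
}

# pseudo-counts proportional to a usage table's fractions, for weight fitting
usage_to_counts <- function(usage) {
  usage |>
    mutate(count = .data$fraction * 1000) |>
    select("codon", "aa", "count")
}

#' Sample synthetic proteome evidence
#'
#' Emulates shotgun-proteomics under-sampling: each protein's expected unique
#' peptide count is proportional to its abundance share times its length in
#' kbp, scaled by the sampling `depth`, then Poisson-sampled. Coverage is
#' Beta-distributed with mean increasing in peptides per length; zero
#' peptides give zero coverage. Protein length in aa is derived from the CDS
#' length (stop codon excluded).
#'
#' @param expression Result of [sim_expression()].
#' @param config The same [sim_config()].
#' @return Tibble `gene_id`, `unique_peptides`, `coverage`,
#'   `protein_length_aa`, `cds_length_bp`, `mrna_level`.
#' @export
sim_proteome_evidence <- function(expression, config) {
  set.seed(config$seed + 2L)
  n <- nrow(expression)
  share <- expression$protein / sum(expression$protein)
  lambda <- config$depth * share * n * expression$length_kbp
  peptides <- rpois(n, lambda)
  mu <- peptides / (peptides + 10)
  nu <- 20
  coverage <- ifelse(peptides == 0, 0,
                     rbeta(n, mu * nu + 1e-9, (1 - mu) * nu + 1e-9))
  tibble(gene_id = expression$gene_id,
         unique_peptides = peptides,
         coverage = coverage,
         protein_length_aa = expression$length_bp / 3 - 1,
         cds_length_bp = expression$length_bp,
         mrna_level = expression$mrna)
}

#' Partition genes into complex-style cohorts
#'
#' Picks disjoint cohorts of genes with sizes uniform over
#' `cohort_size_range`. When the cohort map is passed to
#' [sim_expression()], members of each cohort are assigned one shared true
#' protein abundance (zero within-cohort variance before evidence sampling)
#' — the structure that makes cohort-level aggregation outperform gene-level
#' comparison under peptide under-sampling.
#'
#' @param config A [sim_config()].
#' @param gene_ids Character vector of available gene ids.
#' @return Tibble `cohort`, `gene_id`.
#' @export
sim_cohorts <- function(config, gene_ids) {
  set.seed(config$seed + 3L)
  sizes <- sample(seq(config$cohort_size_range[1L],
                      config$cohort_size_range[2L]),
                  config$n_cohorts, replace = TRUE)
  if (sum(sizes) > length(gene_ids)) {
    abort("not enough genes for the requested cohorts")
  }
  members <- sample(gene_ids, sum(sizes))
  tibble(cohort = rep(sprintf("cohort%02d", seq_along(sizes)), sizes),
         gene_id = members)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [sim_genes()], [sim_cohorts()] (when
#' `with_cohorts`), [sim_expression()] and [sim_proteome_evidence()] under
#' one configuration.
#'
#' @param config A [sim_config()].
#' @param with_cohorts Also generate complex-style cohorts.
#' @return List with `cds`, `annotation`, `truth`, `expression`, `evidence`,
#'   and (optionally) `cohorts`.
#' @export
sim_dataset <- function(config, with_cohorts = FALSE) {
  genes <- sim_genes(config)
  cohorts <- if (with_cohorts) sim_cohorts(config, genes$cds$gene_id)
  expression <- sim_expression(genes, config, cohorts = cohorts)
  evidence <- sim_proteome_evidence(expression, config)
  c(genes, list(expression = expression, evidence = evidence,
                cohorts = cohorts))
}
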