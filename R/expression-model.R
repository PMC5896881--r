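# The sequence-only expression predictor: length-adjusted CAI score,
# exponential trend fit, relative/absolute abundance estimation, and
# evaluation against observed expression tables.

#' Length-adjusted CAI score
#'
#' The sequence-only expression predictor: `score = CAI - c * sqrt(L)` with
#' `L` the coding-sequence length in kbp (full stored length, stop codon
#' included) and penalty coefficient `c` defaulting to 0.03. Shorter genes
#' make more mRNA, so the penalty rewards short coding sequences.
#'
#' @param data Tibble with columns `cai` and `length_bp`.
#' @param c Length-penalty coefficient (per sqrt-kbp), default 0.03.
#' @return The input with added columns `length_kbp` and `score`.
#' @examples
#' length_adjusted_cai(tibble::tibble(cai = 0.782, length_bp = 1000))
#' @export
length_adjusted_cai <- function(data, c = 0.03) {
  if (any(data$length_bp <= 0)) abort("length_bp must be positive")
  data |>
    mutate(length_kbp = .data$length_bp / 1000,
           score = .data$cai - c * sqrt(.data$length_kbp))
}

#' Fit the exponential trend linking score to expression
#'
#' Ordinary least squares of natural-log expression on the length-adjusted
#' score: `log(y) = alpha + beta * s`, i.e. the exponential trend-line
#' `y = exp(alpha) * exp(beta * s)`. Genes with zero or missing observed
#' expression are dropped (log undefined) and their number recorded.
#' Optionally the top fraction of genes by observed value is excluded before
#' fitting, for use where the most abundant transcripts depart from the
#' trend.
#'
#' @param data Tibble with the score and observed-expression columns.
#' @param score,observed Column names (unquoted or strings via
#'   \link[rlang]{sym}) holding the predictor score and observed expression.
#' @param exclude_top_fraction Fraction in \[0, 1) of the highest observed
#'   values excluded before fitting.
#' @return Object of class `trend_fit` with elements `alpha`, `beta`, `r`
#'   (Pearson correlation of score with log expression; 0 with
#'   `r_defined = FALSE` when the response is degenerate), `n_fit`,
#'   `n_dropped`, and the fitting data.
#' @export
fit_trend <- function(data, score = "score", observed = "observed",
                      exclude_top_fraction = 0) {
  s_col <- rlang::as_name(rlang::ensym(score))
  o_col <- rlang::as_name(rlang::ensym(observed))
  s <- data[[s_col]]
  y <- data[[o_col]]
  keep <- !is.na(s) & !is.na(y) & y > 0
  n_dropped <- sum(!keep)
  s <- s[keep]
  y <- y[keep]
  if (exclude_top_fraction > 0) {
    if (exclude_top_fraction >= 1) abort("exclude_top_fraction must be < 1")
    cut <- stats::quantile(y, 1 - exclude_top_fraction, type = 1)
    low <- y <= cut
    s <- s[low]
    y <- y[low]
  }
  if (length(y) < 3L) abort("need at least 3 genes with positive expression")
  if (sd(s) == 0) abort("degenerate design: all scores identical")
  ly <- log(y)
  fit <- lm(ly ~ s)
  r_defined <- sd(ly) > 0
  r <- if (r_defined) cor(s, ly) else 0
  structure(list(alpha = unname(coef(fit)[1L]),
                 beta = unname(coef(fit)[2L]),
                 r = r, r_defined = r_defined,
                 n_fit = length(y), n_dropped = n_dropped,
                 data = tibble(score = s, log_observed = ly)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Exponential trend: y = %.4g * exp(%.4g * s)\n",
              exp(x$alpha), x$beta))
  cat(sprintf("  n = %d (dropped %d), Pearson r (score vs log y) = %.3f%s\n",
              x$n_fit, x$n_dropped, x$r,
              if (x$r_defined) "" else " [degenerate response]"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta, r = x$r, n_fit = x$n_fit,
         n_dropped = x$n_dropped)
}

#' @export
predict.trend_fit <- function(object, newdata, score = "score", ...) {
  s <- if (is.data.frame(newdata)) newdata[[score]] else newdata
  exp(object$alpha + object$beta * s)
}

#' Scatter and trend-line of a fitted expression trend
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot object: score vs observed expression (log scale) with the
#'   fitted exponential trend-line.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  dat <- object$data |> mutate(observed = exp(.data$log_observed))
  ggplot2::ggplot(dat, ggplot2::aes(.data$score, .data$observed)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_function(
      fun = function(s) exp(object$alpha + object$beta * s),
      colour = "red3") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "length-adjusted CAI score", y = "observed expression",
                  subtitle = sprintf("y = %.3g e^(%.3g s),  r = %.2f",
                                     exp(object$alpha), object$beta,
                                     object$r)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Predicted relative expression shares
#'
#' Converts scores into relative abundance through the fitted trend:
#' `y_hat = exp(alpha + beta * s)`, normalized so shares sum to 1.
#'
#' @param data Tibble with `gene_id` and a `score` column.
#' @param model A `trend_fit`.
#' @return Tibble `gene_id`, `score`, `predicted`, `relative_share`.
#' @export
predict_relative <- function(data, model) {
  if (nrow(data) == 0L) abort("no genes to predict")
  data |>
    mutate(predicted = exp(model$alpha + model$beta * .data$score),
           relative_share = .data$predicted / sum(.data$predicted)) |>
    select("gene_id", "score", "predicted", "relative_share")
}

#' Molecules per cell from relative shares
#'
#' Scales relative shares to absolute molecule counts given a per-cell total
#' (defaults in this organism's literature: 19,000 non-VSG mRNAs and 1e8
#' non-VSG proteins per cell). Excluded genes (e.g. VSGs, pol-I transcribed
#' genes, whose expression is dominated by transcription rather than codon
#' usage) are removed before renormalization.
#'
#' @param estimates Tibble with `gene_id` and `relative_share`.
#' @param total Total molecules per cell to distribute.
#' @param exclude Character vector of gene ids removed before renormalizing.
#' @return Tibble `gene_id`, `relative_share` (renormalized),
#'   `molecules_per_cell`.
#' @export
molecules_per_cell <- function(estimates, total = 19000,
                               exclude = character()) {
  if (total <= 0) abort("total must be positive")
  kept <- filter(estimates, !.data$gene_id %in% exclude)
  kept |>
    mutate(relative_share = .data$relative_share /
             sum(.data$relative_share),
           molecules_per_cell = total * .data$relative_share) |>
    select("gene_id", "relative_share", "molecules_per_cell")
}

#' mRNA-adjusted protein abundance estimates
#'
#' Rescales sequence-based protein estimates by the ratio of observed to
#' predicted mRNA — a proxy adjustment for gene copy-number, since tandem
#' gene amplification raises observed mRNA above the single-copy sequence
#' prediction. `adjusted_i` is proportional to
#' `protein_i * observed_mrna_i / predicted_mrna_i`, renormalized to shares.
#' Genes with zero predicted mRNA are dropped with a message.
#'
#' @param data Tibble with `gene_id`, `protein_share`, `observed_mrna`,
#'   `predicted_mrna`.
#' @return Tibble `gene_id`, `adjusted_share`.
#' @export
mrna_adjusted_protein <- function(data) {
  drop <- data$predicted_mrna == 0 | is.na(data$predicted_mrna)
  if (any(drop)) {
    inform(paste0("dropping ", sum(drop),
                  " gene(s) with zero predicted mRNA"))
    data <- data[!drop, ]
  }
  data |>
    mutate(adjusted = .data$protein_share * .data$observed_mrna /
             .data$predicted_mrna,
           adjusted_share = .data$adjusted / sum(.data$adjusted)) |>
    select("gene_id", "adjusted_share")
}

#' Fraction of genes predicted within k-fold of observation
#'
#' For each fold-threshold `k`, the fraction of genes whose predicted and
#' observed values agree within k-fold: `max(pred/obs, obs/pred) <= k`
#' (boundary inclusive). Monotone non-decreasing in `k`.
#'
#' @param data Tibble with paired positive `predicted` and `observed`
#'   columns (names overridable).
#' @param k Numeric vector of fold thresholds, each >= 1.
#' @param predicted,observed Column names.
#' @return Tibble `k`, `fraction`.
#' @export
fold_agreement <- function(data, k = c(2, 3, 4, 5), predicted = "predicted",
                           observed = "observed") {
  if (any(k < 1)) abort("fold threshold k must be >= 1")
  p <- data[[predicted]]
  o <- data[[observed]]
  if (any(p <= 0 | o <= 0, na.rm = TRUE)) {
    abort("fold agreement needs positive predicted and observed values")
  }
  ratio <- pmax(p / o, o / p)
  tibble(k = k, fraction = map_dbl(k, function(kk) mean(ratio <= kk)))
}

#' Evaluate scores against observed expression
#'
#' Pearson correlation between a predictor score and natural-log observed
#' expression (or raw observed values with `log_observed = FALSE`, the mode
#' used for mRNA half-life). When a baseline score is supplied (typically raw
#' CAI against the length-adjusted score) the percentage improvement
#' `100 * (r - r_baseline) / r_baseline` is reported.
#'
#' @param data Tibble holding the score(s) and observations.
#' @param score,observed,baseline Column names; `baseline` optional.
#' @param log_observed Correlate against `log(observed)` (default) or raw.
#' @return Tibble `r`, `n`, and when a baseline is given `r_baseline` and
#'   `improvement_percent`.
#' @export
evaluate_scores <- function(data, score = "score", observed = "observed",
                            baseline = NULL, log_observed = TRUE) {
  s <- data[[score]]
  y <- data[[observed]]
  keep <- !is.na(s) & !is.na(y)
  if (log_observed) keep <- keep & y > 0
  s <- s[keep]
  y <- y[keep]
  if (length(y) < 3L) abort("need at least 3 paired values")
  resp <- if (log_observed) log(y) else y
  out <- tibble(r = cor(s, resp), n = length(y))
  if (!is.null(baseline)) {
    b <- data[[baseline]][keep]
    r_b <- cor(b, resp)
    out$r_baseline <- r_b
    out$improvement_percent <- 100 * (out$r - r_b) / r_b
  }
  out
}

#' Cohort-level observed and predicted abundance
#'
#' Aggregates genes into cohorts (protein complexes or functionally related
#' sets) to damp proteomic under-sampling noise. Observed abundance is total
#' unique peptides per total coding kbp; predicted abundance is the mean of
#' the members' predicted relative shares. Members lacking proteome evidence
#' are counted and reported via a message.
#'
#' @param cohorts Tibble `cohort`, `gene_id`.
#' @param evidence Tibble `gene_id`, `unique_peptides`, `cds_length_bp`.
#' @param predictions Tibble `gene_id`, `relative_share`.
#' @return Tibble `cohort`, `n_proteins`, `n_missing_evidence`,
#'   `observed_peptides_per_kbp`, `predicted_abundance`, sorted by observed
#'   peptides/kbp.
#' @export
cohort_summary <- function(cohorts, evidence, predictions) {
  if (nrow(cohorts) == 0L) abort("empty cohort table")
  sizes <- cohorts |> group_by(.data$cohort) |> summarise(n = n())
  if (any(sizes$n == 0L)) abort("empty cohort")
  joined <- cohorts |>
    left_join(evidence, by = "gene_id") |>
    left_join(predictions, by = "gene_id")
  n_missing <- sum(is.na(joined$unique_peptides))
  if (n_missing > 0L) {
    inform(paste0(n_missing, " cohort member(s) lack proteome evidence"))
  }
  joined |>
    group_by(.data$cohort) |>
    summarise(
      n_proteins = sum(!is.na(.data$unique_peptides)),
      n_missing_evidence = sum(is.na(.data$unique_peptides)),
      observed_peptides_per_kbp =
        sum(.data$unique_peptides, na.rm = TRUE) /
        (sum(.data$cds_length_bp, na.rm = TRUE) / 1000),
      predicted_abundance = mean(.data$relative_share, na.rm = TRUE)
    ) |>
    arrange(dplyr::desc(.data$observed_peptides_per_kbp))
}
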