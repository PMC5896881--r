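---
title: "Predicting expression from codon usage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting expression from codon usage: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonexpress)
library(dplyr)
```

## The problem

Trypanosomatids transcribe almost all protein-coding genes constitutively,
in long polycistronic units, with no regulated RNA polymerase II promoters.
Steady-state differences in mRNA and protein abundance — which span several
orders of magnitude — must therefore arise post-transcriptionally. Synonymous
codon usage is a dominant contributor: highly expressed genes are enriched
in GC3 codons (G/C at the third position), matching the wobble tRNA pool,
and codon-optimal mRNAs are both better translated and more stable. This
package computes the codon-usage statistics behind that observation and
turns them into a quantitative, sequence-only predictor of relative
expression.

## The predictor

**CAI.** For a reference set of highly expressed genes, each codon's
relative adaptiveness is
$w_c = f_c / \max_{c' \in \mathrm{fam}(c)} f_{c'}$, where $f$ are usage
frequencies within each synonymous family (Ser/Leu/Arg six-codon sets are
treated as single families). A gene's CAI is the geometric mean of $w$
over its codons. Numerical conventions, all standard practice for small
reference sets:

- zero reference counts are replaced by a 0.5 pseudo-count before
  frequencies are formed, and $w$ is floored at 0.01, so no observed codon
  annihilates the product;
- stop codons and the single-codon families Met and Trp, whose $w$ is
  constitutively 1, are excluded from the mean;
- the mean is computed in the log domain, $\exp(\tfrac1n\sum\log w)$, so
  genes of thousands of codons cannot underflow.

**Length adjustment.** Shorter coding sequences yield more mRNA, so the
predictor is the penalized score
$$s = \mathrm{CAI} - c\,\sqrt{L_{\mathrm{kbp}}}, \qquad c = 0.03,$$
with $L$ the stored CDS length *including* the trailing stop codon — the
published formula leaves "CDS length" unqualified, and the stop is part of
the annotated CDS, so the full length is used consistently everywhere.
$c$ is in units of score per $\sqrt{\mathrm{kbp}}$ and is exposed as an
argument; 0.03 is the default because it is the published coefficient.

**Trend and prediction.** Expression is related to the score by the
exponential trend $\log y = \alpha + \beta s$, fitted by ordinary least
squares of natural-log expression on $s$. The published analyses show
exponential trend-lines without stating the fitting procedure; OLS on the
log scale is the simplest estimator consistent with those figures, and
multiplicative (log-normal) noise is the natural error model for abundance
data. Genes with zero observed expression have no defined log and are
dropped, with the count reported. Predicted relative abundance is the
normalized $\hat y_i = e^{\alpha + \beta s_i}$; molecules per cell scale
those shares by a configurable per-cell total (defaults 19,000 mRNAs and
$10^8$ proteins, the literature values for bloodstream-form *T. brucei*,
always excluding VSG/pol-I genes whose abundance is transcription-driven).

**Evaluation.** Pearson correlation is computed between the score and
log-transformed expression by default. mRNA half-life is the exception —
the published comparison pairs raw CAI with half-life on the raw scale, so
`evaluate_scores(..., log_observed = FALSE)` preserves that mode. Whether
the published correlations used log or raw expression is not stated; log
is this package's default because the trend model is log-linear.
Fold-agreement (`max(pred/obs, obs/pred) <= k`) treats the boundary as
inclusive: a gene exactly 2-fold off counts as "within 2-fold".

**Cohorts.** Individual proteins are undersampled by shotgun proteomics, so
predictions are also evaluated at the level of cohorts (complexes,
functional groups): observed abundance is total unique peptides per total
coding kbp; predicted abundance is the unweighted mean of member shares.
The published aggregation is not stated; the mean was chosen over a
length-weighted mean for symmetry with peptides/kbp already being
length-normalized.

## Cohort construction rules

Reference and analysis sets follow the printed thresholds with strict
inequalities throughout (the rules are printed as ">"): reference genes
encode proteins of more than 250 aa with more than 25 unique peptides and
more than 75% coverage; the proteome analysis set requires more than 3
unique peptides; pol-I-transcribed genes are always excluded. The
*T. vivax* and *L. mexicana* variants (peptides/kbp, tag and FPKM
thresholds, ortholog restriction) are encoded as species rules.

Strand-switch genes are those immediately adjacent to a divergent `(-,+)`
or convergent `(+,-)` polycistron boundary: for every adjacent same-
chromosome gene pair with opposing strands, the flanking gene on each side
is returned. "Immediately adjacent" is parameterized as `flank = 1`
because the published cohort's exact membership cannot be re-derived
without its annotation version; wider flanks are available but are a
different definition. Chromosome-terminal genes are not strand-switch
genes by position alone.

The stage filter removes developmentally regulated genes: retained genes
differ by at most 3-fold (inclusive) between two life-cycle stages.

## Codon-pair bias

Adjacent sense-codon pairs are counted within genes only — pairs never
straddle a stop codon or a gene boundary. The 61×61 pair table is tested
against row/column independence with adjusted Pearson residuals
$z = (O - E)/\sqrt{E\,(1 - \mathrm{row}/N)(1 - \mathrm{col}/N)}$, which
are asymptotically standard normal under independence, making the null
calibration testable (about 5% of cells beyond $|z| > 1.96$ on an
independent-codon genome). The original analysis used a dedicated
codon-pair tool whose internal statistic is unpublished; adjusted
contingency residuals reproduce the figure-level semantics
(over/under-represented pairs) with a calibrated, documented statistic.
Amino-acid-level co-occurrence collapses the counts to 20×20 before the
same computation; positional 4×4 summaries average $z$ by (third base,
first base) and (third, third) combinations. Outputs are descriptive
residuals; no multiple-testing machinery is attached.

## Reporter recoding

Recoding schemes are deterministic: `max_gc3` / `min_gc3` choose a
G/C- or A/T-ending codon per residue (ties broken by usage fraction, then
alphabetically), `alternating` alternates the two target classes by
position, and `table_optimal` takes each family's most frequent codon.
Every multi-codon family contains both third-base classes, so `max_gc3`
designs have GC3 exactly 1, and under `min_gc3` only Met and Trp (sole
codons ATG, TGG) contribute G3. Fixed-codon residues advance the
alternation phase — the alternative (holding the phase) would make the
design depend on Met/Trp placement in a way that is harder to reason
about; the choice is stated here and fixed. Recoded output carries no stop
codon by default (`append_stop = TRUE` adds TAA), so designs map
codon-for-codon onto the input protein.

## The synthetic-data generator

`sim_config()` fixes the study conditions; everything is driven by one
integer seed and nothing else (no time-based entropy), so generation is
reproducible byte-for-byte.

- **Codon bias**: per-gene propensity $t \sim \mathrm{Beta}(2,2)$;
  per-family codon probabilities are $(1-t)\,\mathrm{baseline} +
  t\,\mathrm{optimal}$. Defaults: uniform baseline; optimal table with 80%
  of each family's mass on G/C-ending codons. Amino acids are uniform over
  the 20.
- **Lengths**: log-normal, median 1.2 kbp, sdlog 0.6 — the scale of
  trypanosomatid CDS lengths.
- **Layout**: genes fill fixed-size polycistrons (default 10 genes) whose
  strands alternate along each of 4 chromosomes, so every internal
  polycistron boundary is a strand-switch region; boundary genes have $t$
  multiplied by `ssr_factor` (default 0.3), planting the depressed-CAI
  signal the caller must recover. An optional VSG-like cohort is drawn
  from an A3-enriched table and flagged pol-I.
- **Expression**: $\log(\mathrm{mRNA}) = \alpha + \beta s + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$, with $s$ the length-adjusted CAI under
  weights derived from the generator's own optimal table. Defaults
  $\alpha = 1$, $\beta = 5$, $c = 0.03$, $\sigma = 0.5$. Protein is
  generated conditionally on mRNA (slope 1, extra noise 0.4), so the
  mRNA-protein link carries recoverable signal; optional tandem
  copy-number multipliers scale both layers while remaining invisible to
  sequence-based prediction — the structure the mRNA-adjustment operation
  exploits.
- **Proteome evidence**: expected unique peptides proportional to
  abundance share × length (kbp) × depth, Poisson-sampled; coverage is
  Beta-distributed with mean increasing in peptide yield. Depth 20 gives
  realistic undersampling of low-abundance proteins.
- **Cohorts**: disjoint gene sets (default 23 cohorts of 3–30, the scale
  of the published complex analysis) whose members share one true protein
  abundance — the geometric mean of their individually generated levels —
  so cohort aggregation genuinely outperforms gene-level comparison under
  undersampling.

What the generator does **not** emulate: untranslated-region regulation,
amino-acid composition bias, tryptic-digestion peptide detectability, read
mapping artefacts, or real gene-family redundancy. Passing tests therefore
validate the statistical machinery under the model's own assumptions; they
do not certify performance on real genomes, where the score-expression
correlation is substantially weaker (published r ≈ 0.5 for mRNA) than in
clean simulations. One visible consequence of keeping the specified
Beta(2,2) propensity with an unadapted baseline table is that synthetic
CAI values concentrate around 0.5–0.7 when scored against the generator's
optimal-table weights, a narrower and lower band than the 0.6–0.9 of the
real genome; weights estimated from the synthetic reference set (as in the
README example) sit higher. Absolute CAI level affects no calibration
result, which are all relative or slope-based.

## Validation problem sizes

The test suite validates the CAI implementation against a brute-force
product-then-root oracle (500 random genes of up to 60 codons, agreement
to 1e-12), recovers the trend slope within 5% on a 5,000-gene genome
(β = 5, σ = 0.3), confirms that the √length penalty improves correlation
exactly when the generating process contains it, checks the 2-fold
agreement calibration (σ = ln 2/1.0364 puts 70% of genes within 2-fold;
observed fraction must fall in [0.67, 0.73] at n = 5000), calibrates
pair-bias residuals on a 2,000-gene independent-codon genome, and recovers
100% of planted strand-switch genes. These sizes were chosen so each
property is measured with comfortable statistical margin at desk scale.

## Known limitations

- CAI values on real genomes depend mildly on the zero-count convention of
  the weight calculator; third-decimal agreement with published tables is
  not guaranteed.
- The exact published strand-switch and VSG cohort memberships are not
  re-derivable from printed information; only the qualitative contrast
  (depressed CAI) is testable.
- The predictor is single-score OLS by design; it does not model UTR
  regulation, protein turnover, or stage-specific expression, and
  cell-cycle or membrane-protein cohorts are expected to deviate from the
  trend.
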