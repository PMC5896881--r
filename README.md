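# codonexpress

Codon usage bias and sequence-based expression prediction for
trypanosomatids.

Trypanosomatid parasites (*Trypanosoma brucei*, *T. vivax*, *Leishmania*
spp.) transcribe nearly all protein-coding genes constitutively in
polycistronic units, so differences in steady-state mRNA and protein
abundance arise post-transcriptionally — to a large extent from synonymous
codon usage. In these genomes GC3 codons (G or C at the third, wobble
position) mark highly expressed genes, and relative expression can be
predicted from the coding sequence alone.

`codonexpress` implements that analysis end to end for R users:

- **Codon statistics** — codon counting, per-family usage tables, GC3,
  Codon Adaptation Index (CAI) weights and scores, and codon
  over/under-representation maps. CAI is the geometric mean over a gene's
  codons of relative adaptiveness values
  *w*(codon) = *f*(codon) / max *f*(synonym), with *f* the usage
  frequencies in a reference set of highly expressed genes (zero counts get
  a 0.5 pseudo-count; *w* is floored at 0.01; stops, Met and Trp are
  excluded from the mean).
- **Expression prediction** — the length-adjusted score
  *s* = CAI − 0.03·√(*L*/kbp), the fitted exponential trend
  log *y* = α + β·*s*, relative shares, molecules-per-cell estimates
  (19,000 non-VSG mRNAs / 10⁸ non-VSG proteins per cell by default),
  mRNA-adjusted protein estimates, fold-agreement and correlation
  evaluation, and cohort-level (protein complex) aggregation.
- **Codon-pair bias** — adjusted Pearson residuals on the 61×61 adjacent
  codon-pair contingency table, with amino-acid-level and positional
  (third→first, third→third base) aggregations.
- **Genome context** — highly-expressed reference sets and per-species
  analysis sets from proteome/transcriptome evidence, strand-switch-region
  gene calling, and a developmental-stage stability filter.
- **Reporter design** — deterministic synonymous recoding with maximal GC3,
  minimal GC3, alternating GC3/AT3, or table-optimal codons, with design
  verification.
- **Synthetic genomes** — a fully seeded generator of coding sequences with
  tunable codon bias, polycistronic chromosome layouts with strand-switch
  regions, log-linear expression, a conditional protein layer and
  undersampled proteome evidence, so the whole pipeline can be exercised
  and validated without external data.

I/O helpers read CDS FASTA, genome FASTA + GFF3, and TSV
expression/proteome/cohort/ortholog tables, and write per-gene CAI bedGraph
tracks. All user-facing functions take a data frame first and return
tibbles, so steps chain with the pipe; fitted trends support `tidy()`,
`glance()`, `predict()` and `autoplot()`.

## Worked example

Score a (here synthetic) genome, fit the expression trend, and predict
abundance:

```r
library(codonexpress)
library(dplyr)

cfg <- sim_config(seed = 7, n_genes = 2000, sigma = 0.3)
d   <- sim_dataset(cfg)   # cds, annotation, truth, expression, evidence

# reference set: proteins > 250 aa, > 25 unique peptides, > 75% coverage
ref <- select_reference_set(d$evidence)
w   <- cai_weights(count_codons(filter(d$cds, gene_id %in% ref),
                                drop_stops = TRUE), reference_ids = ref)

scored <- d$cds |>
  mutate(cai = cai(seq, w)) |>
  length_adjusted_cai()                   # adds score = cai - 0.03 sqrt(L)

obs <- left_join(scored, select(d$expression, gene_id, mrna), "gene_id")
fit <- fit_trend(obs, score, mrna)
fit
#> Exponential trend: y = 0.1308 * exp(7.739 * s)
#>   n = 2000 (dropped 0), Pearson r (score vs log y) = 0.736

pred <- predict_relative(scored, fit)
molecules_per_cell(pred, total = 19000,
                   exclude = d$annotation$gene_id[d$annotation$is_VSG])
#> # A tibble: 1,980 x 3
#>   gene_id relative_share molecules_per_cell
#>   <chr>            <dbl>              <dbl>
#> 1 g00001        0.00108               20.5
#> 2 g00002        0.000364               6.92
#> 3 g00003        0.000360               6.84
#> # ...

evaluate_scores(obs, score = "score", observed = "mrna", baseline = "cai")
#> # A tibble: 1 x 4
#>       r     n r_baseline improvement_percent
#>   <dbl> <int>      <dbl>               <dbl>
#> 1 0.736  2000      0.725                1.61
```

The trend says an increase of 0.1 in the length-adjusted score multiplies
expected expression by e^0.77 ≈ 2.2; the evaluation says the score
correlates with log mRNA at r = 0.74 on this genome, and the √length
penalty improves on raw CAI by 1.6%. Strand-switch genes show the expected
depressed codon adaptation:

```r
ssr <- strand_switch_genes(d$annotation)
mean(scored$cai[scored$gene_id %in% ssr])   # 0.739
mean(scored$cai)                            # 0.783
```

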