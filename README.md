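# rippmine

Deep-learning metagenome mining of RiPP precursors and prokaryote–phage
interactions, at desk scale and fully offline.

Ribosomally synthesized and post-translationally modified peptides
(RiPPs) are short genetically encoded natural products: a precursor
peptide (leader + core) matured by neighboring tailoring enzymes.
Classic genome mining finds RiPP biosynthetic gene clusters by spotting
intact modification enzymes — which fails on highly fragmented
metagenomic contigs where the enzyme genes are missing or truncated.
`rippmine` implements the alternative, hallmark-gene-independent route
for the analysts who need it: classify the precursor itself, then use
whatever genomic context *is* available to grade the call, group
precursors into families, and connect RiPP-encoding hosts to their
phages.

The package provides, as composable data-frame-in / tibble-out
functions:

* **Precursor classifier** — a Transformer encoder (4 layers, 4 heads,
  d = 128) + two Bi-LSTM layers (hidden 64) + feed-forward head over the
  concatenated max/mean/last outputs, trained with focal loss
  `FL = -(1 - p_c)^γ log p_c` (γ = 1) under AdamW with a linear
  warmup/decay schedule and early stopping. The network and its
  backpropagation are implemented in vectorised base R and
  gradient-checked against finite differences. Nine RiPP classes +
  non-RiPP; the ROC score is `1 − P(non-RiPP)`.
* **Evaluation** — binary (RiPP vs non-RiPP) accuracy, precision,
  recall, F1, MCC and trapezoidal AUROC; multiclass accuracy, weighted
  F1 (predicted-count weights, with the conventional weighting behind a
  flag) and Cohen's kappa; stratified k-fold cross-validation; an
  identity-binned generalization benchmark.
* **Dereplication** — greedy UCLUST-style clustering (90% identity for
  train/test hygiene, 60%/60% for RiPP families, 95% ANI / 85% AF for
  vOTUs) with a split that provably keeps near-duplicates out of the
  test set.
* **Rule engines** — small-ORF admission (complete ends, 45–450 bp,
  RBS unless the phylum is exempt), the four exclusive validity levels
  (PTM > RiPP-related > AA > None) from filtered domain hits in a
  ten-gene neighborhood, family confidence, and MGE/defense keyword
  categorization.
* **Host–phage linkage** — viral-contig triage (BUSCO < 0.067 or ≥ 3
  VPF hits, k-mer rescue, hallmark/completeness removal), alternative
  genetic-code selection (≥ 1.2× the standard code's cumulative coding
  score), CRISPR-spacer matches (≤ 2 bases difference, both strands),
  shared tRNAs (promiscuous sequences removed), prophage alignments
  (≥ 2500 bp at ≥ 70% identity with viral/host coverage rules), and a
  deduplicated evidence network.
* **Metatranscriptomics** — read-alignment filtering (score ≥ 120,
  identity ≥ 95%, ≥ 45 bases; ambiguous and single-mate inserts
  dropped), family count aggregation, ≥ 6-sample prevalence filtering,
  hypergeometric module enrichment.
* **Synthetic fixtures** — seeded generators for every input class with
  planted ground truth, so the full stack is testable with no downloads.

## Worked example

Train a compact classifier on synthetic, compositionally separable
peptides, then predict and evaluate:

```r
library(rippmine)

fx <- gen_peptide_dataset(
  n_per_class = 40,
  classes = c("lanthipeptide", "non-RiPP", "cyanobactin"), seed = 3
)
cfg <- ripp_model_config(
  n_encoder_layers = 2, n_heads = 2, d_embed = 32, d_ff_encoder = 64,
  n_lstm_layers = 2, lstm_hidden = 16, d_ff_head = 32, dropout = 0.2
)
tc <- ripp_train_config(
  peak_lr = 2e-3, warmup_steps = 20, max_epochs = 8, patience = 8,
  batch_size = 32, seed = 2
)
fit <- train_ripp(fx$data, cfg, tc)
glance(fit)
#> # A tibble: 1 × 6
#>   epochs best_epoch best_val_loss final_train_loss n_params variant
#>    <int>      <int>         <dbl>            <dbl>    <int> <chr>
#> 1      8          8        0.0857            0.159    38570 full

newpep <- gen_peptide_dataset(
  n_per_class = 3, classes = c("lanthipeptide", "non-RiPP"), seed = 77
)$data
predict(fit, newpep)[, c("id", "predicted_class", "prob", "ripp_score")]
#> # A tibble: 6 × 4
#>   id                predicted_class  prob ripp_score
#>   <chr>             <chr>           <dbl>      <dbl>
#> 1 lanthipeptide_001 lanthipeptide   0.676      0.903
#> 2 lanthipeptide_002 lanthipeptide   0.656      0.919
#> 3 lanthipeptide_003 lanthipeptide   0.664      0.911
#> 4 non_RiPP_001      non-RiPP        0.768      0.232
#> 5 non_RiPP_002      non-RiPP        0.719      0.281
#> 6 non_RiPP_003      non-RiPP        0.763      0.237

glance(evaluate_predictions(newpep$class, predict_probs(fit$model, newpep$sequence)))
#> # A tibble: 1 × 9
#>   accuracy precision recall    f1   mcc auroc mc_accuracy mc_weighted_f1
#> 1        1         1      1     1     1     1           1              1
```

Every `prob` row is the softmax probability of the predicted class;
`ripp_score` is the binary ROC score `1 − P(non-RiPP)`. Downstream, the
same fitted object plugs into `crossvalidate_ripp()`,
`identity_binned_eval()`, and the context/linkage engines; `tidy()`,
`glance()` and `autoplot()` methods cover the fit, metric and CV
objects. A thin command-line dispatcher over the same functions ships in
`inst/cli/rippmine.R`.

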