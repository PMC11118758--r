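---
title: "Methods: models, rules and design choices in rippmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in rippmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rippmine` is a desk-scale implementation of a deep-learning metagenome
mining stack for ribosomally synthesized and post-translationally
modified peptides (RiPPs): a precursor-peptide classifier, the small-ORF
and genomic-context rule engines around it, greedy identity clustering,
viral triage with host–phage linkage, and metatranscriptomic abundance
plumbing. External heavy tools (gene callers, HMMER/BLAST searches,
virus detectors, WGCNA) are *consumed as tabular inputs*, never re-run:
every function takes a data frame and returns a tibble, so pipelines
compose with the pipe.

# The precursor classifier

## Model

Precursors are short peptides (up to 150 residues). Sequences are
tokenized with a frozen vocabulary: id 0 = padding, id 1 = any
non-canonical residue, ids 2–21 = the twenty canonical amino acids in
alphabetical one-letter order. Freezing the vocabulary (and the class
order: nine RiPP classes alphabetically, non-RiPP last) makes serialized
weights portable.

The network is a Transformer encoder followed by a bidirectional LSTM
stack and a feed-forward head:

* token embedding + **learned** positional embedding (dimension 128).
  A learned table was chosen over fixed sinusoids; at 150 positions the
  distinction is immaterial and a learned table matches the encoder
  family the architecture derives from.
* 4 encoder layers, 4 attention heads, feed-forward width 256,
  post-layer-norm residual blocks. Padded positions are masked out of
  the attention keys, so a sequence's representation is independent of
  its batch mates — asserted to 1e-5 in the tests.
* 2 stacked Bi-LSTM layers with 64 hidden units per direction. Padded
  steps carry the previous state through unchanged, which makes the
  final state the state at the last *real* residue.
* pooling concatenates the per-position maximum, the masked mean, and
  the output at the last unpadded position ("last output" is read as the
  final element of the output sequence, both directions included).
* two dense layers (width 192, ReLU) and a softmax over 10 classes.

Dropout (single rate, default 0.4) is applied where the architecture
description places it: on the attention weights, on each encoder
sublayer output, between the LSTM layers, and between the head's dense
layers. Evaluation mode applies no dropout and is exactly deterministic.

The network, its backpropagation and the AdamW optimizer are implemented
in vectorised base R inside the package; gradients of every variant are
verified against central finite differences on a small configuration in
the test suite (relative error below 1e-3 at step size 1e-5).

## Ablation variants

`variant` in `ripp_model_config()` switches between the full model and
three reduced forms used for ablation: `lstm_only` drops the encoder
(token embedding feeds the Bi-LSTM directly, no positional table),
`transformer_cls` drops the Bi-LSTM and classifies from a prepended CLS
token's encoding, and `transformer_max` classifies from the masked
max-pool of the encoder output.

## Loss and score

Training minimises the focal loss
`FL = -(1 - p_c)^gamma * log(p_c)` with `gamma = 1`, which down-weights
easy examples under the heavy non-RiPP class imbalance; `gamma = 0`
recovers plain cross-entropy exactly (a tested identity). Probabilities
are clamped at 1e-12 inside the log so the loss is never infinite. Batch
reduction is the arithmetic mean — the conventional choice, and the one
that keeps step sizes comparable across batch sizes. The ROC score of a
peptide is `1 - P(non-RiPP)`.

## Training protocol

`ripp_train_config()` defaults encode the published protocol: AdamW,
learning rate warmed linearly from 0 to 0.001 over the first 10,000
steps and then decayed linearly to 0 at the last scheduled step (total
steps = `max_epochs` x steps per epoch, fixed up front), at most 200
epochs, early stopping after 50 epochs without improvement, batch size
128. Because the protocol names no validation set, the package carves a
stratified 10% of the training records and monitors validation loss;
the best-validation weights are restored at the end. With a fixed seed
the loss history is bit-reproducible on CPU.

Desk-scale runs in the tests and the acceptance script use the same
machinery with smaller sizes — 200 synthetic peptides, batch 32, a
30-step warmup and 20 scheduled epochs — which saturates training
accuracy on separable synthetic data in a few minutes on one CPU. These
sizes are the package's own test-design choice.

## Metrics

`evaluate_predictions()` computes both views. The binary view collapses
the nine RiPP classes to "RiPP" and derives accuracy, precision, recall,
F1 and the Matthews correlation coefficient from TP/TN/FP/FN counts;
AUROC integrates the ROC of the RiPP score by the trapezoidal rule over
all score thresholds (ties grouped). The multiclass view reports
accuracy, weighted F1, and Cohen's kappa with chance agreement
`p_e = (1/N^2) * sum_c n_c1 * n_c2`.

One documented quirk: the weighted-F1 weight `N_c` is the number of
**predictions** in class c, which differs from the conventional
true-count weighting. The printed form is the default
(`weights = "predicted"`); the conventional form is available via
`weights = "true"`. Ratios with zero denominators are reported as 0 and
flagged in the result's `flags` field rather than propagating NaN, which
matches common tooling and keeps downstream aggregation total.

## Dereplication and splitting

`dedup_split()` clusters all sequences greedily at the identity
threshold (default 90%, coverage 90% of the shorter sequence), keeps the
founding (longest) member of each cluster as representative, samples a
stratified 10% of representatives as the test set, and trains on the
remaining representatives plus their cluster members. Members of
test-selected clusters are excluded entirely — the only reading under
which no test sequence can be threshold-similar to any training
sequence, which the tests verify with an alignment-free upper bound
(longest-common-subsequence matches over the shorter length, an upper
bound on any alignment's identity).

Cross-validation folds are stratified and seeded; dereplication is done
once before folding, not per fold. The generalization benchmark
(`identity_binned_eval()`) bins each test record by its best global
identity against the training set (deciles; records with no
positive-scoring hit fall into the lowest bin; empty bins are absent,
not zero).

# Rule engines

## Small-ORF screen

A call is admitted iff it is complete on both ends (Prodigal
`partial=00`), spans 45–450 bp inclusive (the span includes the stop
codon — the minimum-length convention chosen here), and either carries
an RBS motif or belongs to one of the RBS-exempt phyla (Cyanobacteria,
Chlorobi, Chlamydiae, Ignavibacteriae, Verrucomicrobia; matched
case-insensitively). An unknown taxon conservatively requires the RBS.
"Has RBS" trusts the caller's `rbs_motif` attribute (present and not
"None"); the package does not re-detect Shine–Dalgarno motifs.

## Validity levels

Domain hits are pre-filtered by source: profile (HMM) hits need
score > 0 (strict), PSSM hits need e-value <= 0.001 *and* at least 80%
of the PSSM length aligned (both inclusive); keyword hits pass through.
The four exclusive levels then cascade over the ten-gene neighborhood
(gene ranks on the same contig, strand ignored, windows clipped at
contig ends, the precursor's own gene included — the level-2 wording
explicitly includes the encoding gene, and the same reading is applied
to level 1):

1. **PTM** — class-defining domain present and the intrinsic residue
   predicate satisfied;
2. **RiPP-related** — otherwise, any RiPP-related domain (transporters
   and similar, a configurable list) in the window;
3. **AA** — otherwise, residue predicate satisfied;
4. **None** — otherwise.

Classes without intrinsic amino-acid requirements (autoinducing
peptides, head-to-tail cyclized peptides, cyanobactins, other RiPPs) can
only ever reach RiPP-related or None. The shipped per-class rule table
(`inst/extdata/ripp_class_rules.yaml`) marks the lasso peptide,
graspetide, thiopeptide and rSAM entries as *provisional* package
defaults — the complete curated table is not in the public text — and
the whole table is user-overridable. A family is "high confidence" iff
at least one member sits at PTM or RiPP-related.

MGE categorization is keyword-based with precedence Defense > Phage >
Other-MGE > other; matching is case-insensitive on whole words (tokens
split at non-alphanumerics, so "virus" never fires on "virulence"), and
membership in a configurable defense Pfam list also triggers Defense.

## Clustering

`greedy_cluster()` is UCLUST-style: length-sorted (descending, ties by
input order), each sequence joins the earliest-founded representative
meeting both thresholds, else founds a cluster. Identity is matches over
alignment columns of a local alignment (BLOSUM62, gap open 11 / extend
1); coverage is the aligned span over the shorter sequence's length,
mirroring coverage-mode-2 semantics. Family construction uses 60%/60%,
dereplication 90%/90%. Because the upstream tools' exact identity
definitions are version-dependent, the package documents its own and the
tests pin behaviour to an independently coded brute-force greedy oracle
rather than to third-party bit-parity. `votu_cluster()` applies the same
greedy semantics to precomputed ANI records at 95% ANI / 85% aligned
fraction, both inclusive.

## Viral triage, genetic codes, host–phage links

Triage: a contig is putative viral iff the similarity tool flagged it
and (BUSCO ratio < 0.067 or >= 3 VPF hits); otherwise a k-mer rescue
(score > 0.9, p < 0.05) applies. The text is ambiguous about whether the
rescue covers all remaining contigs or only unflagged ones; both are
implemented (`rescue_scope`), defaulting to all. Putative virals with no
hallmark gene or "Not-determined" completeness are removed.

Genetic code: the alternative code (25, 15 or 90) replaces the standard
code 11 iff its cumulative coding score is strictly highest and at least
1.2x the standard score (boundary inclusive); the decision is invariant
to rescaling all scores.

Host–phage evidence channels: (1) CRISPR spacers matched into phage
contigs by exhaustive semi-global search on both strands at at most 2
bases difference — substitutions and gap bases combined, since the
difference is counted over an alignment; (2) shared tRNAs at Levenshtein
distance <= 2, after removing viral tRNAs within distance 2 of any
promiscuous sequence; (3) prophage alignments: HSPs at >= 70% identity,
host-side spans merged when overlapping or adjacent, total >= 2500 bp,
with >= 30% of the viral contig covered and >= 30% of the host contig
outside the merged region. The "outside" fraction uses the merged
region — the reading consistent with treating the merged span as *the*
prophage — rather than the single best HSP. All thresholds are
inclusive. Pairs are deduplicated across channels with their evidence
concatenated.

## Metatranscriptomic plumbing

Read alignments are kept at score >= 120, identity >= 95% and >= 45
aligned bases (all inclusive). For paired libraries an insert needs both
mates on the same gene; an insert whose best insert-level score ties
across more than one gene is ambiguous and dropped (the tie rule is the
package's definition — the source text does not define "ambiguous").
Counting is per insert, not per read. Family counts sum inserts over
member genes; column sums equal retained inserts (a tested conservation
law). Features seen in fewer than six samples are dropped before
co-expression work. Module enrichment is the upper-tail hypergeometric
probability `P(X >= k)` via `stats::phyper`. Variance stabilization and
module detection themselves are out of scope: the package emits the
filtered matrix and ingests module assignments.

# Synthetic fixtures

The generators exist to make every stage testable offline with known
ground truth; they are pure functions of their seed. The peptide
generator draws each class from an invented preferred-residue profile
(70% of probability mass on 4 class-specific residues; non-RiPP is
uniform), with a 20-residue leader plus a 20–40-residue core, and
constructively guarantees Cys and Ser/Thr in lanthipeptide-like records.
These profiles guarantee *learnability and rule coverage*; they do not
model real precursor composition, leader/core grammar, homology
structure, or database noise — so a passing learnability test shows the
optimizer and architecture work, not that real-data accuracy would be
reproduced. The genome, phage and expression generators plant their
evidence (domain offsets including the 10/11 window boundary, spacer
distances 0–3, prophage spans straddling 2499/2500 bp, alignment rows
straddling each filter threshold, block-correlated counts) and write the
expected outcome into a manifest that the test suite replays against the
real implementations.

# Numerical choices and degenerate inputs

* focal-loss probability clamp 1e-12; layer-norm epsilon 1e-5; AdamW
  (beta1 0.9, beta2 0.999, eps 1e-8, decoupled weight decay 0.01).
* attention tie-breaks: `max.col(ties.method = "first")` throughout, so
  argmax-style choices are deterministic.
* sequences longer than `max_len` are truncated with a warning, not
  rejected — metagenomic callers occasionally emit slightly longer ORFs.
* non-canonical residues align as mismatching unknowns (mapped to X
  before scoring); empty sequences are input errors.
* zero-denominator metrics return 0 and are flagged; empty ROC classes
  likewise.
* clustering of a single sequence yields one singleton cluster;
  identity searches with no positive-scoring hit report identity 0 with
  a `no_hit` flag.

# Known limitations

* The classifier is trained from scratch at desk scale; no published
  weights are reproduced, and ocean-scale corpus statistics are out of
  reach by design.
* The per-class residue-requirement table is partly provisional (see
  above) and should be overridden with a curated table for real use.
* Alignment-based steps are exhaustive and quadratic; they are meant for
  fixtures and small studies, not millions of contigs.
* The spacer search honors the published BLAST parameters only when
  parsing externally produced tabular hits; internally it is exact
  (no seeding heuristics), which at desk scale is strictly more
  sensitive.
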