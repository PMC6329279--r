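---
title: "Methods: biased matrix factorization embeddings of expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biased matrix factorization embeddings of expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`genevec` fits a two-layer collaborative-filtering model to a log2
expression matrix of n samples by k genes. Each gene a carries an
m-dimensional entity vector $G_a$, each sample i a vector $S_i$, and the
predicted expression of gene a in sample i is

$$\hat G_{ai} = G_a \cdot S_i^T + b_a + b_i$$

with scalar gene and sample biases. The model is symmetric in its two
factors — transposing the input and exchanging the roles of genes and
samples yields the same optimization problem — and the package's trainer
preserves that symmetry exactly (it is asserted to floating-point
equality in the test suite). The biases absorb per-gene baseline
abundance and per-sample depth effects, so the vectors are free to encode
co-variation structure; an additive constant on the whole matrix is
likewise absorbed by the biases.

The default dimension is m = 50, a deliberately generous width for
whole-transcriptome compendia; the synthetic studies in this package use
m = 10 against rank-5 ground truth, which is the same regime (m at least
the true rank) at desk scale.

### Input convention

Expression values are RSEM-style normalized counts. Counts below 1 are
regarded as noise and replaced by 1, then the matrix is log2-transformed,
so every value is finite and non-negative and a raw count of 1 or less
maps exactly to 0. TCGA-style composite identifiers ("TP53|7157") resolve
to symbols, falling back to the full composite string when two rows would
collide or the symbol is unknown ("?|100130426"). Samples whose TCGA
sample-type code starts with "1" are flagged normal and can be dropped
with an annotation predicate before training.

## Training

Training examples are individual (sample, gene, value) cells. Each epoch
shuffles all training cells with the seeded generator and consumes them
in mini-batches (64 by default, the standard recommender-system batch
size for this model family); the exact analytic gradient of the batch
mean squared error is applied with Adam. Choices worth recording:

- **Adam hyperparameters** β1 = 0.9, β2 = 0.999, ε = 1e-8 — the standard
  defaults. A weight-decay knob exists and defaults to 0 (no
  regularization).
- **Sparse updates with a global step counter.** A mini-batch touches at
  most `batch_size` gene rows and sample rows; only those rows' Adam
  moments are updated (lazy sparse Adam), with one global bias-correction
  step count per batch. This keeps an epoch O(cells × m).
- **Initialization** is uniform on [−0.05, 0.05] for every parameter,
  drawn from the seeded generator in a fixed order, so a (config, seed)
  pair reproduces a run bit-exactly; serialized models from identical
  runs are byte-identical.
- **Validation** holds out a seeded random 10% of cells (cell-level
  holdout) and scores them after every epoch. Cell-level rather than
  sample-level holdout matches the training granularity and directly
  measures the model's ability to impute unseen cells.
- **Per-epoch training MSE** is the running mean of batch losses over the
  epoch (each cell scored when visited), while validation MSE is computed
  with end-of-epoch parameters.
- **Divergence** (non-finite batch loss) raises an error advising a lower
  learning rate rather than returning garbage.
- For reproducibility research the fitter accepts an explicit
  initialization, an explicit holdout set, and explicit per-epoch visit
  orders; the defaults derive all three from the seed.

The learning rate is the one genuinely free parameter. `lr_find()`
implements the usual range test: one Adam step per mini-batch while the
rate grows geometrically, recording an exponentially smoothed loss
(factor 0.98, debiased), stopping when the smoothed loss exceeds four
times its running minimum. The suggested rate is one order of magnitude
below the loss minimum. For the synthetic studies here the suggestion
lands near 1e-2, which is the package default.

The default of three epochs suits corpora with thousands of
samples; the small synthetic matrices used in tests need more passes to
reach the noise floor (60 epochs at 200 × 500), which is an optimization
budget choice, not a change in the study conditions.

## Geometry

All relatedness queries use Euclidean distance on entity vectors. A
*close neighbor* is an entity at distance strictly below the threshold
(default 0.1); the strictness at the boundary is deliberate and tested.
Ties in neighbor lists sort lexicographically by id so output is
reproducible.

A group's *centroid* is the coordinate-wise mean of its member sample
vectors, and its *predicted profile* multiplies that centroid with the
gene entity matrix: one scalar per gene. Biases are excluded by default —
the profile is the centroid-projected co-variation signal, not an
absolute expression estimate — and can be included via a flag, which adds
the gene bias plus the mean member sample bias. Because a profile assigns
one scalar per gene, the Euclidean distance between genes *within a
profile* reduces to the absolute difference of their values; this is the
only reading under which profile neighborhoods are well defined from the
stated objects, and it is the one implemented.

## Dimension interpretation and subtyping

- `group_dimension_matrix()` gives one row per sample group (the
  centroid), the object whose heatmap shows group preferences across
  dimensions. "Differentially hot" dimensions of a group are quantified
  as the group-vs-rest contrast divided by the across-group standard
  deviation of the coordinate — a standardized effect size replacing
  visual inspection; degenerate (zero-variance) coordinates score 0.
- `top_genes_by_dimension()` ranks genes by their coordinate in a
  dimension; the default statistic is the absolute coordinate, with
  signed variants exposed because a group can be distinguished by *low*
  weight in a dimension just as well as by high weight.
- Over-representation uses the one-sided hypergeometric upper tail
  (`phyper`) — the standard Fisher-exact reading of enrichment — with
  Benjamini–Hochberg FDR across tested sets (`p.adjust`); both routes are
  cross-checked in the tests against exhaustive tail enumeration and a
  hand-coded step-up. A set is significant when p < 0.01 and FDR < 0.05.
  The universe is the caller's choice; all genes in the model is the
  natural default.
- The signature dimension of a marker gene is the dimension with the
  largest absolute coordinate of its vector (ties to the lower index) —
  the simplest rule that assigns one dimension per marker. Subtyping cuts
  a UPGMA tree (average linkage on Euclidean distances, delegated to
  `hclust`, cross-checked against a naive O(n³) reference) of the samples
  restricted to the selected dimensions; the cluster count is a
  parameter, since no cut rule is forced by the method. Dimensions are
  1-based throughout, matching both R convention and 1..m figure labels.
- `dimension_sd_filter()` reproduces the display filter used before
  subtype heatmaps: keep dimensions whose across-sample standard
  deviation strictly exceeds the mean of all per-dimension standard
  deviations.

## Discovery workflow

Given disjoint responder and non-responder sample lists, anchor genes,
and a threshold t (default 0.1): compute both group centroids and
predicted profiles; take the anchor's profile neighbors present
exclusively in the responder profile; intersect with the anchor's close
neighbors in gene entity space at the same threshold (one threshold
governs both spaces, as only one is defined); the intersection is the
candidate set, scored by Pearson correlation with the anchor across
responder samples only. Multiple anchors produce per-anchor reports plus
a deduplicated union. The set identity
candidates = (responder-close \ non-responder-close) ∩ entity-close is
re-derived by independent brute-force passes on every test fixture.

## The synthetic generator

The generator is the package's test bed and defines its study
conditions. Defaults: 200 samples × 500 genes, latent rank 5, 4 sample
groups with centers ~2 apart and within-group jitter 0.3, two planted
30-gene modules with spread 0.1 around their centers, background gene
vectors i.i.d. N(0, 0.5) per coordinate, gene biases N(0, 0.5), sample
biases N(0, 0.2), and cell-level Gaussian noise SD 0.1 on the log2 scale.
These are sizes and magnitudes typical of a log2 RNA-seq submatrix at
desk scale: values span roughly 0–10 log2 units after the constant shift
that places the minimum at exactly 0 (shifting, not clipping, keeps the
planted low-rank structure intact). What the generator deliberately does
*not* emulate: count-level negative-binomial noise, batch effects, and
library-size artifacts beyond the additive sample bias. Passing tests
therefore demonstrate correct recovery of the factorization's own data
model, not robustness to real-data pathologies.

The responder scenario adds one latent "activity" coordinate: active
(mean 1, SD 0.3) in responder samples, exactly 0 elsewhere. The first
module — anchor first — loads on it with weight `module_effect` (default
1), so module genes co-vary through the shared activity factor only
where it varies. Each non-anchor module gene also carries a small offset
β (0.15–0.35) along a direction w chosen as the minimum-norm solution of
three linear constraints on the realized centroids: w ⊥ responder
centroid (offsets invisible in the responder profile), w · non-responder
centroid = 1 (offsets separate genes by β in the non-responder profile),
and w ⊥ the differences between non-responder group centers (offsets do
not create shared variation within non-responders). Displacing the
non-responder centers by a strong lineage signal (default 8 along one
latent axis) keeps this system well conditioned and ‖w‖ small, so module
genes stay within the 0.1 entity threshold of the anchor while leaving
the non-responder profile neighborhood. This is precisely the geometry
the exclusive-neighbor workflow is designed to detect, constructed so
that ground truth is known exactly. One further realism note: the
additive per-sample bias correlates all gene pairs within any group
(a library-size-like baseline of ~0.8 at the default bias SD); the
activity factor adds responder-only co-variation on top, and the test
suite asserts the within-responder correlation exceeds the non-responder
baseline rather than an absolute gap.

A deliberate limitation governs how recovery is tested: the factorization
is identifiable only up to an invertible linear map (G → GA,
S → SA<sup>-T</sup> leaves every prediction unchanged), so absolute
distances — and with them the 0.1 threshold — are not preserved by
training. Scale-free claims (planted-module pairs closer than background
pairs by a ratio; within-group sample distances below between-group) are
asserted on trained models, while threshold-dependent discovery claims
are asserted on the ground-truth embedding (`as_embedding(truth)`), with
the set identity additionally verified on arbitrary models.

## Numerical choices

- Serialization writes 17 significant digits (`%.17g`), enough to
  round-trip doubles exactly; reruns with identical config and seed are
  byte-identical, which the tests assert at the file level.
- Neighbor and ranking ties break by id or lower index everywhere, so no
  output depends on hash or sort instability.
- Gradients are verified against central finite differences (relative
  error below 1e-5 on every parameter of a small dense model).
- Problem sizes in the test suite: oracle checks on 4×5 to 10×8 models;
  training properties on 60×80 (noiseless) and 80×150 matrices;
  full-scale recovery on three seeds of the default 200×500 generator
  with m = 10, 60 epochs, learning rate 0.01. The whole suite runs in a
  couple of minutes on one CPU.

## Known limitations

- Exact pairwise distances only; no approximate-nearest-neighbor index.
  At m = 50 and 20k genes this is a deliberate simplicity choice.
- The trainer is single-threaded CPU code; a full compendium
  (20,531 genes, ~10k samples, 3 epochs) is hours of work, as expected
  for this model class, and out of scope for the test suite.
- Genes with zero expression everywhere are kept; their vectors converge
  toward bias-only explanations. Dropping them is the caller's decision.
- Whether candidate discovery should instead compare gene-space
  neighborhoods of two separately trained models (one per group) is a
  defensible alternative reading; the centroid-profile construction is
  the one implemented because it is fully determined by a single trained
  model and the stated objects.
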