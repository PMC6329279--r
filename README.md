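# genevec

Gene and sample embeddings from bulk expression matrices by biased matrix
factorization, with neighbor-based downstream analyses: dimension
interpretation through over-representation analysis, signature-dimension
molecular subtyping, and a responder/non-responder exclusive-neighbor
biomarker discovery workflow.

## The problem and the model

Large cancer expression compendia (for example TCGA RNA-seq, ~20,000 genes
across thousands of tumors) contain rich information about which genes
behave alike and which samples resemble each other, but the raw matrix is
too wide to inspect directly. `genevec` learns a compact distributed
representation of both axes at once, the way recommender systems factor a
user–item rating matrix: every gene *a* gets an m-dimensional entity
vector *G<sub>a</sub>*, every sample *i* a vector *S<sub>i</sub>*, and the
log2 expression of gene *a* in sample *i* is modelled as

> Ĝ<sub>ai</sub> = G<sub>a</sub> · S<sub>i</sub><sup>T</sup> + b<sub>a</sub> + b<sub>i</sub>

with per-gene and per-sample scalar biases. All parameters are initialized
uniformly in [−0.05, 0.05] and fitted with mini-batch Adam (batch 64 by
default) on the mean squared error over individual (sample, gene, value)
cells. Expression input follows the RSEM normalized-count convention:
counts below 1 are treated as noise and floored at 1, then
log2-transformed.

Distances in the learned spaces are meaningful: genes with similar
expression behaviour land near each other, so *close neighbors* — entities
within a strict Euclidean threshold (0.1 by default) — give a fast,
database-free notion of gene relatedness. On top of that the package
implements:

- **Dimension interpretation** — per-group centroids over embedding
  dimensions, differentially "hot" dimensions, top genes per dimension,
  and over-representation analysis of those genes against any GMT gene-set
  collection (one-sided hypergeometric test, Benjamini–Hochberg FDR;
  significant when p < 0.01 and FDR < 0.05).
- **Molecular subtyping** — pick the signature dimension of each marker
  gene (largest |coordinate|), then UPGMA-cluster samples on those
  dimensions.
- **Biomarker discovery** — with responder and non-responder sample
  groups and anchor genes (e.g. the immune checkpoint genes *PDCD1*,
  *CD274*, *CTLA4*): predict each group's expression profile from its
  sample-centroid, take the anchor's profile neighbors present exclusively
  in responders, intersect with the anchor's entity-space neighbors, and
  score surviving candidates by Pearson correlation with the anchor across
  responder samples.
- **Synthetic data with known truth** — a generator for low-rank
  log2 expression with sample groups, planted co-regulated gene modules,
  biases, noise, and a responder scenario in which one module co-varies
  with its anchor only in responder samples. Every downstream claim in the
  test suite is validated against this ground truth.

## Worked example

```r
library(genevec)

# a planted responder scenario: 200 samples, 500 genes, rank-5 structure,
# one 30-gene module (anchor G0001) active only in responder samples
sc  <- make_responder_scenario(synth_config(seed = 1))
fit <- gene_embed(sc$expr, dim = 10, learning_rate = 0.01,
                  epochs = 60, seed = 101)
fit
#> gene_embedding: 500 genes, 200 samples, dimension 10
#>   epochs run: 60  final train MSE: 0.02718  validation MSE: 0.02797

# discovery on the ground-truth embedding of the same scenario
report <- discover_candidates(as_embedding(sc$truth), sc$expr, sc$spec)
report
#> candidate_report (threshold 0.1):
#>   G0001: 42 responder-exclusive, 29 entity neighbors, 29 candidates
#>   union over anchors: 29 candidate gene(s)

head(as.data.frame(report), 3)
#>   anchor candidate profile_delta_resp profile_delta_nonresp entity_distance pearson_r
#> 1  G0001     G0002        0.009623890             0.2770601      0.04078197 0.9278147
#> 2  G0001     G0003        0.001230745             0.2154059      0.04155278 0.9131696
#> 3  G0001     G0004        0.005606159             0.3575816      0.05462210 0.9206293
```

The fitted model's validation MSE (0.028) sits close to the generator's
noise floor (noise SD 0.1, variance 0.01), and the 29 reported candidates
are exactly the planted module members: genes whose predicted expression
tracks the anchor in the responder profile (small `profile_delta_resp`)
but not in the non-responder profile, and whose entity vectors lie within
0.1 of the anchor. The Pearson column confirms they co-express with the
anchor across responder samples.

A command-line wrapper with the same functionality (subcommands
`preprocess`, `train`, `lr-find`, `neighbors`, `enrich`, `subtype`,
`discover`, `simulate`, `export-projector`, including
TensorBoard-projector-compatible exports) is installed at
`system.file("cli", "genevec.R", package = "genevec")`.

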