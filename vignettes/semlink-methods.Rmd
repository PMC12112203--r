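---
title: "Semantic-evidence graph encoding with a Tucker decoder: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic-evidence graph encoding with a Tucker decoder: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semlink)
```

## The problem

A knowledge graph stores facts as triples `(head entity, relation, tail
entity)` — for instance `(Zaobaijian, suitable_for, obese_people)` in a graph
linking tea varieties to the populations they benefit. Such graphs are
incomplete by construction: curation finds only a fraction of the true
links. *Link prediction* ranks candidate entities for queries like
`(Zaobaijian, suitable_for, ?)`; *graph completion* turns high-confidence
predictions into new triples.

`semlink` implements an encoder–decoder embedding model for this task,
trains it end to end, evaluates it with the filtered ranking protocol, and
completes graphs by probability thresholding. A seeded synthetic-graph
generator provides benchmark data whose structure matches the signals the
encoder is built to exploit.

## The model

### Decoder: Tucker decomposition with a nonlinearity

Every entity and relation has a d-dimensional embedding. A query
`(e_s, r, ?)` is scored against a candidate tail `e_o` by the trilinear
form

$$f_r(e_s, e_o) = e_o^\top\, f_{\mathrm{non}}\!\big(\mathcal{W} \times_1 e_s \times_2 r\big),$$

where $\mathcal{W}$ is a shared $d \times d \times d$ core tensor,
$\times_n$ is the mode-n tensor–vector product, and $f_{\mathrm{non}}$ is an
elementwise nonlinearity (leaky ReLU by default; `identity` recovers the
classical linear Tucker scorer). The core tensor mediates all
entity–relation–entity interactions, which is what gives Tucker-family
models their parameter sharing and interpretability; the nonlinearity lets
the query vector $\mathcal{W} \times_1 e_s \times_2 r$ express non-additive
interactions before the candidate read-out. Scores pass through the
logistic function when probabilities are needed.

All candidates are scored at once (1-N scoring): the contraction against
the full entity table is a single matrix product.

### Encoder: three levels of semantic evidence

Plain Tucker models ignore the graph around an entity. The encoder stacks
L graph-attention layers (L in 0..3, default 1) that aggregate, for every
entity $e_i$, three evidence signals from its incoming training edges
$\mathcal{N}_i = \{(e_j, r_j)\}$ (reciprocal edges included, so
neighbourhoods are symmetric):

- **relation level** — attention-weighted sum of transformed neighbour
  *relation* embeddings: a relation that frequently points at an answer type
  is itself predictive (a `production_location` query is answered by a
  place regardless of the head);
- **entity level** — the same over neighbour *entity* embeddings: two-hop
  paths support the direct link they short-circuit;
- **triple level** — the same over composed pairs $\phi(e_j, r_j)$
  (elementwise product by default, sum as an option): similar trained
  triples support similar queries.

Attention weights are softmaxes of dot products against the centre
entity's current-layer embedding, computed with max-subtraction; an entity
with no neighbours gets zero evidence vectors. The three signals are
summed, passed through a learned fusion transform and the activation, and
added residually:

$$e_i^{(l+1)} = e_i^{(l)} + \sigma\!\big(F^{(l)}(s^{rel}_i + s^{ent}_i + s^{tri}_i)\big), \qquad
  r^{(l+1)} = U^{(l)} r^{(l)}.$$

Updates are synchronous (all entities advance from layer-l values), and
message passing uses training edges only, so no information leaks from
held-out splits. `L = 0` makes the encoder the identity — this is the
"no GNN" ablation arm, and together with `f_non = "identity"` it reduces
the whole model exactly (bitwise, in the single-query path) to plain
Tucker.

Design points that the model family leaves open, resolved here once:

- the composition $\phi$ is elementwise multiplication by default
  (dimension-preserving, and the standard choice in composition-based
  graph encoders); `composition = "add"` is available;
- the fusion of the three evidence vectors is sum → single learned
  $d \times d$ transform → activation → residual;
- attention keys use current-layer embeddings, consistent with recursive
  stacking;
- there are no self-loops; the residual term carries self-information;
- relations are transformed once per layer;
- batch normalisation is not used anywhere in the decoder.

### Head prediction through reciprocal relations

The scorer answers tail queries. To score head queries `(?, r, t)`, every
relation gets a reciprocal partner `r_rev` and every training triple a
mirrored copy, so the head query becomes the tail query `(t, r_rev, ?)`.
Training on the augmented query set trains both directions symmetrically;
evaluation pools both.

## Training protocol

Training follows the standard 1-N protocol for Tucker-family models:
queries are the distinct `(head, relation)` pairs of the augmented
training set; the target over all entities is 1 on observed tails and 0
elsewhere, smoothed by `label_smoothing` (default 0.1 — hard targets make
1-N binary cross-entropy saturate); the loss is binary cross-entropy
computed in logit space for stability. Parameters are Xavier-initialised
(the core tensor uniform on (-1, 1)) from a fixed seed (default 1234) and
optimised with Adam (defaults 0.9/0.999/1e-8). Dropout acts at the three
standard positions of the Tucker pipeline: on the head embedding, after
the relation contraction, and after the nonlinearity.

After each epoch (configurable), filtered MRR on the validation triples is
computed; the best snapshot is kept and training stops after `patience`
consecutive non-improving evaluations (default 50) or at `epochs_max`
(default 500). Early stopping selects on MRR — the summary statistic the
evaluation reports first — rather than Hits@k, which is coarser.

All gradients are computed by an analytic backward pass through the
decoder contraction and all encoder layers (attention softmax included),
written against the same vectorised operations as the forward pass and
verified in the test suite against central finite differences.

Everything above is driven from `kge_config()`. The defaults (learning
rate 0.001, batch 256, one encoder layer, dimension 200, dropouts
0.1/0.2/0.3, leaky ReLU in both stages) are a setting suited to curated
graphs of roughly a thousand entities; examples and tests in this package
use smaller dimensions and epoch caps, noted below.

## Evaluation

Every evaluated triple contributes two rank records: the tail query
`(h, r, ?)` and the head query `(t, r_rev, ?)`. Under the *filtered*
protocol, candidates known to be true for the query (in any split, from
the filter map built at augmentation time) are removed before ranking, so
a model is not penalised for ranking another correct answer above the one
being tested; raw ranks are kept alongside for diagnostics, and filtered
ranks never exceed raw ones. Ties receive half-credit per tied competitor
by default (`tie_policy = "mean"`), which avoids the optimistic-rank
artifact of scoring constant models as perfect; optimistic and pessimistic
policies are available for cross-checking other implementations.
Aggregates are MRR, MR and Hits@1/3/10 over the pooled records.

Validation/test triples naming an entity or relation never seen in
training are excluded with a message: an embedding model has no
representation to score them with.

## Graph completion

Candidates are the cross product of a head pool, one relation, and a tail
pool, minus all triples already present anywhere in the graph. Each
candidate is scored in both directions; the *final* score is the
head-direction probability (read from the reciprocal query at the
candidate head). The rationale, inherited from the tea use case: with far
more candidate heads (hundreds of tea varieties) than tails (a dozen
population groups), the head-prediction direction is the more
discriminative read-out. Both scores are always reported so the choice is
auditable, and `score_histogram()` exposes their distributions.
A candidate is accepted when its final score reaches the threshold
(default 0.9 — a deliberately conservative bar, since accepted triples
feed back into the graph and false positives are costlier than missed
links). Acceptance is monotone in the threshold by construction.
Thresholds are applied to logistic probabilities, the quantity the
binary cross-entropy objective calibrates.

## The synthetic generator

`kg_simulate()` draws seeded graphs with four motif classes, in
proportions (0.40, 0.30, 0.20, 0.10) by default:

- *relation-determined* triples, where the relation maps any head into a
  small designated tail set (at most 3 tails per designated relation; the
  `suitable_for` relation links the `tea_*` head pool to the `pop_*` tail
  pool) — the signal relation-level evidence targets;
- *compositional* chains `(a, precedes, b)`, `(b, follows, c)` with the
  implied triple `(a, implies, c)`; implied triples are preferentially
  held out, so recovering them requires the two-hop structure that
  entity-level evidence aggregates;
- *near-duplicate* pairs sharing `(head, relation)` with adjacent tails —
  the similar-context signal for triple-level evidence;
- uniform *noise*, which also guarantees every entity and relation occurs
  at least once.

The default scale (1064 entities, 28 relations, 6698 triples, ~80/10/10
split, pools of 330 heads and 12 tails) mirrors a curated tea-and-health
knowledge graph. Split assignment guarantees that held-out triples never
orphan an entity or relation from training and that no held-out triple is
the same-relation reverse of a retained one (the inverse-leakage flaw that
benchmark revisions exist to remove). A `motifs.tsv` sidecar labels every
triple's motif so analyses can condition on structure.

What the generator does *not* emulate: real label semantics, realistic
degree distributions (real graphs are heavy-tailed; motif sampling here is
near-uniform), relation cardinality skew, and annotation noise that is
correlated rather than uniform. Passing tests on this data demonstrates
that the implementation learns and exploits the intended structures — not
that the model will match any particular accuracy on a real graph.

## Numerical and degenerate-input choices

- Softmax attention uses per-neighbourhood max-subtraction; empty
  neighbourhoods yield zero evidence by definition.
- The loss is evaluated in logit space (`max(s,0) - s y + log1p(exp(-|s|))`),
  so extreme scores cannot overflow; the exported `bce_loss()` reference
  form clamps probabilities at 1e-12.
- Non-finite embeddings abort training, naming the encoder layer; a
  non-finite loss aborts with the epoch.
- Duplicate triples in input files are dropped with a logged count;
  labels are case-sensitive and trimmed of trailing whitespace only.
- Ranking ties: mean policy by default (see above). The PReLU negative
  slope is a fixed configuration constant (0.25), not a trained scalar.
- Entity and relation embeddings share one dimension d; the general
  Tucker case with distinct entity/relation dimensions is unsupported
  because the encoder mixes the two spaces.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on deliberately small instances chosen as the
smallest sizes at which each property is informative: oracle comparisons
at d ≤ 4 and ≤ 20 entities; memorisation on the 8-entity fixture and on a
100-entity / 5-relation / 600-triple graph (dimension 32, ≤ 300 epochs);
the ablation-direction benchmark on a 120-entity / 6-relation / 700-triple
graph with both arms sharing one protocol — dimension 32, learning rate
0.005, batch 256, dropouts 0.1/0.2/0.3, ≤ 150 epochs with patience 25,
three training seeds per arm, the within-run snapshot selected on
validation MRR. The shared setting is the one with the best mean
validation MRR in a small configuration study over dimension, depth and
learning rate (larger embedding dimension helped, consistent with the
general experience of Tucker-family models). The acceptance script re-runs
the same pipeline end to end and reports the quantities it computes.

## Known limitations

- Full-graph encoding per mini-batch is quadratic-ish in practice and
  suits graphs up to a few thousand entities; no neighbour sampling or
  mini-batched message passing is implemented.
- No GPU path; everything is dense base-R linear algebra.
- No basis/block decomposition of relation transforms, no multi-head
  attention, no edge dropout, no batch normalisation.
- Hyperparameter search is left to the user (the config is a plain list;
  grids can be enumerated with `purrr`), and no significance testing is
  offered between model variants.
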