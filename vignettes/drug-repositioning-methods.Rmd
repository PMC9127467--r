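---
title: "Drug-disease association prediction with network clustering features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-disease association prediction with network clustering features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgcc)
```

## The problem

Given a binary drug-disease association matrix $Y \in \{0,1\}^{N_{drug}
\times N_{dis}}$ assembled from curated therapeutic evidence, the package
scores every unobserved pair with the probability that the drug treats the
disease. Two complementary views of each entity feed the predictor:

* **attribute features** — what a drug *is* (its chemical substructure
  fingerprint) and what a disease *looks like* (its symptom profile);
* **network clustering features** — where an entity *sits* in its similarity
  network, encoded by a masked nonnegative factorization of $Y$ whose factors
  are pushed to separate network clusters.

A two-tower inductive graph neural network (GraphSAGE) embeds both feature
channels over the drug-drug interaction network and the disease similarity
network, and a small fully connected softmax head scores each pair from the
concatenated embeddings $(z^F_{drug}, z^U_{drug}, z^F_{dis}, z^V_{dis})$.

## Network reconstruction

Curated drug-drug interactions cover only part of the drug registry, and
semantic disease similarity is undefined across vocabulary subtrees, so both
networks are completed from gene-association evidence:

* missing drug-drug entries get the Jaccard similarity of the two drugs' gene
  sets, $|G_i \cap G_j| / |G_i \cup G_j|$ (0 when the union is empty); known
  interactions are kept, binarized to 1;
* missing disease-disease entries get the shared-gene count divided by the
  *product* of the two diseases' gene counts. As printed, this denominator is
  a product rather than the geometric mean of a cosine normalization; the
  package implements the product form and exposes
  `disease_sim_denominator = "cosine"` for the normalized variant, because
  the printed form's intent is ambiguous. Both fills lie in $[0,1]$;
  entities without gene annotations stay unconnected except through known
  edges.

Diagonals are set to 1 (self-similarity) but self-loops are never neighbor
candidates in the graph neural network.

## Attribute features

Drug substructure fingerprints are 881 ordered bits stored as 115-byte
records: a 4-byte big-endian prefix carrying the bit length (881), then 111
payload bytes (888 bits, 7 of them padding), packed most-significant-bit
first. `decode_fingerprint()` / `encode_fingerprint()` implement the layout
and round-trip exactly.

The binary drug-by-substructure table is weighted by TF-IDF: a drug holding
$n$ substructures contributes $1/n$ to each one it holds (term frequencies
sum to 1 across a drug), and each substructure is scaled by
$\log(N_{drug}/\mathit{df})$ with natural logarithm — the base only rescales
features, so it is fixed rather than exposed. Disease-symptom tables are
accepted either binary (weighted by the same TF-IDF) or already weighted
(`symptom_weighting = "given"`).

Weighted tables are embedded by truncated SVD. The embedding is
$U_d \Sigma_d$ — left singular vectors scaled by singular values — so that
components retain their spectral importance; whether the published method
scales by the singular values is unstated, and this convention was chosen
once for its interpretability. Each singular vector's sign is flipped so its
largest-magnitude entry is positive, which makes the embedding
bit-reproducible. Requests beyond the numerical rank zero-fill the trailing
components with a warning (small synthetic tables are often rank-deficient).
Defaults: 300 dimensions for drugs, 100 for diseases, capped at the table
shape when a fixture is smaller.

## Network clustering features

Each reconstructed network is partitioned by a seed-and-grow clustering in
the MCODE style: vertices are weighted by the order times the density of the
highest k-core of their closed neighborhood; complexes grow from the
highest-weight unassigned seed, admitting neighbors whose weight exceeds
$(1-0.2)$ of the seed's; haircut removes singly connected members, and a
complex must contain a 2-core to survive. Two departures from the bare
algorithm were needed to meet this package's requirements:

* the factorization constraint needs a *full disjoint partition*, so every
  node outside a surviving complex becomes a singleton cluster;
* binarizing at weight $> 0$ is meaningless for densely filled similarity
  matrices (any stray shared gene creates an edge and the whole network
  becomes one complex), so the pipeline binarizes at weight $> 0.2$ by
  default — a weak-similarity cutoff — while `cluster_network()` itself keeps
  the permissive 0 default. Assignments computed elsewhere can be supplied
  via `cluster_assignments` and bypass the clustering entirely.

The clustering features are the factors of a masked nonnegative
factorization $Y \approx UV$, fitted by multiplicative updates on the
objective

$$\tfrac{1-2\alpha-2\beta}{2}\,\|P \odot (Y - UV)\|_F^2
  + \tfrac{\alpha}{2}(\|U\|_F^2 + \|V\|_F^2)
  - \tfrac{\beta}{2}\sum_i \|\bar U^{(i)} - \bar U^{all}\|^2
  - \tfrac{\beta}{2}\sum_i \|\bar V^{(i)} - \bar V^{all}\|^2,$$

where $P$ marks the labeled (positive and negative) pairs, $\bar U^{(i)}$ is
the mean factor vector of cluster $i$ and $\bar U^{all}$ the global mean: the
$\beta$ terms *reward* cluster separation. Validity requires
$1 - 2\alpha - 2\beta > 0$; defaults $\alpha = 0.2$, $\beta = 0.1$, $k = 200$.
The objective is also implemented in its trace expansion and the two forms
are verified to agree to $10^{-8}$ in the tests, as is the equality of the
trace constraint with loop-computed cluster-mean deviations.

Numerical choices: factors start at $\mathrm{Uniform}(0.01, 1.01)$ under a
fixed seed (strict positivity keeps multiplicative updates well defined);
denominators are stabilized by $\varepsilon = 10^{-12}$; iteration stops when
the relative objective change drops below $10^{-6}$ or after 1000 rounds (no
stopping rule is published). The updates are the fixed-point form of the
gradient and carry no monotonicity proof, so the fit records the whole
objective trace and warns if it ever increased. Within cross-validation the
mask $P$ is restricted to the training pairs of each fold, so held-out pairs
never inform the factors.

## The two-tower model

Each network gets a 2-layer tower. Neighbor sampling takes each node's
$n_k = 5$ highest-weight neighbors (edge weight is the similarity), ties
broken by ascending node index, isolated nodes aggregating over themselves.
Because this rule is deterministic, the per-layer sampled sets coincide
across layers and epochs, and one row-stochastic neighbor operator per
network expresses the whole sampling scheme; "resampling per epoch" is a
no-op under this tie rule, which is what makes reported metrics exactly
reproducible.

Five aggregators are implemented (mean, mean-pool, max-pool, GCN, LSTM); all
five run in the forward/embedding path, and all but LSTM are permutation
invariant over neighbors, which the tests check by shuffling. Gradient-based
training is implemented for mean (the published default), GCN and mean-pool,
whose layers reduce to linear operators with hand-derived reverse-mode
gradients (verified against finite differences to $10^{-7}$); max-pool and
LSTM towers are inference-only and `train_drgcc()` says so. Hidden
activations are rectified-linear (the activation is not named in the source
method), dropout 0.5 is applied to layer inputs during training, and weights
start from a symmetric uniform fan-based (Glorot) scheme under a fixed seed.

Layer dimensions are {128, 64} for drug attribute features, {64, 32} for
disease attribute features and {128, 32} for both clustering channels; the
concatenated pair representation feeds a {64, 32, 2} fully connected head
with a softmax. The loss is cross-entropy over the *labeled* pairs plus
$\tfrac{\lambda}{N}\sum w^2$ over all weight matrices ($\lambda = 0.01$).
The printed objective ranges over all $N_{drug} \times N_{dis}$ pairs, but
unlabeled pairs have no defined label under the negative-sampling scheme, so
the sum is restricted to the labeled set. Training runs 30 epochs of
minibatch (128) adaptive-moment updates at learning rate 0.001 — the
optimizer family is a design choice; only the rate is published.

### Inductive embedding of new nodes

A node added after training (a new virus, say) is embedded with frozen
weights: existing nodes keep their training-time neighbor samples (so their
embeddings are unchanged — the tests check bit equality), and the new node
aggregates from its own top-$n_k$ neighbors layer by layer. A brand-new node
has no row in $Y$ and therefore no clustering features; `score_new_node()`
zero-fills that channel, which is a documented deviation: the zero vector
sits off the head's training manifold, so rankings for new nodes are most
meaningful from an attribute-only model or with clustering features supplied
explicitly.

## Negative sampling and evaluation

Unknown pairs are scored by a bi-random walk: row-stochastic transition
matrices on both networks propagate $Y$ for two steps on each side with
restart probability 0.3 (the cited method family's convention; no parameters
are published), averaging the left and right walks while their step budgets
last. The lowest-scoring unknown pairs — the least supported by network
proximity — become negatives, as many as there are positives, with ties
broken by a seeded shuffle then pair index. Zero steps, or restart 1,
reproduce $Y$ exactly, which the tests use as anchors. The same labeled set
defines both the factorization mask and the training labels, and negatives
are fixed once before fold splitting (re-sampling per fold is not ruled out
by the source description; fixing them keeps folds comparable).

Cross-validation stratifies positives and negatives separately into five
folds, re-randomized per repeat. Seven metrics are reported: AUC and
precision-recall AUC are threshold-free rank statistics (AUC equals the
concordant-pair fraction, verified against a brute-force oracle and an
independent ROC library; PRAUC is trapezoidal over observed thresholds —
unspecified in the source, chosen as the standard convention), and F1,
accuracy, specificity, precision and recall are computed at the
F1-maximizing threshold, ties resolved toward the lowest threshold.

## The synthetic fixture

`generate_fixture()` emulates the *shape and statistical structure* of the
curated inputs without any download: planted drug and disease clusters drive
compact, per-cluster disjoint gene pools (strong within-cluster gene overlap,
rare stray overlap across), modular interaction edges, within-cluster
semantic similarities with unscored cross-subtree pairs, and
prototype-derived fingerprints and symptom profiles. Associations come from
a planted nonnegative rank-4 product aligned with the clusters; exactly
`round(density * n * m)` top-scoring pairs become ones, and a noise fraction
of ones is relocated count-preservingly. Defaults — 60 drugs, 40 diseases,
200 genes, 3+2 clusters, rank 4, density 0.15, noise 0.02 — were chosen once
as a desk-scale regime in which every stage runs in seconds; density 0.15
gives 360 positives, enough to train the towers, and 2% noise keeps the task
realistic without burying the planted signal.

What the fixture does *not* emulate: real identifier vocabularies,
heavy-tailed degree distributions, cross-module interaction edges (absent so
that planted-cluster recovery is measurable — real networks have them and
seed-growth clustering may merge bridged modules), and the regime where
single feature channels are far from ceiling. The last point matters for
interpreting ablations: at desk scale either channel alone nearly saturates
AUC, so the fusion advantage observed on curated data has little headroom
here, and passing tests show mechanical correctness, not that fused features
beat single channels on real data.

## Problem sizes and runtime

The test-suite fixtures use 24-60 drugs, 16-40 diseases and the acceptance
runs use the default 60x40 fixture: a full 5-fold cross-validation plus a
15-run ablation completes in about two minutes on one core, which is the
scale this package targets for its reference experiments. The published
experiments at 780x717 run through the same code path; `fit_cmf()` and the
towers are dense-matrix implementations, so memory grows as the product of
the registry sizes.

## Known limitations

* Multiplicative updates are not provably monotone for $\beta > 0$; the
  objective trace is recorded and monitored instead.
* Max-pool and LSTM towers do not train (inference only).
* New-node scoring zero-fills the clustering channel (see above).
* Semantic similarity is consumed as an input matrix; computing it from a
  vocabulary hierarchy is out of scope.
* Fingerprints are consumed as bit vectors; computing them from chemical
  structures is out of scope.
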