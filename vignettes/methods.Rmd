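---
title: "Joint embedding and cross-species alignment of interaction networks"
author: "bionetalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint embedding and cross-species alignment of interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionetalign)
```

## The problem

Functional knowledge moves between species imperfectly: orthologous genes
often, but not always, perform the same role, and sequence similarity alone
misses cases where a pathway position is filled by a non-orthologous
protein. Protein–protein interaction (PPI) networks carry complementary
information — two proteins with similar interaction neighborhoods tend to
share function. `bionetalign` aligns two PPI networks into a single latent
space so that *any* cross-species gene pair can be scored for functional
similarity, not just ortholog pairs, and so that the alignment is
*bidirectional*: neither species is a designated source or target.

## The model

Each species' network is an undirected, unweighted simple graph
$G = (V, E)$ with $n$ vertices, adjacency $A$, degree matrix $D$ and volume
$\mathrm{vol}(G) = \sum_i D_{ii}$.

**Input representation.** Instead of raw adjacency rows, the embedding
input is a closed-form random-walk similarity matrix

$$R = \frac{\mathrm{vol}(G)}{T}\left(\sum_{i=1}^{T} (D^{-1}A)^i\right)D^{-1},
\qquad M_{uv} = \max\!\big(\log(R_{uv}/b),\, 0\big)$$

with context window $T$ (default 10) and negative-sampling parameter $b$
(default 1). $M_{uv}$ is a weighted count of paths of length at most $T$
between $u$ and $v$, so rows of $M$ see beyond direct and two-hop
neighbors — important because functional chains (signalling cascades,
complexes in series) routinely span more than three genes. Entries with no
path of length $\le T$ are exact structural zeros; no logarithm is taken
there. Because the truncation $\max(\cdot, 0)$ keeps $M$ nonnegative, the
rows can serve directly as soft reconstruction targets.

**Autoencoder.** Each species gets an autoencoder with a 1024-unit hidden
layer and a 128-dimensional latent layer (encoder $n \to 1024 \to 128$,
decoder $128 \to 1024 \to n$, independent hidden layers). Hidden layers use
a leaky rectifier with negative slope 0.1; the latent layer and the output
logits are affine. The decoder output is read as pre-sigmoid logits.

**Objective.** The per-species embedding loss is

$$L_{\text{embed}} = \alpha L_{\text{high}} + \gamma L_{\text{1st}}
  + \lambda L_2 + \omega \sum_i \lVert z_i \rVert_2^2 .$$

* $L_{\text{high}}$ — reconstruction of the random-walk matrix: a binary
  cross-entropy between $\sigma(\hat M)$ and $M$ min–max scaled to
  $[0,1]$, computed in the numerically stable logits form. The per-entry
  cross-entropies are summed and divided by the number of rows $n$ (the
  mean over vertices of their summed row cross-entropy). This
  normalization matters: it keeps the reconstruction term dominant at the
  default $\alpha = 100$ against the norm regularizer
  $\omega\sum_i\lVert z_i\rVert^2$, which is an unnormalized sum over
  rows. Normalizing by all $n^2$ entries instead shrinks the
  reconstruction gradient by a factor of $n$; in our experiments the
  latent norms then collapse (to $\sim 10^{-2}$), the decoders become
  bias-dominated, and alignment receives no usable gradient — even
  self-alignment of two identical networks stays at chance retrieval.
* $L_{\text{1st}}$ — first-order proximity:
  $-\frac{1}{2|E|}\sum_{i,j} A_{ij}\log\cos(z_i, z_j)$ over ordered pairs
  (each undirected edge counted twice). Only reported edges contribute;
  absent edges are not negatives, because interaction screens are
  incomplete and false negatives abound. Cosines at or below zero are
  clamped at $\varepsilon = 10^{-8}$ so the logarithm and its gradient
  stay finite.
* $L_2$ — sum of squared weight-matrix entries (biases excluded), applied
  as an explicit penalty rather than optimizer weight decay so the term is
  literally part of the objective.

**Cross-training.** Given ortholog anchor pairs
$\Theta \subset V \times V'$, the alignment objective asks each encoder to
place an anchor where the *other* species' decoder can reconstruct the
partner's neighborhood:

$$L_{\text{cross}} = \phi \sum_{(i,i') \in \Theta}
  \mathrm{BCE}(\sigma(De'(En(m_i))),\, m'_{i'}) +
  \mathrm{BCE}(\sigma(De(En'(m'_{i'}))),\, m_i)$$

with each BCE the mean over the target row's entries and the anchor sum
unnormalized ($\phi$ absorbs scale). Alignment updates **encoders only**:
the joint space should move, not the reconstruction heads. The objective
is symmetric in the two species by construction.

**Training blocks.** Training alternates: one block = a round of embedding
epochs for each species followed by a round of alignment epochs. The
default is 10 blocks (suited to richer networks and anchor sets; 20 for
sparser inputs). Within a block the defaults are 2 embedding epochs per
species and 32 alignment epochs, Adam with learning rate $10^{-3}$,
shuffled mini-batches of 128 rows (vertices for embedding, anchor pairs
for alignment), and global gradient-norm clipping at 5. The asymmetric
epoch ratio is deliberate: an alignment pass touches only the anchor rows
(typically a small fraction of vertices) and costs roughly a fifth of an
embedding pass, while the alignment objective converges much more slowly
per pass; balancing wall-clock effort rather than pass counts is what
brings the cross-reconstruction loss close to the self-reconstruction
floor within 10 blocks. All schedule knobs are configuration fields
(`epochsPerBlock`, `alignEpochs`, `alignLr`, `alignBatch`, `lr`,
`batchSize`, `clip`).

**Scores.** After training, the score matrix is
$S = \cos(Z, Z') \in [-1, 1]^{n \times n'}$: cosine similarity between
every cross-species embedding pair.

## Bidirectionality as an exact property

Swapping the two input networks must not change the result. We make this
exact rather than approximate: the fit processes the two species in a
canonical order keyed by a content hash of each network (vertex ids plus
edge set), every random stream (initialization, batch shuffles) is seeded
from the master seed plus that content hash — never from argument
position — and the score matrix is computed in canonical orientation and
transposed (an exact operation) into the caller's orientation. Fitting
(A, B) and (B, A) therefore performs the *identical* floating-point
computation, and the two score matrices are bit-exact transposes at any
thread count.

## Preprocessing

Self-loops are dropped at read time. Preprocessing then iterates to a
fixpoint: degree-0 vertices are removed (the random-walk matrix needs
$D^{-1}$, and an all-zero input row carries no signal), and groups of
vertices with an *identical neighbor set* are collapsed to one uniformly
random representative (seeded). Such vertices — typically degree-1
vertices hanging off the same hub — are indistinguishable to a
topology-only model. We compare open neighborhoods only: adjacent
vertices never collapse. Extending the rule to closed neighborhoods
(adjacent twins) looks natural but degenerates — the two endpoints of any
isolated edge, and all vertices of any clique, become mutual "twins", so
recursion erases legitimate structure; the open rule matches the intended
"typically single-edge vertices" case without that pathology. Every
removal is logged in a replayable report whose application to the raw
network reproduces the preprocessed network exactly.

## Evaluation stack

* **Co-annotation standard.** Gene Ontology annotations (GAF 2.x; default
  filters: Biological Process aspect, low-throughput experimental
  evidence codes EXP/IDA/IMP/IGI/IEP, excluding IPI to avoid circularity
  with physical-interaction networks) are propagated through `is_a` and
  `part_of`. A slim set keeps terms annotated to 10–100 genes in *each*
  species (the bounds are applied per species; a union rule would admit
  terms hugely general in one organism). Cross-species pairs of annotated
  genes are positive when they share a slim term; unannotated genes are
  excluded rather than counted as negatives.
* **AUPRC over random.** Step-interpolated average precision over the
  descending ranking, reported as $\log_2(\mathrm{AUPRC}/\text{prior})$:
  0 is random, 1 is two-fold enrichment. Ties break lexicographically on
  the id pair so rankings are bit-reproducible.
* **Jaccard profiles.** For graded similarity, the Jaccard index of full
  term profiles of the top-$k$ pairs, optionally after removing anchor
  pairs (to show the method prioritizes novel pairs, not just the anchors
  it trained on).
* **Gene-set matching.** For matched gene sets (e.g. one GO term's genes
  in both species), the observed statistic is the mean score over the
  set-by-set block, standardized as
  $t = (\text{mean(block)} - \text{mean}(S)) /
  (\mathrm{sd(block)}/\sqrt{|block|})$, then compared against 100 null
  replicates drawn to match each set's size and degree profile (10
  degree-quantile bins per species): $z = (t - \mu_0)/\sigma_0$. The
  construction of the connectivity correction is our documented
  interpretation and is configuration-overridable; a zero standard
  deviation flags the result degenerate instead of producing infinities.
* **Gene-stratified cross-validation.** Folds partition *genes*, not
  pairs; anchored orthologs always share a fold (connected components of
  the anchor graph are assigned greedily to the smallest fold after a
  seeded shuffle), and pairs spanning folds are excluded entirely. A
  construction audit raises a hard error if any test-fold gene appears in
  a training pair.
* **Genetic-interaction transfer.** Pair features are the elementwise sum
  of the two embedding rows (order-invariant); a balanced standard
  subsamples negatives among genes participating in at least one positive
  pair; the classifier is a radial-basis-kernel SVM (cost 1, kernel width
  from the median pairwise-distance heuristic). Cross-species mode trains
  on one species' standard and evaluates on the other's, both featurized
  in the joint space.
* **Top-percentile graph.** The top percent of all pairs (deterministic
  tie-break) forms an unweighted bipartite graph, with an optional
  minimum-degree display filter.

## The synthetic twin generator

Real cross-species evaluations need large curated downloads; the package
instead ships a generator whose outputs exercise every pipeline stage.
A planted-partition core (near-equal modules, within-module edge
probability `pIn`, between `pOut`) is shared by both species: species A
adds its own species-specific vertices with random attachments; species B
receives an isomorphic, randomly relabeled copy of the core with each
edge independently rewired with probability `rewireP`, plus its own
species-specific part. A seeded fraction of the true correspondence is
revealed as anchors; the held-out rest are the evaluation pairs. Term
annotations are drawn preferentially from one home module per term and
mirrored across the correspondence with seeded membership flips, so
co-annotation structure transfers but imperfectly. Labeled
genetic-interaction pairs are within-module pairs mirrored across the
correspondence, with between-module negatives, balanced exactly 1:1.

The shipped `twin-small` preset is the package's default study condition:
300 core genes, 3 modules, `pIn = 0.15`, `pOut = 0.02` (mean within-module
degree ≈ 15 — denser than genome-scale PPI maps, deliberately, so a
300-gene graph carries comparable neighborhood signal), 5% rewiring, 10%
species-specific vertices, half the true pairs as anchors. `twin-noisy`
raises rewiring to 15%, species-specific content to 20%, and drops anchors
to 30%. A duplication–divergence core (`coreModel = "duplication"`) is
available for degree-heterogeneity stress tests.

**What passing these tests does and does not show.** The generator plants
a correspondence that is recoverable from topology by construction; its
degree distribution (planted-partition) is lighter-tailed than real PPI
networks, its noise is independent edge rewiring rather than systematic
ascertainment bias, and its annotations are module-aligned by design.
Success here demonstrates the machinery — losses, optimization,
anchored alignment, leak-free evaluation — is correct and that the method
recovers planted signal; it does not by itself calibrate performance on
real interactome data.

## Numerical choices and degenerate inputs

* Stable logits-form cross-entropy everywhere; no probability is ever
  materialized in a loss.
* Cosine clamp $[\varepsilon, 1]$ in the first-order loss; entries outside
  the open interval get zero gradient.
* An all-constant target matrix scales to all zeros rather than dividing
  by zero.
* Structural zeros of the random-walk matrix are preserved exactly; the
  analytic symmetry $M = M^\top$ is restored by averaging away the last
  ulp of floating-point asymmetry.
* Training aborts with a stage-tagged diagnostic on non-finite losses and
  on divergence (any block loss above `divergenceGuard`, default $10^6$).
* Hidden-layer width matters even on small toys: with too little
  reconstruction capacity (e.g. 64 units on a 100-vertex toy), the latent
  space collapses toward a cone and alignment signal vanishes. The
  default 1024 units is part of the fixed architecture.
* The in-place optimizer kernels (compiled) require exclusive ownership
  of the weight buffers; the exported epoch functions defensively copy
  weights so user-held objects are never mutated.

## Problem sizes used in the shipped checks

The automated checks run the full pipeline on the `twin-small` preset
(about 330 vertices per species after adding species-specific content,
150 anchors) with 10 training blocks — the package's default fit — plus
ablations (no cross-training; adjacency-matrix input) over ten seeds, and
metric-level checks against brute-force oracles on instances small enough
to enumerate. These sizes were chosen so the whole suite exercises every
stage end-to-end at desk scale.

## Known limitations

* Two species only; no simultaneous multi-species alignment.
* Unweighted networks; confidence-weighted interactomes are out of scope.
* The Bayesian-optimization hyperparameter search of the original
  framework is not implemented; `randomSearchWeights()` provides a plain
  seeded random search over the documented log-scale ranges.
* Determinism is promised on fixed hardware; across BLAS implementations
  the usual floating-point caveats apply (the bidirectionality guarantee,
  being a statement about one machine, is unaffected).
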