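# bionetalign

Bidirectional cross-species alignment of protein–protein interaction (PPI)
networks by ortholog-anchored joint embedding.

## The problem

Model organisms are where most functional genetics happens, but moving a
finding from yeast or mouse into human (or back) requires knowing which
genes play corresponding roles. Sequence orthology answers that only
partially: similar sequence does not imply similar function, and pathway
roles are sometimes filled by non-orthologous proteins. PPI networks carry
the missing signal — proteins with similar interaction neighborhoods tend
to share function. `bionetalign` is for computational biologists who have
two species' interaction networks and a list of ortholog pairs, and want a
score for *every* cross-species gene pair, plus embeddings usable for
downstream prediction tasks such as transferring synthetic-lethality
labels between species.

## The method

For each species' network G = (V, E) with adjacency A, degrees D and
volume vol(G), the embedding input is the closed-form random-walk matrix

    R = vol(G)/T * (Σ_{i=1..T} (D⁻¹A)^i) D⁻¹,   M = max(log(R/b), 0)

whose entry (u, v) weights the paths of length ≤ T between u and v. Each
species trains an autoencoder (n → 1024 → 128 → 1024 → n, leaky-ReLU
hidden layers) on the rows of M with the objective

    L_embed = α·L_high + γ·L_1st + λ·L2 + ω·Σᵢ‖zᵢ‖²

(reconstruction cross-entropy, direct-edge cosine loss, weight penalty,
norm penalty; defaults α=100, γ=5, λ=1, ω=1). The two latent spaces are
tied together by cross-training over ortholog anchors Θ:

    L_cross = φ · Σ_{(i,i')∈Θ} BCE(σ(De'(En(mᵢ))), m'ᵢ') + BCE(σ(De(En'(m'ᵢ'))), mᵢ)

with φ=50, updating encoders only. Training alternates embedding and
alignment passes in blocks (default 10). The output is the score matrix
S = cos(Z, Z′): cosine similarity between every cross-species pair in the
joint latent space. The fit is bidirectional by construction — swapping
the two input networks yields the bit-exact transposed score matrix.

The package also ships the full evaluation stack (GO co-annotation
standards with `is_a`/`part_of` propagation, AUPRC-over-random, Jaccard
profiles of top pairs, degree-matched gene-set matching z-scores,
gene-stratified cross-validation with leakage audits, SVM-based
synthetic-lethality transfer, top-percentile score graphs) and a synthetic
twin-network generator with planted correspondence, so the whole pipeline
runs and is testable without any external database.

## Worked example

Generate a twin study (two networks sharing a noisy 300-gene core, half
the true correspondence revealed as anchors), fit the joint embedding, and
ask where the held-out true partners rank:

```r
library(bionetalign)

pair <- do.call(generateNetworkPair, c(twinPreset("twin-small"), list(seed = 1)))
ppA  <- preprocessNetwork(pair$netA, seed = 1)$network
ppB  <- preprocessNetwork(pair$netB, seed = 1)$network
anch <- readAnchorPairs(pair$truth$anchors, ppA, ppB)

joint <- fitJoint(ppA, ppB, anch, blocks = 10, seed = 1)
S <- values(scoreMatrix(joint))

tm   <- pair$truth$trueMap
keep <- !(paste(tm[,1], tm[,2]) %in% paste(pair$truth$anchors[,1], pair$truth$anchors[,2]))
held <- tm[keep, , drop = FALSE]
held <- held[held[,1] %in% rownames(S) & held[,2] %in% colnames(S), ]
pct  <- sapply(seq_len(nrow(held)), function(i) {
    row <- S[held[i,1], ]; mean(row < row[held[i,2]]) * 100
})
median(pct)
#> [1] 97.27273
```

A median retrieval percentile of 97 means that for a typical held-out
gene — one whose ortholog pairing the model never saw — the true partner
outranks ~97% of the other species' genes. The training log
(`trainingLog(joint)`) shows both per-species embedding losses and the
alignment loss falling over the 10 blocks; the ablation switches
(`config = list(crossTraining = FALSE)` or `adjacencyInput = TRUE`)
reproduce the expected degradations.

A command-line interface wraps the same functions:

```sh
Rscript inst/exec/bionetalign simulate --out study/ --preset twin-small --seed 1
Rscript inst/exec/bionetalign fit --net-a study/netA.tsv --net-b study/netB.tsv \
    --anchors study/anchors.tsv --seed 1 --out run/
Rscript inst/exec/bionetalign top-graph --run run/ --percent 1 --out edges.tsv
```

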