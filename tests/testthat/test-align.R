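test_that("cross loss obeys its symmetry and reduction identities", {
    net <- erdosNet(15, 0.25, 3)
    n <- numVertices(net)
    M <- netmfMatrix(net, 3, 1)
    aeA <- initAutoencoder(n, hidden = 8, latent = 4, seed = 1L)
    aeB <- initAutoencoder(n, hidden = 8, latent = 4, seed = 2L)
    pairs <- cbind(1:5, c(2L, 4L, 1L, 5L, 3L))
    anch <- methods::new("OrthologAnchors", pairs = pairs,
                         sourceIds = cbind(vertexIds(net)[pairs[, 1]],
                                           vertexIds(net)[pairs[, 2]]),
                         dropped = matrix(character(), 0, 2))
    mirror <- methods::new("OrthologAnchors", pairs = pairs[, 2:1],
                           sourceIds = cbind(vertexIds(net)[pairs[, 2]],
                                             vertexIds(net)[pairs[, 1]]),
                           dropped = matrix(character(), 0, 2))

    expect_equal(lossCross(aeA, aeB, M, M, anch, phi = 0), 0)
    expect_equal(lossCross(aeA, aeB, M, M, anch, phi = 7),
                 lossCross(aeB, aeA, M, M, mirror, phi = 7),
                 tolerance = 1e-12)

    ## identical networks, identical params, anchors i -> i reduce to twice
    ## the per-row self-reconstruction cross-entropy (per-entry oracle)
    ident <- methods::new("OrthologAnchors",
                          pairs = cbind(1:n, 1:n),
                          sourceIds = cbind(vertexIds(net), vertexIds(net)),
                          dropped = matrix(character(), 0, 2))
    phi <- 3.5
    got <- lossCross(aeA, aeA, M, M, ident, phi = phi)
    Y <- (values(M) - min(values(M))) / (max(values(M)) - min(values(M)))
    O <- decode(aeA, encode(aeA, M))
    bce <- pmax(O, 0) - O * Y + log1p(exp(-abs(O)))
    expect_equal(got, 2 * phi * sum(rowMeans(bce)), tolerance = 1e-10)

    expect_error(lossCross(aeA, aeB, M, M,
                           methods::new("OrthologAnchors",
                                        pairs = matrix(integer(), 0, 2),
                                        sourceIds = matrix(character(), 0, 2),
                                        dropped = matrix(character(), 0, 2)),
                           phi = 1), "empty")
})

test_that("alignment epochs freeze decoders and descend", {
    tw <- smallTwin(3L)
    MA <- netmfMatrix(tw$ppA, 3, 1)
    MB <- netmfMatrix(tw$ppB, 3, 1)
    aeA <- initAutoencoder(numVertices(tw$ppA), hidden = 16, latent = 4,
                           seed = 1L)
    aeB <- initAutoencoder(numVertices(tw$ppB), hidden = 16, latent = 4,
                           seed = 2L)
    decA <- lapply(aeA@weights[c("W3", "b3", "W4", "b4")], identity)
    decB <- lapply(aeB@weights[c("W3", "b3", "W4", "b4")], identity)
    res <- trainAlignEpoch(aeA, aeB, MA, MB, tw$anch, phi = 50, seed = 4L)
    expect_identical(res$aeA@weights[c("W3", "b3", "W4", "b4")], decA)
    expect_identical(res$aeB@weights[c("W3", "b3", "W4", "b4")], decB)
    expect_false(identical(res$aeA@weights$W1, aeA@weights$W1))

    frozen <- trainAlignEpoch(aeA, aeB, MA, MB, tw$anch, phi = 50, lr = 0,
                              seed = 4L)
    expect_identical(frozen$aeA@weights, aeA@weights)
    expect_identical(frozen$aeB@weights, aeB@weights)

    ## self-alignment toy: one epoch does not increase the cross loss in
    ## at least 8 of 10 seeds
    net <- erdosNet(25, 0.2, 7)
    M <- netmfMatrix(net, 3, 1)
    ident <- methods::new("OrthologAnchors",
                          pairs = cbind(seq_len(numVertices(net)),
                                        seq_len(numVertices(net))),
                          sourceIds = cbind(vertexIds(net), vertexIds(net)),
                          dropped = matrix(character(), 0, 2))
    wins <- 0L
    for (s in 1:10) {
        a1 <- initAutoencoder(numVertices(net), hidden = 12, latent = 4,
                              seed = s)
        a2 <- initAutoencoder(numVertices(net), hidden = 12, latent = 4,
                              seed = s + 100L)
        before <- lossCross(a1, a2, M, M, ident, phi = 10)
        res <- trainAlignEpoch(a1, a2, M, M, ident, phi = 10, seed = s)
        after <- lossCross(res$aeA, res$aeB, M, M, ident, phi = 10)
        if (after <= before) wins <- wins + 1L
    }
    expect_gte(wins, 8L)
})

test_that("cosine scores follow hand arithmetic and guard zero norms", {
    ZA <- rbind(a1 = c(1, 0), a2 = c(0, 1))
    ZB <- rbind(b1 = c(1, 1) / sqrt(2), b2 = c(1, 0))
    S <- values(cosineScores(ZA, ZB))
    expect_equal(S["a1", "b2"], 1)
    expect_equal(S["a2", "b2"], 0)
    expect_equal(S["a1", "b1"], sqrt(2) / 2, tolerance = 1e-12)
    expect_true(all(S >= -1 & S <= 1))
    ZB0 <- rbind(b1 = c(0, 0))
    expect_error(cosineScores(ZA, ZB0), "zero-norm.*b1")
})

test_that("fitJoint honors blocks = 0 and the shipped default weights", {
    tw <- smallTwin(1L)
    j0 <- fitJoint(tw$ppA, tw$ppB, tw$anch, blocks = 0,
                   config = tinyFitConfig(), seed = 5L)
    expect_equal(dim(latentEmbedding(j0, "A")),
                 c(numVertices(tw$ppA), 8L))
    expect_equal(dim(latentEmbedding(j0, "B")),
                 c(numVertices(tw$ppB), 8L))
    expect_equal(nrow(trainingLog(j0)), 0L)
    ## blocks = 0 embeddings are the seeded initial encodings
    ae <- initAutoencoder(numVertices(tw$ppA), hidden = 32L, latent = 8L,
                          seed = j0@aeA@seed)
    expect_identical(ae@weights, j0@aeA@weights)

    w <- lossWeights()
    expect_equal(w[c("alpha", "gamma", "omega", "lambda", "phi")],
                 list(alpha = 100, gamma = 5, omega = 1, lambda = 1,
                      phi = 50))
    j1 <- fitJoint(tw$ppA, tw$ppB, tw$anch, weights = w, blocks = 2,
                   config = tinyFitConfig(), seed = 5L)
    expect_s4_class(j1, "JointEmbedding")
    expect_true(all(is.finite(trainingLog(j1)$lossCross)))
})

test_that("argument order does not change the fit (bit-exact transpose)", {
    tw <- smallTwin(2L)
    mirror <- readAnchorPairs(anchorIds(tw$anch)[, 2:1], tw$ppB, tw$ppA)
    j1 <- fitJoint(tw$ppA, tw$ppB, tw$anch, blocks = 2,
                   config = tinyFitConfig(), seed = 9L)
    j2 <- fitJoint(tw$ppB, tw$ppA, mirror, blocks = 2,
                   config = tinyFitConfig(), seed = 9L)
    expect_identical(values(scoreMatrix(j1)), t(values(scoreMatrix(j2))))
    expect_identical(latentEmbedding(j1, "A"), latentEmbedding(j2, "B"))
})

test_that("fitting a small twin pair ranks held-out true pairs highly", {
    tw <- smallTwin(4L, nCore = 100L)
    ## hidden width matters even on toys: too little reconstruction
    ## capacity collapses the joint space (see the methods vignette)
    joint <- fitJoint(tw$ppA, tw$ppB, tw$anch, blocks = 6,
                      config = tinyFitConfig(hidden = 256L, latent = 16L,
                                             alignEpochs = 40L),
                      seed = 4L)
    S <- values(scoreMatrix(joint))
    held <- heldOutPairs(tw$pair$truth, tw$ppA, tw$ppB)
    ts <- S[held]
    set.seed(1)
    rnd <- S[cbind(sample(rownames(S), 1000, TRUE),
                   sample(colnames(S), 1000, TRUE))]
    expect_lt(wilcox.test(ts, rnd, alternative = "greater")$p.value, 1e-4)

    ## alignment effect: true-pair cosine beats the untrained baseline
    j0 <- fitJoint(tw$ppA, tw$ppB, tw$anch, blocks = 0,
                   config = tinyFitConfig(hidden = 256L, latent = 16L),
                   seed = 4L)
    expect_gt(mean(S[held]), mean(values(scoreMatrix(j0))[held]))
})

test_that("divergence and empty anchors are rejected", {
    tw <- smallTwin(1L)
    expect_error(fitJoint(tw$ppA, tw$ppB, tw$anch, blocks = 1,
                          config = tinyFitConfig(divergenceGuard = 1e-6),
                          seed = 1L),
                 "diverged")
})

test_that("random-search weights respect the documented log ranges", {
    ws <- randomSearchWeights(25, seed = 3L)
    expect_length(ws, 25L)
    al <- vapply(ws, `[[`, 0, "alpha")
    expect_true(all(al >= 1 & al <= 1000))
    aux <- unlist(lapply(ws, function(w) w[c("gamma", "lambda", "omega",
                                             "phi")]))
    expect_true(all(aux >= 0.1 & aux <= 100))
    expect_identical(randomSearchWeights(5, seed = 3L),
                     randomSearchWeights(5, seed = 3L))
})

test_that("stored parameters regenerate the joint embeddings exactly", {
    tw <- smallTwin(5L)
    joint <- fitJoint(tw$ppA, tw$ppB, tw$anch, blocks = 2,
                      config = tinyFitConfig(), seed = 3L)
    MA <- netmfMatrix(tw$ppA, window = joint@config$window,
                      negative = joint@config$negative)
    Z <- encode(joint@aeA, MA)
    expect_identical(unname(Z), unname(latentEmbedding(joint, "A")))
})
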