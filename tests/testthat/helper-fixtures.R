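# Fixtures are built in code at test time; nothing is read from disk that a
# test didn't just write.

# Build a PPINetwork from edge strings like c("a b", "b c").
edgeNet <- function(lines, delimiter = NULL) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    on.exit(unlink(f))
    readEdgeList(f, delimiter = delimiter)
}

# Seeded Erdos-Renyi network with all degrees >= 1 (vertices g01, g02, ...).
erdosNet <- function(n, p, seed) {
    set.seed(seed)
    repeat {
        A <- matrix(0, n, n)
        ut <- which(upper.tri(A))
        A[ut[stats::runif(length(ut)) < p]] <- 1
        A <- A + t(A)
        keep <- rowSums(A) > 0
        if (sum(keep) >= 3) {
            A <- A[keep, keep, drop = FALSE]
            break
        }
    }
    ids <- sprintf("g%02d", seq_len(nrow(A)))
    ed <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    edgeNet(paste(ids[ed[, 1]], ids[ed[, 2]]))
}

# Dense-arithmetic oracle for the random-walk matrix: explicit matrix
# powers with solve(D), independent of the package's implementation.
netmfOracle <- function(net, window, negative) {
    A <- as.matrix(adjacency(net))
    n <- nrow(A)
    D <- diag(rowSums(A))
    P <- solve(D) %*% A
    S <- matrix(0, n, n)
    Pk <- diag(n)
    for (i in seq_len(window)) {
        Pk <- Pk %*% P
        S <- S + Pk
    }
    R <- (sum(A) / window) * S %*% solve(D)
    M <- matrix(0, n, n)
    pos <- R > 0
    M[pos] <- pmax(log(R[pos] / negative), 0)
    (M + t(M)) / 2
}

# Tiny fit configuration for unit tests of the joint-fit plumbing.
tinyFitConfig <- function(...) {
    utils::modifyList(
        list(hidden = 32L, latent = 8L, epochsPerBlock = 2L,
             alignEpochs = 4L, window = 3L),
        list(...))
}

# Small twin pair + preprocessed networks + anchors, memoized per seed.
.twinCache <- new.env(parent = emptyenv())
smallTwin <- function(seed = 1L, nCore = 80L) {
    key <- paste0(seed, ":", nCore)
    if (is.null(.twinCache[[key]])) {
        pair <- generateNetworkPair(nCore = nCore, modules = 2L, pIn = 0.2,
                                    pOut = 0.03, rewireP = 0.05,
                                    speciesSpecificFrac = 0.1,
                                    anchorFrac = 0.5, seed = seed)
        ppA <- preprocessNetwork(pair$netA, seed = seed)$network
        ppB <- preprocessNetwork(pair$netB, seed = seed)$network
        anch <- readAnchorPairs(pair$truth$anchors, ppA, ppB)
        .twinCache[[key]] <- list(pair = pair, ppA = ppA, ppB = ppB,
                                  anch = anch)
    }
    .twinCache[[key]]
}

# Row-retrieval percentile of each true pair (i, j*): the percentage of
# species-B candidates in row i scoring strictly below the true partner.
truePairPercentiles <- function(S, pairs) {
    vapply(seq_len(nrow(pairs)), function(i) {
        row <- S[pairs[i, 1L], ]
        mean(row < row[pairs[i, 2L]]) * 100
    }, 0)
}

# Held-out (non-anchor) true pairs surviving preprocessing.
heldOutPairs <- function(truth, ppA, ppB) {
    tm <- truth$trueMap
    akey <- paste(tm[, 1L], tm[, 2L]) %in%
        paste(truth$anchors[, 1L], truth$anchors[, 2L])
    held <- tm[!akey, , drop = FALSE]
    held[held[, 1L] %in% vertexIds(ppA) & held[, 2L] %in% vertexIds(ppB), ,
         drop = FALSE]
}

# Within-species module co-membership AUROC from an embedding.
withinModuleAUROC <- function(Z, moduleOf) {
    core <- intersect(rownames(Z), names(moduleOf))
    C <- values(cosineScores(Z[core, , drop = FALSE], Z[core, , drop = FALSE]))
    ut <- upper.tri(C)
    aurocScore(C[ut], outer(moduleOf[core], moduleOf[core], "==")[ut])
}
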