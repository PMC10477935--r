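makeAnn <- function(...) {
    # makeAnn(g1 = c("t1","t2"), ...)
    l <- list(...)
    annotationTable(rep(names(l), lengths(l)), unlist(l, use.names = FALSE),
                    propagated = TRUE)
}

test_that("slim selection filters by per-species annotation counts", {
    gA <- paste0("a", 1:30)
    gB <- paste0("b", 1:30)
    annA <- annotationTable(c(gA[1:5], gA[1:15], gA),
                            c(rep("small", 5), rep("mid", 15), rep("big", 30)))
    annB <- annotationTable(c(gB[1:12], gB[1:25], gB[1:2]),
                            c(rep("mid", 12), rep("big", 25), rep("small", 2)))
    slim <- selectSlim(annA, annB, minGenes = 10, maxGenes = 20)
    expect_equal(slim, "mid")                      # small below min, big over max in...
    ## big: 30 in A exceeds max -> excluded even though 25 > 20 too
    slim2 <- selectSlim(annA, annB, minGenes = 2, maxGenes = 100,
                        curated = c("small", "absent"))
    expect_setequal(slim2, c("small", "mid", "big"))
    expect_error(selectSlim(annA, annB, minGenes = 99, maxGenes = 100),
                 "empty slim")

    ## filter-comprehension oracle on a random toy table
    set.seed(2)
    terms <- sprintf("t%02d", 1:20)
    tA <- annotationTable(sample(gA, 200, TRUE), sample(terms, 200, TRUE))
    tB <- annotationTable(sample(gB, 200, TRUE), sample(terms, 200, TRUE))
    slim3 <- selectSlim(tA, tB, minGenes = 5, maxGenes = 12)
    oracle <- Filter(function(t) {
        cA <- length(termToGenes(tA)[[t]])
        cB <- length(termToGenes(tB)[[t]])
        !is.null(termToGenes(tA)[[t]]) && !is.null(termToGenes(tB)[[t]]) &&
            cA >= 5 && cA <= 12 && cB >= 5 && cB <= 12
    }, terms)
    expect_setequal(slim3, oracle)
})

test_that("the pair standard labels by shared slim terms", {
    annA <- makeAnn(a1 = "t1", a2 = "t2", a3 = c("t1", "t3"))
    annB <- makeAnn(b1 = "t1", b2 = "t4")
    std <- buildPairStandard(annA, annB, slim = c("t1", "t2", "t4"),
                             genesA = c("a1", "a2", "a3", "aX"),
                             genesB = c("b1", "b2"))
    expect_true(std$labels["a1", "b1"])     # share t1
    expect_false(std$labels["a2", "b1"])    # t2 vs t1
    expect_false(std$labels["a3", "b2"])    # t3 not in slim
    expect_false("aX" %in% std$genesA)      # unannotated genes excluded
    expect_equal(std$prior, mean(std$labels))

    ## exhaustive pair oracle on a random 10x10 table
    set.seed(5)
    terms <- paste0("t", 1:6)
    lA <- setNames(lapply(1:10, function(i) sample(terms, sample(1:3, 1))),
                   paste0("a", 1:10))
    lB <- setNames(lapply(1:10, function(i) sample(terms, sample(1:3, 1))),
                   paste0("b", 1:10))
    annA2 <- do.call(makeAnn, lA)
    annB2 <- do.call(makeAnn, lB)
    std2 <- buildPairStandard(annA2, annB2, slim = terms,
                              genesA = names(lA), genesB = names(lB))
    cnt <- 0
    for (a in names(lA)) for (b in names(lB))
        if (length(intersect(lA[[a]], lB[[b]]))) cnt <- cnt + 1
    expect_equal(std2$prior, cnt / 100)
    ## symmetry in species order
    stdT <- buildPairStandard(annB2, annA2, slim = terms,
                              genesA = names(lB), genesB = names(lA))
    expect_equal(std2$labels, t(stdT$labels))
})

test_that("average precision matches the advertised anchor points", {
    ## perfectly ranked: 3 positives on top of 10 -> auprc 1
    r <- auprcOverRandom(scores = 10:1, labels = c(1, 1, 1, rep(0, 7)))
    expect_equal(r$auprc, 1)
    expect_equal(r$overRandom, log2(1 / 0.3), tolerance = 1e-12)

    ## single positive ranked last: auprc = prior exactly -> 0
    r0 <- auprcOverRandom(scores = 10:1, labels = c(rep(0, 9), 1))
    expect_identical(r0$overRandom, 0)

    ## single positive at rank 5 of 10: auprc = 2 * prior exactly -> 1
    r1 <- auprcOverRandom(scores = 10:1, labels = c(0, 0, 0, 0, 1, rep(0, 5)))
    expect_identical(r1$overRandom, 1)

    ## invariance under strictly monotone transforms
    set.seed(1)
    sc <- rnorm(50)
    lb <- runif(50) < 0.3
    a <- auprcOverRandom(sc, lb)
    b <- auprcOverRandom(exp(2 * sc) + 5, lb)
    expect_identical(a$auprc, b$auprc)

    expect_error(auprcOverRandom(1:3, c(1, 1, 1)), "both classes")
})

test_that("step-interpolated AP agrees with an exhaustive PR-curve oracle", {
    set.seed(9)
    for (rep in 1:5) {
        sc <- rnorm(40)
        lb <- runif(40) < 0.4
        if (!any(lb) || all(lb)) next
        got <- auprcOverRandom(sc, lb)$auprc
        ord <- order(-sc, seq_along(sc))
        y <- lb[ord]
        ## oracle: precision at every positive rank, averaged
        expected <- mean(sapply(which(y), function(k) sum(y[1:k]) / k))
        expect_equal(got, expected, tolerance = 1e-12)
    }
})

test_that("AUROC equals the exhaustive pair-comparison statistic", {
    set.seed(4)
    sc <- rnorm(30)
    lb <- runif(30) < 0.5
    got <- aurocScore(sc, lb)
    pos <- sc[lb]
    neg <- sc[!lb]
    cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(got, mean(cmp), tolerance = 1e-12)
})

test_that("Jaccard index and top-k ranking behave as documented", {
    expect_equal(jaccardIndex(c("a", "b"), c("a", "b")), 1)
    expect_equal(jaccardIndex(c("a", "b"), c("b", "c")), 1 / 3)
    expect_equal(jaccardIndex("a", "z"), 0)
    expect_equal(jaccardIndex(character(), character()), 0)

    annA <- makeAnn(a1 = c("t1", "t2"), a2 = "t3")
    annB <- makeAnn(b1 = c("t1", "t2"), b2 = "t3", b3 = "t9")
    S <- methods::new("ScoreMatrix", values = matrix(
        c(0.9, 0.5, 0.9, 0.1, 0.2, 0.3), nrow = 2,
        dimnames = list(c("a1", "a2"), c("b1", "b2", "b3"))))
    ## scores: a1b1=.9 a2b1=.5 a1b2=.9 a2b2=.1 a1b3=.2 a2b3=.3
    ## tie at .9 broken lexicographically: (a1,b1) before (a1,b2)
    jk <- jaccardTopK(S, annA, annB, k = 3)
    expect_equal(jk, c(1, 0, 0))   # (a1,b1)=1, (a1,b2)=0, (a2,b1)=0
    jk2 <- jaccardTopK(S, annA, annB, k = 2, excludeAnchors = TRUE,
                       anchors = cbind("a1", "b1"))
    expect_equal(jk2, c(0, 0))
    expect_error(jaccardTopK(S, annA, annB, k = 0), "positive")
    expect_error(jaccardTopK(S, annA, annB, k = 99), "exceeds")
})

test_that("top-percent graph selects the exact highest-scoring pairs", {
    set.seed(8)
    v <- matrix(runif(20), 4, 5,
                dimnames = list(paste0("a", 1:4), paste0("b", 1:5)))
    S <- methods::new("ScoreMatrix", values = v)
    ## 10% of 20 pairs = 2 edges, the two largest entries (sort oracle)
    g <- topPercentGraph(S, percent = 10)
    ord <- order(-as.vector(v))
    expect_equal(nrow(g), 2L)
    expect_equal(sort(g$score), sort(as.vector(v)[ord[1:2]]))

    full <- topPercentGraph(S, percent = 100)
    expect_equal(nrow(full), 20L)

    expect_warning(g2 <- topPercentGraph(S, percent = 10, minDegree = 5L),
                   "empty")
    expect_equal(nrow(g2), 0L)
    expect_error(topPercentGraph(S, percent = 0), "percent")
})

test_that("gene-stratified folds keep orthologs together", {
    genesA <- paste0("a", 1:8)
    genesB <- paste0("b", 1:4)
    anch <- cbind(paste0("a", 1:3), paste0("b", 1:3))
    f <- geneStratifiedFolds(genesA, genesB, anch, k = 3, seed = 2)
    expect_equal(unname(f$foldA[anch[, 1]]), unname(f$foldB[anch[, 2]]))
    expect_true(all(table(names(f$foldA)) == 1))
    expect_setequal(names(f$foldA), genesA)
    ## exclusions equal a brute-force count of cross-fold pairs
    cnt <- 0
    for (a in genesA) for (b in genesB)
        if (f$foldA[a] != f$foldB[b]) cnt <- cnt + 1
    expect_equal(f$excludedPairs, cnt)
    expect_error(geneStratifiedFolds(c("x", "y"), k = 3, seed = 1),
                 "fewer")
})

test_that("gene-set matching standardizes against a degree-matched null", {
    tw <- smallTwin(6L)
    nA <- numVertices(tw$ppA)
    nB <- numVertices(tw$ppB)
    set.seed(3)
    v <- matrix(rnorm(nA * nB), nA, nB,
                dimnames = list(vertexIds(tw$ppA), vertexIds(tw$ppB)))
    ## 3x3 printed toy: observed statistic equals hand mean
    S3 <- v
    setA <- rownames(v)[1:3]
    setB <- colnames(v)[1:3]
    gm <- geneSetMatchZ(S3, setA, setB, tw$ppA, tw$ppB, nNull = 20,
                        seed = 1)
    expect_equal(gm$observed, mean(v[setA, setB]))
    expect_false(gm$degenerate)

    ## constant matrix: zero block sd -> degenerate flag
    Sc <- matrix(0.5, nA, nB, dimnames = dimnames(v))
    gmc <- geneSetMatchZ(Sc, setA, setB, tw$ppA, tw$ppB, nNull = 10,
                         seed = 1)
    expect_true(gmc$degenerate)
    expect_true(is.na(gmc$zScore))

    ## planted high-similarity block scores z > 3
    vp <- v
    pa <- rownames(v)[4:18]
    pb <- colnames(v)[4:18]
    vp[pa, pb] <- vp[pa, pb] + 1.5
    gmp <- geneSetMatchZ(vp, pa, pb, tw$ppA, tw$ppB, nNull = 50, seed = 2)
    expect_gt(gmp$zScore, 3)
})
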