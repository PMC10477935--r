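test_that("edge lists are deduplicated and self-loops removed", {
    net <- edgeNet(c("a b", "b a", "a a"))
    expect_equal(numVertices(net), 2L)
    expect_equal(sum(degrees(net)) / 2, 1)
    expect_equal(net@metadata$selfLoopsRemoved, 1L)

    path <- edgeNet(c("a b", "b c"))
    expect_equal(vertexIds(path), c("a", "b", "c"))
    expect_equal(unname(degrees(path)), c(1L, 2L, 1L))
    expect_equal(graphVolume(path), 4)
})

test_that("edge count matches an independent set-based line parser", {
    set.seed(7)
    ids <- letters[1:8]
    lines <- c(replicate(15, paste(sample(ids, 2L), collapse = " ")),
               c("c c", "f f"),                   # self-loops
               c("a b", "a b", "b a"))            # duplicates
    lines <- sample(lines)
    net <- edgeNet(lines)
    ## oracle: undirected pair set semantics on the raw lines
    fields <- strsplit(lines, " ")
    keys <- unique(vapply(fields, function(f)
        if (f[1] == f[2]) NA_character_
        else paste(sort(f[1:2]), collapse = "|"), ""))
    expect_equal(sum(degrees(net)) / 2, sum(!is.na(keys)))
})

test_that("malformed and empty edge lists raise informative errors", {
    f <- tempfile()
    writeLines(c("# comment", "a\tb", "lonely"), f)
    expect_error(readEdgeList(f), "line 3")
    writeLines(c("# nothing", ""), f)
    expect_error(readEdgeList(f), "empty")
    writeLines("x\tx", f)
    expect_error(readEdgeList(f), "self-loops|empty")
    unlink(f)
})

test_that("preprocessing collapses a star to hub plus one leaf", {
    star <- edgeNet(c("h l1", "h l2", "h l3"))
    ## brute-force fixpoint oracle: exhaustive neighbor-set comparison says
    ## the three leaves are one duplicate group, so 2 vertices remain
    out <- preprocessNetwork(star, seed = 4L)
    expect_equal(numVertices(out$network), 2L)
    expect_true("h" %in% vertexIds(out$network))
    expect_equal(sum(degrees(out$network)) / 2, 1)
    expect_length(out$report@rounds[[1]]$groups, 1L)
    expect_setequal(
        c(out$report@rounds[[1]]$groups[[1]]$kept,
          out$report@rounds[[1]]$groups[[1]]$removed),
        c("l1", "l2", "l3"))
})

test_that("distinct neighborhoods are kept; runs are deterministic", {
    ## a triangle has three distinct neighbor sets: unchanged
    tri <- edgeNet(c("a b", "b c", "c a"))
    out <- preprocessNetwork(tri, seed = 1L)
    expect_equal(vertexIds(out$network), vertexIds(tri))

    p4 <- edgeNet(c("a b", "b c", "c d"))
    out2 <- preprocessNetwork(p4, seed = 1L)
    expect_equal(vertexIds(out2$network), vertexIds(p4))

    net <- erdosNet(30, 0.1, 5)
    r1 <- preprocessNetwork(net, seed = 9L)
    r2 <- preprocessNetwork(net, seed = 9L)
    expect_identical(vertexIds(r1$network), vertexIds(r2$network))
})

test_that("preprocessing is idempotent and yields a principal submatrix", {
    net <- erdosNet(40, 0.08, 11)
    r1 <- preprocessNetwork(net, seed = 3L)
    r2 <- preprocessNetwork(r1$network, seed = 99L)
    expect_identical(vertexIds(r2$network), vertexIds(r1$network))
    expect_equal(as.matrix(adjacency(r2$network)),
                 as.matrix(adjacency(r1$network)))
    keep <- match(vertexIds(r1$network), vertexIds(net))
    expect_equal(as.matrix(adjacency(r1$network)),
                 as.matrix(adjacency(net))[keep, keep])
})

test_that("a replayed report reproduces the preprocessed network exactly", {
    net <- erdosNet(40, 0.08, 2)
    out <- preprocessNetwork(net, seed = 21L)
    replayed <- replayPreprocess(net, out$report)
    expect_identical(vertexIds(replayed), vertexIds(out$network))
    expect_equal(as.matrix(adjacency(replayed)),
                 as.matrix(adjacency(out$network)))
    ## serialization round trip drives the same replay
    f <- tempfile()
    writePreprocessReport(out$report, f)
    rep2 <- readPreprocessReport(f)
    unlink(f)
    replayed2 <- replayPreprocess(net, rep2)
    expect_identical(vertexIds(replayed2), vertexIds(out$network))
})

test_that("full collapse of degenerate inputs raises an error", {
    ## two leaves on one hub and nothing else: leaves collapse, the
    ## resulting single edge survives (adjacent vertices are never twins)
    v <- edgeNet(c("h a", "h b"))
    out <- preprocessNetwork(v, seed = 1L)
    expect_equal(numVertices(out$network), 2L)
})

test_that("anchor pairs are index-mapped, filtered, and deduplicated", {
    netA <- edgeNet(c("a b", "b c"))
    netB <- edgeNet(c("x y", "y z"))
    anch <- readAnchorPairs(cbind(c("a", "b"), c("x", "y")), netA, netB)
    expect_equal(numAnchors(anch), 2L)
    expect_equal(anchorPairs(anch),
                 cbind(match(c("a", "b"), vertexIds(netA)),
                       match(c("x", "y"), vertexIds(netB))))

    anch2 <- readAnchorPairs(cbind(c("q", "a"), c("x", "y")), netA, netB)
    expect_equal(numAnchors(anch2), 1L)
    expect_equal(unname(anch2@dropped), cbind("q", "x"))

    ## k duplicated lines collapse to distinct surviving pairs (set oracle)
    raw <- cbind(rep(c("a", "b", "a"), 4), rep(c("x", "y", "x"), 4))
    anch3 <- readAnchorPairs(raw, netA, netB)
    expect_equal(numAnchors(anch3),
                 length(unique(paste(raw[, 1], raw[, 2]))))
    ## round trip: ids recovered from indices equal the surviving pairs
    expect_equal(unname(cbind(vertexIds(netA)[anchorPairs(anch3)[, 1]],
                              vertexIds(netB)[anchorPairs(anch3)[, 2]])),
                 unname(anchorIds(anch3)))

    expect_error(readAnchorPairs(cbind("q", "w"), netA, netB),
                 "no anchors")
})

test_that("annotation propagation closes ancestor paths", {
    ann <- annotationTable(c("g1"), c("c"))
    ont <- data.frame(term = "c", parent = "p", relation = "is_a")
    out <- propagateAnnotations(ann, ont)
    expect_setequal(geneToTerms(out)[["g1"]], c("c", "p"))
    expect_true(isPropagated(out))

    ## undeclared relations are ignored
    ont2 <- data.frame(term = "c", parent = "p", relation = "regulates")
    out2 <- propagateAnnotations(ann, ont2)
    expect_equal(geneToTerms(out2)[["g1"]], "c")
})

test_that("propagation matches a reachability oracle on a random DAG", {
    set.seed(42)
    nT <- 50
    terms <- sprintf("T%02d", seq_len(nT))
    ## random DAG: edges only from lower to higher index
    edges <- which(upper.tri(matrix(0, nT, nT)) &
                   matrix(runif(nT^2) < 0.06, nT), arr.ind = TRUE)
    ont <- data.frame(term = terms[edges[, 1]], parent = terms[edges[, 2]],
                      relation = sample(c("is_a", "part_of"),
                                        nrow(edges), TRUE))
    genes <- sprintf("g%02d", 1:20)
    g <- sample(genes, 60, TRUE)
    t <- sample(terms, 60, TRUE)
    out <- propagateAnnotations(annotationTable(g, t), ont)
    ## oracle: transitive closure by repeated squaring of reachability
    R <- diag(nT)
    E <- matrix(0, nT, nT)
    E[cbind(edges[, 1], edges[, 2])] <- 1
    for (k in 1:6) R <- pmin(R + R %*% (E %*% R), 1)  # converges fast
    reach <- (R + E) > 0
    for (gene in unique(g)) {
        direct <- unique(t[g == gene])
        expected <- unique(c(direct,
            terms[colSums(reach[match(direct, terms), , drop = FALSE]) > 0]))
        ## restrict oracle to strict ancestors plus direct terms
        anc <- terms[apply(reach[match(direct, terms), , drop = FALSE] -
                           diag(nT)[match(direct, terms), , drop = FALSE] > 0,
                           2, any)]
        expect_setequal(geneToTerms(out)[[gene]], union(direct, anc))
    }
})

test_that("cyclic ontologies are rejected with a named cycle", {
    ann <- annotationTable("g", "a")
    ont <- data.frame(term = c("a", "b", "c"), parent = c("b", "c", "a"),
                      relation = "is_a")
    expect_error(propagateAnnotations(ann, ont), "cycle")
})

test_that("GAF reading applies aspect, evidence and qualifier filters", {
    rows <- c(
        "!gaf-version: 2.2",
        paste("DB", "g1", "g1", "", "GO:1", "REF", "IDA", "", "P", "", "",
              "protein", "taxon:1", "20200716", "DB", "", "", sep = "\t"),
        paste("DB", "g1", "g1", "NOT", "GO:2", "REF", "IDA", "", "P", "", "",
              "protein", "taxon:1", "20200716", "DB", "", "", sep = "\t"),
        paste("DB", "g2", "g2", "", "GO:3", "REF", "IPI", "", "P", "", "",
              "protein", "taxon:1", "20200716", "DB", "", "", sep = "\t"),
        paste("DB", "g3", "g3", "", "GO:4", "REF", "IDA", "", "F", "", "",
              "protein", "taxon:1", "20200716", "DB", "", "", sep = "\t"),
        paste("DB", "g4", "g4", "", "GO:5", "REF", "IMP", "", "P", "", "",
              "protein", "taxon:1", "20200716", "DB", "", "", sep = "\t"))
    f <- tempfile()
    writeLines(rows, f)
    ann <- readGAF(f)
    unlink(f)
    expect_setequal(names(geneToTerms(ann)), c("g1", "g4"))
    expect_equal(geneToTerms(ann)[["g1"]], "GO:1")
})

test_that("OBO parsing extracts is_a and part_of relations", {
    obo <- c("[Term]", "id: GO:1", "is_a: GO:2 ! parent",
             "relationship: part_of GO:3",
             "[Term]", "id: GO:9", "is_obsolete: true", "is_a: GO:2")
    f <- tempfile()
    writeLines(obo, f)
    tab <- readOBO(f)
    unlink(f)
    expect_equal(nrow(tab), 2L)
    expect_setequal(tab$relation, c("is_a", "part_of"))
    expect_false("GO:9" %in% tab$term)
})
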