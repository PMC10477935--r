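#' @include evaluation.R
NULL

## Degree-quantile bin label per gene.
.degreeBins <- function(net, bins = 10L) {
    d <- degrees(net)
    br <- unique(stats::quantile(d, probs = seq(0, 1, length.out = bins + 1L)))
    if (length(br) < 2L) br <- c(min(d) - 0.5, max(d) + 0.5)
    stats::setNames(cut(d, breaks = br, include.lowest = TRUE,
                        labels = FALSE), names(d))
}

## Sample a gene set matching the bin composition of `set` (ids), from the
## per-bin pools. Size- and degree-matched by construction.
.sampleMatched <- function(set, binOf, pools) {
    tab <- table(binOf[set])
    out <- character()
    for (b in names(tab)) {
        pool <- pools[[b]]
        out <- c(out, pool[sample.int(length(pool), tab[[b]])])
    }
    out
}

#' Cross-species gene-set matching score
#'
#' Measures how strongly a gene set in one species scores against a gene
#' set in the other, correcting for background connectivity. The observed
#' statistic is the mean score over the set-by-set block; it is
#' standardized against the global score matrix as a t-score,
#' \code{t = (mean(block) - mean(S)) / (sd(block)/sqrt(|block|))}, and the
#' final z-score compares that t-score against a null distribution of
#' t-scores from random gene sets matched in size and degree distribution
#' (per-species degree-quantile bins), sampled \code{nNull} times.
#'
#' @param S A \linkS4class{ScoreMatrix}, or any numeric matrix with gene
#'   dimnames (the statistic is defined for arbitrary score scales).
#' @param setA,setB Character vectors of gene ids present in \code{S}.
#' @param netA,netB \linkS4class{PPINetwork}s supplying degrees for the
#'   matched null.
#' @param nNull Number of null samples (default 100).
#' @param seed Integer seed.
#' @param bins Number of degree-quantile bins per species.
#' @return List of class \code{GeneSetMatch}: \code{observed},
#'   \code{tScore}, \code{nullMean}, \code{nullSd}, \code{zScore},
#'   \code{degenerate} (TRUE when a zero standard deviation made the
#'   z-score undefined).
#' @export
geneSetMatchZ <- function(S, setA, setB, netA, netB, nNull = 100L,
                          seed = 1L, bins = 10L) {
    v <- if (methods::is(S, "ScoreMatrix")) values(S) else S
    if (!length(setA) || !length(setB)) stop("gene sets must be nonempty")
    if (!all(setA %in% rownames(v)) || !all(setB %in% colnames(v)))
        stop("gene sets must be present in the score matrix")
    gMean <- mean(v)
    tOf <- function(a, b) {
        block <- v[a, b, drop = FALSE]
        s <- stats::sd(block)
        if (is.na(s) || s == 0) return(NA_real_)
        (mean(block) - gMean) / (s / sqrt(length(block)))
    }
    tObs <- tOf(setA, setB)
    binA <- .degreeBins(netA, bins)[rownames(v)]
    binB <- .degreeBins(netB, bins)[colnames(v)]
    poolsA <- split(rownames(v), binA)
    poolsB <- split(colnames(v), binB)
    names(poolsA) <- as.character(names(poolsA))
    nullT <- withSeed(.mixSeed(seed, "geneset-null"), vapply(seq_len(nNull),
        function(r) tOf(.sampleMatched(setA, binA, poolsA),
                        .sampleMatched(setB, binB, poolsB)), 0))
    nullT <- nullT[is.finite(nullT)]
    nm <- mean(nullT)
    ns <- stats::sd(nullT)
    degen <- is.na(tObs) || length(nullT) < 2L || is.na(ns) || ns == 0
    structure(list(observed = mean(v[setA, setB, drop = FALSE]),
                   tScore = tObs, nullMean = nm, nullSd = ns,
                   zScore = if (degen) NA_real_ else (tObs - nm) / ns,
                   degenerate = degen),
              class = "GeneSetMatch")
}

#' Gene-stratified cross-validation folds
#'
#' Assigns genes of both species to \code{k} folds such that anchored
#' orthologs always share a fold: connected components of the
#' anchor graph over the union gene set are shuffled (seeded) and
#' assigned greedily to the currently smallest fold. Pairs whose genes
#' land in different folds are excluded from fold-based evaluation.
#'
#' @param genesA,genesB Character vectors of gene ids (either may be
#'   empty).
#' @param anchors \linkS4class{OrthologAnchors}, a two-column id matrix,
#'   or \code{NULL} for no cross-species ties.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of class \code{FoldAssignment}: \code{foldA}, \code{foldB}
#'   (named integer vectors), \code{k}, and \code{excludedPairs}, the count
#'   of cross-species pairs (over the full genesA x genesB grid) whose
#'   genes sit in different folds.
#' @export
geneStratifiedFolds <- function(genesA, genesB = character(), anchors = NULL,
                                k = 5L, seed = 1L) {
    if (k < 2L) stop("k must be >= 2")
    tag <- function(prefix, g) if (length(g)) paste0(prefix, g) else character()
    nodes <- c(tag("A:", genesA), tag("B:", genesB))
    am <- if (is.null(anchors)) matrix(character(), 0L, 2L)
          else if (methods::is(anchors, "OrthologAnchors")) anchorIds(anchors)
          else anchors
    am <- am[am[, 1L] %in% genesA & am[, 2L] %in% genesB, , drop = FALSE]
    fromB <- if (nrow(am)) paste0("A:", am[, 1L]) else character()
    toB <- if (nrow(am)) paste0("B:", am[, 2L]) else character()
    g <- igraph::graph_from_data_frame(
        d = data.frame(from = c(fromB, nodes), to = c(toB, nodes)),
        directed = FALSE, vertices = nodes)
    comp <- igraph::components(g)$membership[nodes]
    nComp <- max(comp)
    if (nComp < k) stop("fewer connected components than folds")
    sizes <- tabulate(comp, nComp)
    ord <- withSeed(.mixSeed(seed, "folds"), sample.int(nComp))
    foldOf <- integer(nComp)
    load <- numeric(k)
    for (cp in ord) {
        f <- which.min(load)
        foldOf[cp] <- f
        load[f] <- load[f] + sizes[cp]
    }
    fold <- foldOf[comp]
    names(fold) <- nodes
    foldA <- fold[seq_along(genesA)]
    names(foldA) <- genesA
    foldB <- fold[length(genesA) + seq_along(genesB)]
    names(foldB) <- genesB
    excluded <- length(genesA) * length(genesB) -
        sum(vapply(seq_len(k), function(f)
            sum(foldA == f) * sum(foldB == f), 0))
    structure(list(foldA = foldA, foldB = foldB, k = as.integer(k),
                   excludedPairs = excluded),
              class = "FoldAssignment")
}
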