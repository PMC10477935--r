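#' @include align.R
NULL

#' Select a slim term set for evaluation
#'
#' Keeps terms of moderate specificity: annotated to at least
#' \code{minGenes} and at most \code{maxGenes} genes in each species
#' separately. An optional curated term list is unioned in, restricted to
#' terms annotated in both species.
#'
#' @param annA,annB Propagated \linkS4class{AnnotationTable}s.
#' @param minGenes,maxGenes Per-species annotated-gene bounds.
#' @param curated Optional character vector of curated slim terms.
#' @return Character vector of slim term ids.
#' @export
selectSlim <- function(annA, annB, minGenes = 10L, maxGenes = 100L,
                       curated = NULL) {
    cntA <- lengths(termToGenes(annA))
    cntB <- lengths(termToGenes(annB))
    okA <- names(cntA)[cntA >= minGenes & cntA <= maxGenes]
    okB <- names(cntB)[cntB >= minGenes & cntB <= maxGenes]
    slim <- intersect(okA, okB)
    if (!is.null(curated))
        slim <- union(slim, intersect(curated,
                                      intersect(names(cntA), names(cntB))))
    if (!length(slim)) stop("empty slim set")
    sort(slim)
}

#' Build the cross-species co-annotation pair standard
#'
#' Labels every cross-species pair of annotated genes: positive when the
#' two genes share at least one slim term, negative otherwise. Genes
#' without any annotation are excluded from the standard rather than
#' counted as negatives.
#'
#' @param annA,annB Propagated \linkS4class{AnnotationTable}s.
#' @param slim Character vector of slim terms (see
#'   \code{\link{selectSlim}}).
#' @param genesA,genesB Gene universes (typically the preprocessed
#'   networks' vertex ids).
#' @return List of class \code{PairStandard}: \code{genesA}, \code{genesB}
#'   (annotated genes in the universes), \code{labels} (logical matrix),
#'   \code{prior} (positive fraction), \code{slim}.
#' @export
buildPairStandard <- function(annA, annB, slim, genesA, genesB) {
    if (!length(slim)) stop("slim set is empty")
    inc <- function(ann, genes) {
        g2t <- geneToTerms(ann)
        genes <- genes[genes %in% names(g2t)]
        m <- matrix(0, length(genes), length(slim),
                    dimnames = list(genes, slim))
        for (g in genes) {
            ts <- intersect(g2t[[g]], slim)
            if (length(ts)) m[g, ts] <- 1
        }
        m
    }
    IA <- inc(annA, genesA)
    IB <- inc(annB, genesB)
    if (nrow(IA) == 0L || nrow(IB) == 0L)
        stop("no annotated genes in one of the universes")
    labels <- tcrossprod(IA, IB) > 0
    prior <- mean(labels)
    if (prior == 0) stop("pair standard has zero positives")
    if (prior == 1) stop("pair standard has zero negatives")
    structure(list(genesA = rownames(IA), genesB = rownames(IB),
                   labels = labels, prior = prior, slim = slim),
              class = "PairStandard")
}

## Deterministic ranking order: score descending, then lexicographic id
## pair, then original index.
.rankOrder <- function(scores, idA = NULL, idB = NULL) {
    if (is.null(idA)) order(-scores, seq_along(scores))
    else order(-scores, idA, idB, seq_along(scores))
}

#' Area under the precision-recall curve, relative to random
#'
#' Computes step-interpolated average precision over the descending score
#' ranking and reports \code{log2(auprc / prior)}: 0 is random
#' performance, 1 a two-fold improvement over random. Monotone transforms
#' of the scores leave the result unchanged.
#'
#' @param scores Numeric vector.
#' @param labels Logical or 0/1 vector (both classes present).
#' @param idA,idB Optional id vectors used for deterministic tie-breaking
#'   (lexicographic), falling back to input order.
#' @return List with \code{auprc}, \code{prior}, \code{overRandom}.
#' @export
auprcOverRandom <- function(scores, labels, idA = NULL, idB = NULL) {
    labels <- as.logical(labels)
    if (!any(labels) || all(labels))
        stop("both classes must be present")
    ord <- .rankOrder(scores, idA, idB)
    y <- labels[ord]
    prec <- cumsum(y) / seq_along(y)
    auprc <- sum(prec[y]) / sum(y)
    prior <- mean(labels)
    list(auprc = auprc, prior = prior, overRandom = log2(auprc / prior))
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) with midrank tie handling.
#'
#' @param scores Numeric vector.
#' @param labels Logical or 0/1 vector.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels) {
    labels <- as.logical(labels)
    nP <- sum(labels)
    nN <- sum(!labels)
    if (nP == 0L || nN == 0L) stop("both classes must be present")
    r <- rank(scores)
    (sum(r[labels]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Jaccard index of two term sets
#'
#' Intersection over union; 0 when both sets are empty.
#'
#' @param termsA,termsB Character vectors.
#' @return Scalar in [0, 1].
#' @export
jaccardIndex <- function(termsA, termsB) {
    u <- length(union(termsA, termsB))
    if (u == 0L) return(0)
    length(intersect(termsA, termsB)) / u
}

#' Jaccard profile of the top-ranked cross-species pairs
#'
#' Ranks all annotated cross-species pairs by score (descending, ties
#' broken lexicographically on the id pair), optionally removes anchor
#' pairs first, and returns the Jaccard index of the full term profiles of
#' the top \code{k} pairs. Only genes with at least one annotation enter
#' the ranking.
#'
#' @param S A \linkS4class{ScoreMatrix}.
#' @param annA,annB \linkS4class{AnnotationTable}s.
#' @param k Number of top pairs.
#' @param excludeAnchors Drop anchor pairs before ranking?
#' @param anchors \linkS4class{OrthologAnchors} or two-column id matrix
#'   (required when \code{excludeAnchors}).
#' @return Numeric vector of length \code{k} of Jaccard indices, in rank
#'   order.
#' @export
jaccardTopK <- function(S, annA, annB, k, excludeAnchors = FALSE,
                        anchors = NULL) {
    if (k <= 0L) stop("k must be positive")
    v <- values(S)
    gA <- intersect(rownames(v), names(geneToTerms(annA)))
    gB <- intersect(colnames(v), names(geneToTerms(annB)))
    v <- v[gA, gB, drop = FALSE]
    idA <- rep(gA, times = length(gB))
    idB <- rep(gB, each = length(gA))
    sc <- as.vector(v)
    if (excludeAnchors) {
        if (is.null(anchors)) stop("anchors required to exclude them")
        am <- if (methods::is(anchors, "OrthologAnchors")) anchorIds(anchors)
              else anchors
        drop <- paste(idA, idB) %in% paste(am[, 1L], am[, 2L])
        sc <- sc[!drop]; idA <- idA[!drop]; idB <- idB[!drop]
    }
    if (k > length(sc)) stop("k exceeds the number of annotated pairs")
    ord <- .rankOrder(sc, idA, idB)[seq_len(k)]
    g2tA <- geneToTerms(annA)
    g2tB <- geneToTerms(annB)
    vapply(ord, function(i) jaccardIndex(g2tA[[idA[i]]], g2tB[[idB[i]]]), 0)
}

#' Top-percentile cross-species score graph
#'
#' Selects the \code{floor(percent/100 * n * n')} highest-scoring pairs
#' (deterministic tie-break: score descending, then lexicographic id pair)
#' as edges of an unweighted bipartite graph, optionally dropping vertices
#' whose degree in that graph is below \code{minDegree}.
#'
#' @param S A \linkS4class{ScoreMatrix}.
#' @param percent Percentage of all pairs to keep (0 < percent <= 100).
#' @param minDegree Vertices with smaller degree are omitted (0 keeps
#'   all).
#' @return \code{data.frame} with columns \code{geneA}, \code{geneB},
#'   \code{score}; zero rows (with a warning) if the degree filter empties
#'   the graph.
#' @export
topPercentGraph <- function(S, percent = 1, minDegree = 0L) {
    if (percent <= 0 || percent > 100) stop("percent must be in (0, 100]")
    v <- values(S)
    m <- floor(percent / 100 * length(v))
    if (m < 1L) stop("zero pairs selected; increase percent")
    idA <- rep(rownames(v), times = ncol(v))
    idB <- rep(colnames(v), each = nrow(v))
    sc <- as.vector(v)
    top <- .rankOrder(sc, idA, idB)[seq_len(m)]
    edges <- data.frame(geneA = idA[top], geneB = idB[top],
                        score = sc[top], stringsAsFactors = FALSE)
    if (minDegree > 0L) {
        degA <- table(edges$geneA)
        degB <- table(edges$geneB)
        keep <- degA[edges$geneA] >= minDegree & degB[edges$geneB] >= minDegree
        edges <- edges[as.vector(keep), , drop = FALSE]
        if (nrow(edges) == 0L)
            warning("degree filter removed every vertex; empty graph")
    }
    rownames(edges) <- NULL
    edges
}
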