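#' @include AllClasses.R
NULL

#' @rdname vertexIds
#' @export
setMethod("vertexIds", "PPINetwork", function(x) x@vertexIds)

#' @rdname vertexIds
#' @export
setMethod("vertexIds", "NetMFMatrix", function(x) x@vertexIds)

#' @rdname adjacency
#' @export
setMethod("adjacency", "PPINetwork", function(x) x@adjacency)

#' @rdname numVertices
#' @export
setMethod("numVertices", "PPINetwork", function(x) length(x@vertexIds))

#' @rdname degrees
#' @export
setMethod("degrees", "PPINetwork", function(x) {
    d <- as.integer(Matrix::rowSums(x@adjacency))
    names(d) <- x@vertexIds
    d
})

#' @rdname graphVolume
#' @export
setMethod("graphVolume", "PPINetwork", function(x) sum(Matrix::rowSums(x@adjacency)))

#' @rdname edgeList
#' @export
setMethod("edgeList", "PPINetwork", function(x) {
    A <- methods::as(methods::as(x@adjacency, "generalMatrix"), "TsparseMatrix")
    keep <- A@i < A@j
    cbind(x@vertexIds[A@i[keep] + 1L], x@vertexIds[A@j[keep] + 1L])
})

#' @rdname anchorPairs
#' @export
setMethod("anchorPairs", "OrthologAnchors", function(x) x@pairs)

#' @rdname anchorIds
#' @export
setMethod("anchorIds", "OrthologAnchors", function(x) x@sourceIds)

#' @rdname numAnchors
#' @export
setMethod("numAnchors", "OrthologAnchors", function(x) nrow(x@pairs))

#' @rdname geneToTerms
#' @export
setMethod("geneToTerms", "AnnotationTable", function(x) x@geneToTerms)

#' @rdname termToGenes
#' @export
setMethod("termToGenes", "AnnotationTable", function(x) x@termToGenes)

#' @rdname isPropagated
#' @export
setMethod("isPropagated", "AnnotationTable", function(x) x@propagated)

#' @rdname values
#' @export
setMethod("values", "ScoreMatrix", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "NetMFMatrix", function(x) x@values)

#' @rdname latentEmbedding
#' @export
setMethod("latentEmbedding", "JointEmbedding", function(x, species = c("A", "B")) {
    species <- match.arg(species)
    if (species == "A") x@ZA else x@ZB
})

#' @rdname trainingLog
#' @export
setMethod("trainingLog", "JointEmbedding", function(x) x@trainLog)
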