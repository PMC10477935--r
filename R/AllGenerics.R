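#' @include utils-rng.R
NULL

#' Vertex identifiers of an object
#'
#' @param x A \linkS4class{PPINetwork}, \linkS4class{NetMFMatrix}, or other
#'   object carrying an ordered vertex set.
#' @return Character vector of gene identifiers in vertex order.
#' @export
setGeneric("vertexIds", function(x) standardGeneric("vertexIds"))

#' Adjacency matrix of a network
#'
#' @param x A \linkS4class{PPINetwork}.
#' @return A symmetric sparse 0/1 \code{Matrix} with zero diagonal.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Number of vertices
#' @param x A \linkS4class{PPINetwork}.
#' @return Integer vertex count.
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' Vertex degrees
#' @param x A \linkS4class{PPINetwork}.
#' @return Integer vector of degrees, named by vertex id.
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' Graph volume (sum of degrees)
#' @param x A \linkS4class{PPINetwork}.
#' @return Numeric scalar, twice the edge count.
#' @export
setGeneric("graphVolume", function(x) standardGeneric("graphVolume"))

#' Edge list of a network
#' @param x A \linkS4class{PPINetwork}.
#' @return Two-column character matrix of undirected edges (each once).
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' Encode input rows to the latent space
#'
#' @param object An \linkS4class{Autoencoder}.
#' @param x Numeric matrix whose rows are inputs (one per vertex), or a
#'   \linkS4class{NetMFMatrix}.
#' @return Numeric matrix of latent embeddings, one row per input row.
#' @export
setGeneric("encode", function(object, x) standardGeneric("encode"))

#' Decode latent rows to reconstruction logits
#'
#' @param object An \linkS4class{Autoencoder}.
#' @param z Numeric matrix of latent rows.
#' @return Numeric matrix of pre-sigmoid reconstruction logits.
#' @export
setGeneric("decode", function(object, z) standardGeneric("decode"))

#' Anchor index pairs
#' @param x An \linkS4class{OrthologAnchors}.
#' @return Two-column integer matrix of (index in A, index in B) pairs.
#' @export
setGeneric("anchorPairs", function(x) standardGeneric("anchorPairs"))

#' Anchor identifier pairs
#' @param x An \linkS4class{OrthologAnchors}.
#' @return Two-column character matrix of the surviving source id pairs.
#' @export
setGeneric("anchorIds", function(x) standardGeneric("anchorIds"))

#' Number of anchors
#' @param x An \linkS4class{OrthologAnchors}.
#' @return Integer count of anchor pairs.
#' @export
setGeneric("numAnchors", function(x) standardGeneric("numAnchors"))

#' Gene-to-term annotation map
#' @param x An \linkS4class{AnnotationTable}.
#' @return Named list mapping gene id to a character vector of term ids.
#' @export
setGeneric("geneToTerms", function(x) standardGeneric("geneToTerms"))

#' Term-to-gene annotation map
#' @param x An \linkS4class{AnnotationTable}.
#' @return Named list mapping term id to a character vector of gene ids.
#' @export
setGeneric("termToGenes", function(x) standardGeneric("termToGenes"))

#' Has the table been propagated through the ontology?
#' @param x An \linkS4class{AnnotationTable}.
#' @return Logical flag.
#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))

#' Latent embedding of one species from a joint fit
#'
#' @param x A \linkS4class{JointEmbedding}.
#' @param species \code{"A"} or \code{"B"}, in the argument order of the
#'   \code{\link{fitJoint}} call that produced \code{x}.
#' @return Numeric matrix of latent rows, rownames are gene ids.
#' @export
setGeneric("latentEmbedding", function(x, species = c("A", "B"))
    standardGeneric("latentEmbedding"))

#' Cross-species cosine score matrix
#'
#' @param x A \linkS4class{JointEmbedding}.
#' @param ... Unused.
#' @return A \linkS4class{ScoreMatrix} with rows = species A, cols = B.
#' @export
setGeneric("scoreMatrix", function(x, ...) standardGeneric("scoreMatrix"))

#' Numeric values of a matrix-like object
#' @param x A \linkS4class{ScoreMatrix} or \linkS4class{NetMFMatrix}.
#' @return Base numeric matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Training log of a joint fit
#' @param x A \linkS4class{JointEmbedding}.
#' @return \code{data.frame} of per-block losses.
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))
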