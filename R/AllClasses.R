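#' @include AllGenerics.R
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' PPINetwork: an undirected, unweighted, simple graph
#'
#' Stores an ordered vertex set of gene identifiers and a symmetric binary
#' adjacency matrix with zero diagonal. This is the canonical network
#' container for the whole package: readers produce it, the preprocessing
#' step consumes and returns it, and the random-walk matrix is computed from
#' it.
#'
#' @slot vertexIds Character vector of gene identifiers in vertex order.
#' @slot adjacency Symmetric sparse 0/1 \code{Matrix}, zero diagonal.
#' @slot metadata List of provenance notes (e.g. self-loop counts removed
#'   at read time).
#' @export
setClass("PPINetwork",
    representation(vertexIds = "character", adjacency = "Matrix",
                   metadata = "list"),
    prototype(metadata = list()))

setValidity("PPINetwork", function(object) {
    A <- object@adjacency
    n <- length(object@vertexIds)
    msg <- character()
    if (nrow(A) != n || ncol(A) != n)
        msg <- c(msg, "adjacency dimensions do not match vertex count")
    if (anyDuplicated(object@vertexIds))
        msg <- c(msg, "duplicated vertex identifiers")
    if (n > 0) {
        if (!Matrix::isSymmetric(A))
            msg <- c(msg, "adjacency is not symmetric")
        if (any(Matrix::diag(A) != 0))
            msg <- c(msg, "adjacency has nonzero diagonal")
        v <- A@x
        if (length(v) && !all(v %in% c(0, 1)))
            msg <- c(msg, "adjacency entries must be 0/1")
    }
    if (length(msg)) msg else TRUE
})

#' PreprocessReport: a replayable log of network preprocessing
#'
#' Records, per recursion round, the vertices removed because they were
#' isolated and the duplicate-neighborhood groups collapsed to a random
#' representative. \code{\link{replayPreprocess}} applies the report to the
#' raw network and reproduces the preprocessed network exactly.
#'
#' @slot selfLoops Integer count of self-loops removed when the raw edge
#'   list was read (copied from network metadata when available).
#' @slot rounds List; element \code{r} is a list with components
#'   \code{isolated} (character ids removed) and \code{groups} (list of
#'   lists with \code{kept} and \code{removed} ids).
#' @slot seed Integer seed used to pick group representatives.
#' @export
setClass("PreprocessReport",
    representation(selfLoops = "integer", rounds = "list", seed = "integer"))

#' OrthologAnchors: cross-network anchor pairs
#'
#' Ortholog pairs mapped to vertex indices of two preprocessed networks.
#' Pairs whose genes are absent from either network are dropped (and kept in
#' \code{dropped}); duplicates are collapsed.
#'
#' @slot pairs Two-column integer matrix of (index in A, index in B).
#' @slot sourceIds Two-column character matrix of the surviving id pairs.
#' @slot dropped Two-column character matrix of input pairs that were
#'   dropped because a gene was missing from a network.
#' @export
setClass("OrthologAnchors",
    representation(pairs = "matrix", sourceIds = "matrix",
                   dropped = "matrix"))

setValidity("OrthologAnchors", function(object) {
    msg <- character()
    if (ncol(object@pairs) != 2L) msg <- c(msg, "pairs must have 2 columns")
    if (nrow(object@pairs) != nrow(object@sourceIds))
        msg <- c(msg, "pairs and sourceIds row counts differ")
    if (anyDuplicated(paste(object@pairs[, 1L], object@pairs[, 2L])))
        msg <- c(msg, "duplicate anchor pairs")
    if (length(msg)) msg else TRUE
})

#' AnnotationTable: gene-to-term functional annotations
#'
#' A two-way map between genes and ontology terms, optionally closed under
#' ancestor propagation along the declared ontology relations.
#'
#' @slot geneToTerms Named list: gene id -> character vector of term ids.
#' @slot termToGenes Named list: term id -> character vector of gene ids
#'   (exact inverse of \code{geneToTerms}).
#' @slot propagated Logical; \code{TRUE} once the table is closed under
#'   ancestor traversal.
#' @export
setClass("AnnotationTable",
    representation(geneToTerms = "list", termToGenes = "list",
                   propagated = "logical"),
    prototype(propagated = FALSE))

setValidity("AnnotationTable", function(object) {
    g2t <- object@geneToTerms
    t2g <- object@termToGenes
    fwd <- sort(paste(rep(names(g2t), lengths(g2t)), unlist(g2t, use.names = FALSE)))
    rev <- sort(paste(unlist(t2g, use.names = FALSE), rep(names(t2g), lengths(t2g))))
    if (!identical(fwd, rev))
        return("geneToTerms and termToGenes are not exact inverses")
    TRUE
})

#' NetMFMatrix: truncated-log random-walk similarity matrix
#'
#' The dense nonnegative matrix whose rows are the autoencoder inputs.
#' Entry (i, j) is a truncated-log weighted count of paths of length at
#' most \code{window} joining vertices i and j, normalized by the stationary
#' degree distribution; structural zeros (no short path) stay exactly zero.
#'
#' @slot values Dense numeric n-by-n matrix.
#' @slot window Integer context window T (maximum path length counted).
#' @slot negative Positive numeric negative-sampling parameter b.
#' @slot vertexIds Character vertex ids copied from the source network.
#' @export
setClass("NetMFMatrix",
    representation(values = "matrix", window = "integer",
                   negative = "numeric", vertexIds = "character"))

setValidity("NetMFMatrix", function(object) {
    msg <- character()
    if (nrow(object@values) != ncol(object@values))
        msg <- c(msg, "values must be square")
    if (nrow(object@values) != length(object@vertexIds))
        msg <- c(msg, "vertexIds length must match matrix dimension")
    if (any(!is.finite(object@values)) || any(object@values < 0))
        msg <- c(msg, "values must be finite and nonnegative")
    if (object@window < 1L) msg <- c(msg, "window must be >= 1")
    if (object@negative <= 0) msg <- c(msg, "negative must be > 0")
    if (length(msg)) msg else TRUE
})

#' Autoencoder: encoder-decoder weights for one species
#'
#' A symmetric-shape autoencoder: encoder n -> hidden -> latent, decoder
#' latent -> hidden -> n with an independent hidden layer. Hidden layers use
#' a leaky rectifier (negative slope 0.1); the latent layer and the output
#' logits are affine. The decoder output is interpreted as pre-sigmoid
#' logits of the reconstruction.
#'
#' @slot dims Named integer vector \code{c(n, hidden, latent)}.
#' @slot weights List of parameter matrices/vectors \code{W1, b1, W2, b2}
#'   (encoder) and \code{W3, b3, W4, b4} (decoder).
#' @slot slope Numeric negative slope of the leaky rectifier.
#' @slot seed Integer initialization seed.
#' @export
setClass("Autoencoder",
    representation(dims = "integer", weights = "list", slope = "numeric",
                   seed = "integer"),
    prototype(slope = 0.1))

#' JointEmbedding: an aligned two-species embedding
#'
#' Result of \code{\link{fitJoint}}: the two latent embedding matrices in a
#' shared space, the final autoencoder parameters, the per-block training
#' log and the configuration snapshot. Internally species are stored in a
#' canonical content-derived order so that swapping the two input networks
#' reproduces the identical computation; accessors present results in the
#' caller's argument order.
#'
#' @slot ZA,ZB Latent matrices for the caller's species A and B.
#' @slot aeA,aeB Final \linkS4class{Autoencoder} objects.
#' @slot trainLog \code{data.frame} of per-block losses.
#' @slot config List: the full configuration used for the fit.
#' @slot anchors The \linkS4class{OrthologAnchors} used.
#' @export
setClass("JointEmbedding",
    representation(ZA = "matrix", ZB = "matrix", aeA = "Autoencoder",
                   aeB = "Autoencoder", trainLog = "data.frame",
                   config = "list", anchors = "OrthologAnchors"))

setValidity("JointEmbedding", function(object) {
    if (ncol(object@ZA) != ncol(object@ZB))
        return("latent widths of the two species differ")
    TRUE
})

#' ScoreMatrix: cross-species cosine similarity scores
#'
#' Dense matrix of cosine similarities between every species-A embedding
#' row and every species-B embedding row; entries lie in [-1, 1].
#'
#' @slot values Numeric matrix, rownames = species A ids, colnames = B ids.
#' @export
setClass("ScoreMatrix", representation(values = "matrix"))

setValidity("ScoreMatrix", function(object) {
    v <- object@values
    if (any(!is.finite(v))) return("scores must be finite")
    if (any(v < -1 - 1e-8) || any(v > 1 + 1e-8))
        return("cosine scores must lie in [-1, 1]")
    TRUE
})
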