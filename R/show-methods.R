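#' @include AllClasses.R
NULL

setMethod("show", "PPINetwork", function(object) {
    n <- length(object@vertexIds)
    m <- sum(Matrix::rowSums(object@adjacency)) / 2
    cat("PPINetwork with", n, "vertices and", m, "edges\n")
    if (n) cat("  vertices:", paste(utils::head(object@vertexIds, 4L),
                                    collapse = ", "),
               if (n > 4L) "..." else "", "\n")
})

setMethod("show", "PreprocessReport", function(object) {
    iso <- sum(vapply(object@rounds, function(r) length(r$isolated), 1L))
    grp <- sum(vapply(object@rounds, function(r) length(r$groups), 1L))
    cat("PreprocessReport:", length(object@rounds), "round(s),",
        iso, "isolated vertices removed,", grp,
        "duplicate-neighborhood groups collapsed",
        sprintf("(seed %d)\n", object@seed))
})

setMethod("show", "OrthologAnchors", function(object) {
    cat("OrthologAnchors with", nrow(object@pairs), "pairs (",
        nrow(object@dropped), "dropped )\n")
})

setMethod("show", "AnnotationTable", function(object) {
    cat("AnnotationTable:", length(object@geneToTerms), "genes,",
        length(object@termToGenes), "terms,",
        if (object@propagated) "propagated" else "not propagated", "\n")
})

setMethod("show", "NetMFMatrix", function(object) {
    cat(sprintf("NetMFMatrix %d x %d (window T=%d, negative b=%g)\n",
                nrow(object@values), ncol(object@values), object@window,
                object@negative))
})

setMethod("show", "Autoencoder", function(object) {
    d <- object@dims
    cat(sprintf("Autoencoder %d -> %d -> %d -> %d -> %d (leaky slope %g)\n",
                d[["n"]], d[["hidden"]], d[["latent"]], d[["hidden"]],
                d[["n"]], object@slope))
})

setMethod("show", "JointEmbedding", function(object) {
    cat(sprintf("JointEmbedding: %d x %d (A) and %d x %d (B), %d anchors, %d blocks\n",
                nrow(object@ZA), ncol(object@ZA), nrow(object@ZB),
                ncol(object@ZB), nrow(object@anchors@pairs),
                if (nrow(object@trainLog)) max(object@trainLog$block) else 0L))
})

setMethod("show", "ScoreMatrix", function(object) {
    cat(sprintf("ScoreMatrix %d x %d, range [%.3f, %.3f]\n",
                nrow(object@values), ncol(object@values),
                min(object@values), max(object@values)))
})
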