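#' @include sl-predict.R
NULL

## Planted-partition edge sampler over a fixed module assignment; returns
## a 2-column integer matrix of edges (i < j).
.plantedEdges <- function(module, pIn, pOut) {
    n <- length(module)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- module[idx[, 1L]] == module[idx[, 2L]]
    p <- ifelse(same, pIn, pOut)
    keep <- stats::runif(nrow(idx)) < p
    idx[keep, , drop = FALSE]
}

## Duplication-divergence edge sampler: grow from a seed clique; each new
## vertex copies a random existing vertex's edges, keeping each with
## probability retain, plus one uniform random edge. Heavier degree tails
## than the planted-partition core; module labels are inherited from the
## copied vertex.
.dupDivergence <- function(n, retain = 0.4, seedSize = 4L) {
    edges <- t(utils::combn(seedSize, 2L))
    module <- rep(1L, seedSize)
    nbr <- lapply(seq_len(seedSize), function(i)
        setdiff(seq_len(seedSize), i))
    for (v in (seedSize + 1L):n) {
        anc <- sample.int(v - 1L, 1L)
        kept <- nbr[[anc]][stats::runif(length(nbr[[anc]])) < retain]
        extra <- sample.int(v - 1L, 1L)
        kept <- unique(c(kept, extra))
        edges <- rbind(edges, cbind(kept, v))
        for (u in kept) nbr[[u]] <- c(nbr[[u]], v)
        nbr[[v]] <- kept
        module <- c(module, module[anc])
    }
    list(edges = edges, module = module)
}

#' Generate a pair of twin networks with planted correspondence
#'
#' Emulates the two-species setting: a planted-partition core graph with
#' \code{modules} near-equal communities is shared between the species.
#' Species A carries the core plus its own species-specific vertices with
#' random attachments; species B carries an isomorphic copy of the core
#' (vertices relabeled under a random permutation) in which every core
#' edge is independently rewired with probability \code{rewireP}, plus its
#' own species-specific part. A seeded subsample of the true
#' correspondence is designated as the anchor set; the rest serve as
#' held-out evaluation pairs.
#'
#' @param nCore Number of shared core vertices.
#' @param modules Number of planted modules.
#' @param pIn,pOut Within/between-module edge probabilities
#'   (\code{pIn > pOut}).
#' @param rewireP Per-edge rewiring probability in species B's core copy.
#' @param speciesSpecificFrac Species-specific vertices as a fraction of
#'   \code{nCore}, added to each species.
#' @param anchorFrac Fraction of true pairs given as anchors.
#' @param seed Integer seed.
#' @param coreModel \code{"planted"} (default) or \code{"duplication"}
#'   for a duplication-divergence core with heavier degree tails.
#' @param attempts Regeneration attempts if noise collapses the network.
#' @return List with \code{netA}, \code{netB}
#'   (\linkS4class{PPINetwork}s) and \code{truth}, a \code{TwinPairTruth}
#'   list: \code{trueMap} (two-column id matrix over the core),
#'   \code{anchors} (subsampled rows of \code{trueMap}), \code{moduleA},
#'   \code{moduleB} (named module labels of core genes), \code{rewireLog}
#'   (original and replacement edges), \code{params}, \code{seed}.
#' @export
generateNetworkPair <- function(nCore = 300L, modules = 3L, pIn = 0.15,
                                pOut = 0.02, rewireP = 0.05,
                                speciesSpecificFrac = 0.1,
                                anchorFrac = 0.5, seed = 1L,
                                coreModel = c("planted", "duplication"),
                                attempts = 10L) {
    coreModel <- match.arg(coreModel)
    stopifnot(pIn > pOut, rewireP >= 0, rewireP <= 1,
              speciesSpecificFrac >= 0, speciesSpecificFrac <= 1,
              anchorFrac >= 0, anchorFrac <= 1)
    for (att in seq_len(attempts)) {
        out <- try(withSeed(.mixSeed(seed, paste0("twin:", att)),
                            .generatePairOnce(nCore, modules, pIn, pOut,
                                              rewireP, speciesSpecificFrac,
                                              anchorFrac, coreModel)),
                   silent = TRUE)
        if (!inherits(out, "try-error")) {
            out$truth$seed <- as.integer(seed)
            out$truth$params <- list(nCore = nCore, modules = modules,
                                     pIn = pIn, pOut = pOut,
                                     rewireP = rewireP,
                                     speciesSpecificFrac = speciesSpecificFrac,
                                     anchorFrac = anchorFrac,
                                     coreModel = coreModel)
            return(out)
        }
    }
    stop("failed to generate a usable network pair in ", attempts,
         " attempts: ", attr(out, "condition")$message)
}

.generatePairOnce <- function(nCore, modules, pIn, pOut, rewireP,
                              speciesSpecificFrac, anchorFrac, coreModel) {
    if (coreModel == "planted") {
        module <- sort(rep_len(seq_len(modules), nCore))
        core <- .plantedEdges(module, pIn, pOut)
    } else {
        dd <- .dupDivergence(nCore)
        core <- dd$edges
        module <- dd$module
    }
    ## guarantee min degree 1 inside the core
    deg <- tabulate(core, nCore)
    for (v in which(deg == 0)) {
        mates <- setdiff(which(module == module[v]), v)
        u <- mates[sample.int(length(mates), 1L)]
        core <- rbind(core, c(min(u, v), max(u, v)))
    }
    idsA <- sprintf("a%04d", seq_len(nCore))
    perm <- sample.int(nCore)              # core index -> B index
    idsB <- sprintf("b%04d", seq_len(nCore))
    ## species B core copy with seeded rewiring
    coreKeyB <- function(e) paste(pmin(e[, 1L], e[, 2L]),
                                  pmax(e[, 1L], e[, 2L]))
    edgesB <- cbind(perm[core[, 1L]], perm[core[, 2L]])
    existB <- coreKeyB(edgesB)
    rewire <- which(stats::runif(nrow(edgesB)) < rewireP)
    rewireLog <- list()
    for (r in rewire) {
        u <- edgesB[r, 1L]
        for (try in 1:20) {
            w <- sample.int(nCore, 1L)
            key <- paste(min(u, w), max(u, w))
            if (w != u && !(key %in% existB)) {
                rewireLog[[length(rewireLog) + 1L]] <-
                    data.frame(fromA = idsB[edgesB[r, 1L]],
                               fromB = idsB[edgesB[r, 2L]],
                               toA = idsB[u], toB = idsB[w])
                edgesB[r, ] <- c(u, w)
                existB <- c(existB, key)
                break
            }
        }
    }
    ## species-specific parts: extra vertices wired to random vertices
    addSpecific <- function(edges, n, prefix) {
        nExtra <- round(speciesSpecificFrac * nCore)
        if (nExtra == 0L) return(list(edges = edges, extraIds = character()))
        extraIds <- sprintf("%s%04d", prefix, seq_len(nExtra))
        add <- list()
        for (x in seq_len(nExtra)) {
            kdeg <- 1L + stats::rpois(1L, 2)
            tgt <- sample.int(n, min(kdeg, n))
            add[[x]] <- cbind(n + x, tgt)
        }
        list(edges = rbind(edges, do.call(rbind, add)), extraIds = extraIds)
    }
    spA <- addSpecific(core, nCore, "ax")
    spB <- addSpecific(edgesB, nCore, "bx")
    allIdsA <- c(idsA, spA$extraIds)
    allIdsB <- c(idsB, spB$extraIds)
    eA <- cbind(allIdsA[spA$edges[, 1L]], allIdsA[spA$edges[, 2L]])
    eB <- cbind(allIdsB[spB$edges[, 1L]], allIdsB[spB$edges[, 2L]])
    netA <- .networkFromEdges(eA, metadata = list(synthetic = TRUE))
    netB <- .networkFromEdges(eB, metadata = list(synthetic = TRUE))
    if (numVertices(netA) < nCore / 2 || numVertices(netB) < nCore / 2)
        stop("network collapsed under noise")
    ## both outputs must survive preprocessing
    preA <- preprocessNetwork(netA, seed = 1L)
    preB <- preprocessNetwork(netB, seed = 1L)
    trueMap <- cbind(idA = idsA, idB = idsB[perm])
    nAnchor <- max(1L, round(anchorFrac * nCore))
    anchorRows <- sort(sample.int(nCore, nAnchor))
    truth <- structure(list(
        trueMap = trueMap,
        anchors = trueMap[anchorRows, , drop = FALSE],
        moduleA = stats::setNames(module, idsA),
        moduleB = stats::setNames(module, idsB[perm]),
        rewireLog = if (length(rewireLog)) do.call(rbind, rewireLog)
                    else data.frame(fromA = character(), fromB = character(),
                                    toA = character(), toB = character()),
        params = NULL, seed = NA_integer_), class = "TwinPairTruth")
    list(netA = netA, netB = netB, truth = truth)
}

#' Shipped twin-network presets
#'
#' \code{twin-small}: the default study condition (300 core genes, 3
#' modules, 5\% edge rewiring, 10\% species-specific vertices, half of the
#' true pairs given as anchors). \code{twin-noisy}: heavier noise (15\%
#' rewiring, 20\% species-specific, 30\% anchors).
#'
#' @param name Preset name.
#' @return Named list of \code{\link{generateNetworkPair}} arguments.
#' @export
twinPreset <- function(name = c("twin-small", "twin-noisy")) {
    name <- match.arg(name)
    base <- list(nCore = 300L, modules = 3L, pIn = 0.15, pOut = 0.02,
                 rewireP = 0.05, speciesSpecificFrac = 0.1,
                 anchorFrac = 0.5)
    if (name == "twin-noisy") {
        base$rewireP <- 0.15
        base$speciesSpecificFrac <- 0.2
        base$anchorFrac <- 0.3
    }
    base
}

#' Generate module-structured annotations for a twin pair
#'
#' Each term draws most of its genes from one planted module (preferential
#' sampling), so co-annotation mirrors module co-membership; corresponding
#' genes across the true map share terms except for seeded membership
#' flips at rate \code{flipP} in species B. The returned tables are closed
#' over a trivial two-level ontology (every term is_a one root term) and
#' marked propagated.
#'
#' @param truth \code{TwinPairTruth} from
#'   \code{\link{generateNetworkPair}}.
#' @param nTerms Number of terms.
#' @param termSizeRange Inclusive (min, max) annotated-gene counts per
#'   term.
#' @param flipP Per-membership flip probability in species B.
#' @param homeFrac Fraction of a term's genes drawn from its home module.
#' @param seed Integer seed.
#' @return List with \code{annA}, \code{annB}
#'   (\linkS4class{AnnotationTable}s) and \code{ontology} (relation
#'   table).
#' @export
generateModuleAnnotations <- function(truth, nTerms = 30L,
                                      termSizeRange = c(10L, 100L),
                                      flipP = 0.05, homeFrac = 0.85,
                                      seed = 1L) {
    genesA <- truth$trueMap[, 1L]
    mapB <- stats::setNames(truth$trueMap[, 2L], genesA)
    module <- truth$moduleA[genesA]
    nModules <- max(module)
    lo <- termSizeRange[1L]
    hi <- min(termSizeRange[2L], length(genesA))
    if (lo > hi) stop("infeasible term sizes for this core")
    withSeed(.mixSeed(seed, "annotations"), {
        gA <- character(); tA <- character()
        gB <- character(); tB <- character()
        for (t in seq_len(nTerms)) {
            term <- sprintf("T:%04d", t)
            home <- 1L + (t - 1L) %% nModules
            size <- sample(lo:hi, 1L)
            inHome <- genesA[module == home]
            outHome <- genesA[module != home]
            nIn <- min(round(homeFrac * size), length(inHome))
            members <- c(sample(inHome, nIn),
                         sample(outHome, min(size - nIn, length(outHome))))
            gA <- c(gA, members); tA <- c(tA, rep(term, length(members)))
            isMember <- genesA %in% members
            flip <- stats::runif(length(genesA)) < flipP
            membersB <- mapB[genesA[xor(isMember, flip)]]
            gB <- c(gB, membersB); tB <- c(tB, rep(term, length(membersB)))
        }
        ontology <- data.frame(term = sort(unique(tA)), parent = "T:ROOT",
                               relation = "is_a")
        annA <- propagateAnnotations(annotationTable(gA, tA), ontology)
        annB <- propagateAnnotations(annotationTable(gB, tB), ontology)
        list(annA = annA, annB = annB, ontology = ontology)
    })
}

#' Generate synthetic-lethality-style labeled pairs
#'
#' Positives are within-module gene pairs of species A, mirrored across
#' the true correspondence into species B so that cross-species transfer
#' is learnable; negatives are between-module pairs among the genes that
#' participate in positives. Class balance is exactly 1:1 per species.
#'
#' @param truth \code{TwinPairTruth}.
#' @param nPos Number of positive pairs.
#' @param seed Integer seed.
#' @return List of two \code{data.frame}s (\code{A}, \code{B}) with
#'   columns \code{geneA}, \code{geneB}, \code{label}.
#' @export
generateSLPairs <- function(truth, nPos = 200L, seed = 1L) {
    genesA <- truth$trueMap[, 1L]
    mapB <- stats::setNames(truth$trueMap[, 2L], genesA)
    module <- truth$moduleA[genesA]
    withSeed(.mixSeed(seed, "sl"), {
        within <- list()
        for (m in sort(unique(module))) {
            g <- genesA[module == m]
            cmb <- t(utils::combn(g, 2L))
            within[[m]] <- cmb
        }
        within <- do.call(rbind, within)
        if (nrow(within) < nPos) stop("nPos infeasible: too few within-module pairs")
        pos <- within[sample.int(nrow(within), nPos), , drop = FALSE]
        posGenes <- sort(unique(as.vector(pos)))
        neg <- matrix(character(), 0L, 2L)
        seen <- character()
        while (nrow(neg) < nPos) {
            i <- sample(posGenes, 2L * nPos, replace = TRUE)
            j <- sample(posGenes, 2L * nPos, replace = TRUE)
            ok <- module[i] != module[j]
            a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
            key <- paste(a, b)
            new <- !(key %in% seen) & !duplicated(key)
            seen <- c(seen, key[new])
            neg <- rbind(neg, cbind(a[new], b[new]))
        }
        neg <- neg[seq_len(nPos), , drop = FALSE]
        dfA <- data.frame(geneA = c(pos[, 1L], neg[, 1L]),
                          geneB = c(pos[, 2L], neg[, 2L]),
                          label = rep(c(TRUE, FALSE), each = nPos),
                          stringsAsFactors = FALSE)
        dfB <- data.frame(geneA = mapB[dfA$geneA], geneB = mapB[dfA$geneB],
                          label = dfA$label, stringsAsFactors = FALSE,
                          row.names = NULL)
        list(A = dfA, B = dfB)
    })
}
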