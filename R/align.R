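#' @include training.R
NULL

## Default fit configuration. epochsPerBlock controls how many embedding
## passes each species takes inside one training block; alignEpochs how
## many alignment passes follow them.
.defaultFitConfig <- function() {
    list(window = 10L, negative = 1, hidden = 1024L, latent = 128L,
         lr = 1e-3, batchSize = 128L, epochsPerBlock = 2L, alignEpochs = 32L,
         alignLr = NULL, alignBatch = NULL, clip = 5, divergenceGuard = 1e6,
         adjacencyInput = FALSE, crossTraining = TRUE)
}

#' Fit a joint cross-species embedding
#'
#' Runs the full alignment: computes each species' random-walk input
#' matrix, initializes one autoencoder per species, then iterates training
#' blocks. A block is a round of embedding epochs for each species followed
#' by alignment epochs over the ortholog anchors; the alignment step only
#' updates encoders, pushing both latent spaces toward a joint space while
#' the per-species objectives keep within-species structure.
#'
#' The computation is bidirectional by construction: all random streams are
#' keyed by content hashes of the two networks and the two species are
#' processed in a canonical content-derived order, so
#' \code{fitJoint(A, B, ...)} and \code{fitJoint(B, A, ...)} (with mirrored
#' anchors) perform the identical computation and yield transposed score
#' matrices, exactly.
#'
#' @param netA,netB Preprocessed \linkS4class{PPINetwork} objects.
#' @param anchors \linkS4class{OrthologAnchors} oriented (A, B); nonempty.
#' @param weights A \code{\link{lossWeights}} list, or a list
#'   \code{list(A = , B = )} of two such lists for per-species weights
#'   (the cross-loss weight \code{phi} is taken from species A's list).
#' @param blocks Number of training blocks; 10 suits species pairs with
#'   richer networks and more anchors, 20 sparser ones. \code{blocks = 0}
#'   returns the seeded initial embeddings untouched.
#' @param config Named list overriding entries of the default
#'   configuration: \code{window}, \code{negative} (random-walk matrix),
#'   \code{hidden}, \code{latent} (architecture), \code{lr},
#'   \code{batchSize}, \code{epochsPerBlock}, \code{alignEpochs},
#'   \code{clip}, \code{divergenceGuard}, and the ablation switches
#'   \code{adjacencyInput} (raw adjacency rows replace the random-walk
#'   matrix) and \code{crossTraining} (\code{FALSE} skips alignment).
#' @param seed Master seed; every stream the fit uses derives from it.
#' @return A \linkS4class{JointEmbedding}.
#' @export
fitJoint <- function(netA, netB, anchors, weights = lossWeights(),
                     blocks = 10L, config = list(), seed = 1L) {
    if (numAnchors(anchors) == 0L) stop("anchors nonempty required")
    cfg <- utils::modifyList(.defaultFitConfig(), config)
    if (!is.null(weights$alpha)) weights <- list(A = weights, B = weights)
    ## canonical species order keyed by network content, so that argument
    ## order cannot change any arithmetic
    hA <- .networkHash(netA)
    hB <- .networkHash(netB)
    swap <- (hB < hA) || (hB == hA && numVertices(netB) < numVertices(netA))
    nets <- if (swap) list(netB, netA) else list(netA, netB)
    wts <- if (swap) list(weights$B, weights$A) else list(weights$A, weights$B)
    hashes <- if (swap) c(hB, hA) else c(hA, hB)
    p <- anchorPairs(anchors)
    p <- if (swap) p[, 2:1, drop = FALSE] else p
    ord <- order(p[, 1L], p[, 2L])
    p <- p[ord, , drop = FALSE]
    phi <- wts[[1L]]$phi
    if (is.null(phi)) phi <- wts[[2L]]$phi

    inputs <- lapply(seq_len(2L), function(k) {
        if (isTRUE(cfg$adjacencyInput)) {
            X <- as.matrix(adjacency(nets[[k]]))
            dimnames(X) <- list(vertexIds(nets[[k]]), vertexIds(nets[[k]]))
            X
        } else {
            netmfMatrix(nets[[k]], window = cfg$window,
                        negative = cfg$negative)@values
        }
    })
    preps <- lapply(seq_len(2L), function(k)
        .prepSpecies(inputs[[k]], nets[[k]]))
    aes <- lapply(seq_len(2L), function(k)
        initAutoencoder(numVertices(nets[[k]]), hidden = cfg$hidden,
                        latent = cfg$latent,
                        seed = .mixSeed(seed, paste0("init:", hashes[k]))))
    states <- list(.adamInit(), .adamInit())
    log <- list()
    doAlign <- isTRUE(cfg$crossTraining) && phi > 0
    if (blocks > 0) for (blk in seq_len(blocks)) {
        embLoss <- c(NA_real_, NA_real_)
        for (k in seq_len(2L)) {
            for (ep in seq_len(cfg$epochsPerBlock)) {
                res <- .embedEpoch(aes[[k]]@weights, preps[[k]], wts[[k]],
                                   states[[k]],
                                   seed = .mixSeed(seed,
                                       sprintf("embed:%s:%d:%d", hashes[k], blk, ep)),
                                   lr = cfg$lr, batchSize = cfg$batchSize,
                                   clip = cfg$clip, slope = aes[[k]]@slope)
                aes[[k]]@weights <- res$w
                states[[k]] <- res$state
                embLoss[k] <- res$loss
            }
        }
        crossLoss <- NA_real_
        if (doAlign) {
            for (ep in seq_len(cfg$alignEpochs)) {
                res <- .alignEpoch(aes[[1L]]@weights, aes[[2L]]@weights,
                                   preps[[1L]], preps[[2L]], p, phi,
                                   states[[1L]], states[[2L]],
                                   seed = .mixSeed(seed,
                                       sprintf("align:%d:%d", blk, ep)),
                                   lr = if (is.null(cfg$alignLr)) cfg$lr
                                        else cfg$alignLr,
                                   batchSize = if (is.null(cfg$alignBatch))
                                       cfg$batchSize else cfg$alignBatch,
                                   clip = cfg$clip, slopeA = aes[[1L]]@slope,
                                   slopeB = aes[[2L]]@slope)
                aes[[1L]]@weights <- res$wA
                aes[[2L]]@weights <- res$wB
                states[[1L]] <- res$stateA
                states[[2L]] <- res$stateB
                crossLoss <- res$loss
            }
        }
        bad <- c(embLoss[is.finite(embLoss)], crossLoss[is.finite(crossLoss)])
        if (any(bad > cfg$divergenceGuard))
            stop(sprintf("training diverged at block %d (loss %.3g > %.3g)",
                         blk, max(bad), cfg$divergenceGuard))
        log[[blk]] <- data.frame(block = blk, lossEmbed1 = embLoss[1L],
                                 lossEmbed2 = embLoss[2L],
                                 lossCross = crossLoss)
    }
    Z <- lapply(seq_len(2L), function(k) {
        z <- .encodeW(aes[[k]]@weights, inputs[[k]], aes[[k]]@slope)
        rownames(z) <- vertexIds(nets[[k]])
        z
    })
    trainLog <- if (length(log)) do.call(rbind, log) else
        data.frame(block = integer(), lossEmbed1 = numeric(),
                   lossEmbed2 = numeric(), lossCross = numeric())
    iA <- if (swap) 2L else 1L
    iB <- if (swap) 1L else 2L
    userPairs <- if (swap) p[, 2:1, drop = FALSE] else p
    userAnchors <- methods::new("OrthologAnchors", pairs = userPairs,
                                sourceIds = cbind(vertexIds(nets[[iA]])[userPairs[, 1L]],
                                                  vertexIds(nets[[iB]])[userPairs[, 2L]]),
                                dropped = matrix(character(), 0L, 2L))
    methods::new("JointEmbedding", ZA = Z[[iA]], ZB = Z[[iB]],
                 aeA = aes[[iA]], aeB = aes[[iB]], trainLog = trainLog,
                 config = c(cfg, list(blocks = blocks, seed = seed,
                                      swap = swap,
                                      weightsA = if (swap) wts[[2L]] else wts[[1L]],
                                      weightsB = if (swap) wts[[1L]] else wts[[2L]],
                                      phi = phi)),
                 anchors = userAnchors)
}

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "JointEmbedding", function(x, ...) {
    ## compute in the canonical species order so the arithmetic (and hence
    ## the result, bit for bit) is independent of fitJoint's argument
    ## order; transpose — an exact operation — into the caller's
    ## orientation afterwards
    if (isTRUE(x@config$swap)) {
        S <- values(cosineScores(x@ZB, x@ZA))
        methods::new("ScoreMatrix", values = t(S))
    } else {
        cosineScores(x@ZA, x@ZB)
    }
})

#' Cosine score matrix between two embedding matrices
#'
#' \code{S[i, j] = z_i . z'_j / (||z_i|| ||z'_j||)}; rows are species A,
#' columns species B.
#'
#' @param ZA,ZB Numeric embedding matrices with equal column counts;
#'   rownames become the score matrix dimnames.
#' @return A \linkS4class{ScoreMatrix}.
#' @export
cosineScores <- function(ZA, ZB) {
    nA <- sqrt(rowSums(ZA^2))
    nB <- sqrt(rowSums(ZB^2))
    if (any(nA == 0))
        stop("zero-norm embedding row for vertex ",
             rownames(ZA)[which(nA == 0)[1L]])
    if (any(nB == 0))
        stop("zero-norm embedding row for vertex ",
             rownames(ZB)[which(nB == 0)[1L]])
    S <- tcrossprod(ZA / nA, ZB / nB)
    S[S > 1] <- 1
    S[S < -1] <- -1
    dimnames(S) <- list(rownames(ZA), rownames(ZB))
    methods::new("ScoreMatrix", values = S)
}

#' Seeded random search over loss-weight settings
#'
#' Draws weight settings log-uniformly: the reconstruction weight
#' \code{alpha} over [1, 1e3] and the auxiliary weights over [0.1, 1e2],
#' reflecting that the higher-order reconstruction term is designed to
#' dominate the objective. A plain alternative to model-based
#' hyperparameter search for users who want to tune.
#'
#' @param n Number of settings to draw.
#' @param seed Integer seed.
#' @return List of \code{\link{lossWeights}} lists.
#' @export
randomSearchWeights <- function(n = 10L, seed = 1L) {
    withSeed(seed, lapply(seq_len(n), function(i) {
        lossWeights(alpha = 10^stats::runif(1, 0, 3),
                    gamma = 10^stats::runif(1, -1, 2),
                    lambda = 10^stats::runif(1, -1, 2),
                    omega = 10^stats::runif(1, -1, 2),
                    phi = 10^stats::runif(1, -1, 2))
    }))
}
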